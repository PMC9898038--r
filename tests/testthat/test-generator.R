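test_that("config validation rejects malformed inputs", {
  expect_error(generator_config(cells_per_sample = 0), "cells_per_sample")
  expect_error(generator_config(dropout_extra = 1.5), "probability")
  st <- default_states(2000)
  st$marker_genes[[1]] <- c(1L, 999999L)
  expect_error(generator_config(states = st), "exceed n_genes")
  st2 <- default_states(2000)
  st2$prop_hc <- st2$prop_hc * 0.5
  expect_error(generator_config(states = st2), "sum to 1")
  st3 <- default_states(2000)
  st3$cycling[st3$name == "PSP"] <- FALSE
  expect_error(generator_config(states = st3), "cycling")
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- generator_config(n_patients_aml = 2, n_patients_hc = 2,
                          cells_per_sample = 80, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cells$counts, b$cells$counts)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("planted composition equals realized true-state frequencies exactly", {
  fix <- small_cohort()
  tr <- fix$sim$truth
  for (s in unique(tr$samples$sample)) {
    planted <- tr$samples[tr$samples$sample == s, ]
    freq <- table(factor(tr$cells$state[tr$cells$sample == s],
                         levels = planted$state)) / sum(tr$cells$sample == s)
    expect_equal(planted$proportion, as.numeric(freq))
  }
})

test_that("equal leukemia proportions yield an exact uniform AML composition", {
  st <- default_states(2000)
  st$prop_aml <- c(rep(1 / 6, 6), rep(0, 6))
  cfg <- generator_config(states = st, n_patients_aml = 1, n_patients_hc = 1,
                          cells_per_sample = 120, composition_alpha = 1e9, seed = 5)
  # huge concentration: the Dirichlet draw collapses onto the baseline
  sim <- simulate_cohort(cfg)
  comp <- sim$truth$samples
  aml <- comp[comp$condition == "AML" & comp$proportion > 0, ]
  expect_equal(aml$proportion, rep(1 / 6, 6))
})

test_that("leukemia states appear only in AML samples", {
  fix <- small_cohort()
  tr <- fix$sim$truth$cells
  expect_true(all(tr$condition[tr$malignant] == "AML"))
  expect_true(any(tr$condition[!tr$malignant] == "AML"))  # shared normal lineages
})

test_that("marginal count means match the analytic formula within 3 SE", {
  st <- default_states(1000)[7, ]   # one non-cycling normal state
  st$prop_hc <- 1; st$prop_aml <- 1
  cfg <- generator_config(n_genes = 1000, states = st, n_patients_aml = 1,
                          n_patients_hc = 1, cells_per_sample = 5000,
                          patient_effect_sd = 0, libsize_log_sd = 0,
                          dropout_extra = 0, mito_frac_mean = 0.05, seed = 31)
  mu <- state_profiles(cfg, states = st$name, scale_to = NULL)[, 1]
  sim <- simulate_cohort(cfg)
  obs <- Matrix::rowMeans(sim$cells$counts)
  non_mt <- !startsWith(names(mu), "MT-")
  se <- sqrt((mu + mu^2 / cfg$dispersion) / 10000)
  frac_outside <- mean(abs(obs[non_mt] - mu[non_mt]) > 3 * se[non_mt])
  # pointwise 3-SE exceedances should be at the rare-event level
  expect_lt(frac_outside, 0.01)
})

test_that("stem states express more distinct genes than differentiated states", {
  fix <- small_cohort()
  tr <- fix$truth
  rich <- Matrix::colSums(fix$cells$counts > 0)
  mean_rich <- tapply(rich, tr$state, mean)
  expect_gt(mean_rich["QSC"], mean_rich["mono"])
  expect_gt(mean_rich["PSP"], mean_rich["promono"])
})

test_that("a no-signal config yields no condition-specific clusters", {
  st <- default_states(1000, marker_log_effect = 0)
  cfg <- generator_config(n_genes = 1000, states = st, n_patients_aml = 2,
                          n_patients_hc = 3, cells_per_sample = 120,
                          patient_effect_sd = 0,
                          program_log_effect = 0, cycle_log_effect = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  norm <- normalize_log(qc_filter(sim$cells, min_genes = 50))
  emb <- reduce_and_graph(norm, n_hvg = 300, d = 10)
  cl <- cluster_cells(emb, norm, resolution = 1, seed = 1)
  meta <- sim$cells$cell_meta[match(colnames(norm), sim$cells$cell_meta$cell_id), ]
  mal <- classify_clusters(cl, meta)
  expect_true(all(mal$clusters$call == "normal-like"))
})

test_that("longitudinal lambda=0 and lambda=1 hit the pure state profiles", {
  cfg <- generator_config(seed = 3)
  s0 <- simulate_longitudinal(cfg, 0, cells_per_timepoint = 60)
  expect_equal(s0$truth$post_psp_profile, s0$truth$profiles[, "PSP"])
  s1 <- simulate_longitudinal(cfg, 1, cells_per_timepoint = 60)
  expect_equal(s1$truth$post_psp_profile, s1$truth$profiles[, "QSC"])
  expect_error(simulate_longitudinal(cfg, 1.2), "lambda")
})

test_that("post-PSP pseudo-bulk lies between pre-PSP and pre-QSC at lambda=0.5", {
  cfg <- generator_config(seed = 19)
  sim <- simulate_longitudinal(cfg, 0.5, cells_per_timepoint = 1500)
  tc <- sim$truth$cells
  pre <- sim$pre$counts; post <- sim$post$counts
  markers <- c(cfg$layout$marker_blocks[[1]], cfg$layout$marker_blocks[[2]])
  pb <- function(m, idx) Matrix::rowMeans(m[markers, idx, drop = FALSE])
  qsc_pre <- pb(pre, tc$state[tc$timepoint == "pre"] == "QSC")
  psp_pre <- pb(pre, tc$state[tc$timepoint == "pre"] == "PSP")
  psp_post <- pb(post, tc$state[tc$timepoint == "post"] == "PSP")
  lo <- pmin(qsc_pre, psp_pre); hi <- pmax(qsc_pre, psp_pre)
  # within sampling error of the bracketing interval
  tol <- 0.2 * (hi - lo) + 0.35
  expect_true(all(psp_post > lo - tol & psp_post < hi + tol))
})

test_that("bulk mixtures are exact linear combinations without noise", {
  prof <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  p_id <- diag(2); colnames(p_id) <- c("A", "B")
  bulk <- simulate_bulk_mixtures(prof, p_id, noise_sd = 0)
  expect_equal(unname(bulk[1, ]), unname(prof[, 1]))
  p <- matrix(c(0.7, 0.3), nrow = 1)
  bulk2 <- simulate_bulk_mixtures(prof, p, noise_sd = 0)
  expect_equal(unname(bulk2[1, ]), unname(0.7 * prof[, 1] + 0.3 * prof[, 2]))
  expect_error(simulate_bulk_mixtures(prof, matrix(c(0.5, 0.4), nrow = 1)),
               "sum to 1")
})

test_that("survival generator realizes the planted hazard structure", {
  comp <- tibble::tibble(sample = sprintf("s%02d", 1:40),
                         ith = rep(c(0, 1), each = 20))
  tab <- simulate_survival(comp, betas = c(ith = log(2)), censor_rate = 0, seed = 2)
  expect_true(all(tab$event == 1))
  expect_gt(mean(tab$time[comp$ith == 0]), mean(tab$time[comp$ith == 1]))
  expect_error(simulate_survival(comp, baseline_rate = -1), "positive")
})
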