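ref_fixture <- function() {
  if (!is.null(.fixture_env$ref)) return(.fixture_env$ref)
  fix <- small_cohort()
  set.seed(1)
  n <- ncol(fix$norm)
  test <- sort(sample(n, round(0.2 * n)))
  train <- setdiff(seq_len(n), test)
  emb <- reduce_and_graph(fix$norm[, train])
  out <- list(fix = fix, train = train, test = test, emb = emb,
              labels = fix$truth$state[train])
  .fixture_env$ref <- out
  out
}

test_that("self-transfer reproduces reference labels exactly", {
  rf <- ref_fixture()
  tr <- transfer_labels(list(embedding = rf$emb, labels = rf$labels),
                        rf$fix$cells$counts[, rf$train], k = 5)
  expect_equal(mean(tr$state == rf$labels), 1)
  expect_true(all(tr$confidence > 0 & tr$confidence <= 1))
})

test_that("held-out cells are labeled accurately", {
  rf <- ref_fixture()
  tr <- transfer_labels(list(embedding = rf$emb, labels = rf$labels),
                        rf$fix$cells$counts[, rf$test], k = 15)
  truth <- rf$fix$truth$state[rf$test]
  expect_gte(mean(tr$state == truth), 0.9)
})

test_that("k=1 equals the nearest-neighbor label and order does not matter", {
  rf <- ref_fixture()
  q <- rf$fix$cells$counts[, rf$test]
  t1 <- transfer_labels(list(embedding = rf$emb, labels = rf$labels), q, k = 1)
  nn <- RANN::nn2(rf$emb$pcs,
                  transfer_project(rf$emb, q), k = 1)
  expect_equal(t1$state, rf$labels[nn$nn.idx[, 1]])
  set.seed(3); perm <- sample(ncol(q))
  t2 <- transfer_labels(list(embedding = rf$emb, labels = rf$labels),
                        q[, perm], k = 15)
  t0 <- transfer_labels(list(embedding = rf$emb, labels = rf$labels), q, k = 15)
  expect_equal(t2$state[match(t0$cell_id, t2$cell_id)], t0$state)
  expect_error(transfer_labels(list(embedding = rf$emb, labels = rf$labels),
                               q[1:50, ]), "fewer than 200")
})

test_that("composition shift reports exact deltas and unit column sums", {
  a <- rep(c("QSC", "PSP"), c(30, 70))
  sh <- composition_shift(a, a)
  expect_true(all(sh$proportions$delta == 0))
  b <- rep(c("QSC", "PSP"), c(50, 50))
  sh2 <- composition_shift(a, b)
  expect_equal(sum(sh2$proportions$pre), 1)
  expect_equal(sum(sh2$proportions$post), 1)
  expect_equal(sh2$proportions$delta[sh2$proportions$state == "QSC"], 0.2)
  expect_equal(tidy(sh2)$delta, sh2$proportions$delta)
})

test_that("transferred composition shift recovers the planted QSC rise", {
  fix <- small_cohort()
  lcfg <- generator_config(seed = 23)
  sim <- simulate_longitudinal(lcfg, lambda = 0, cells_per_timepoint = 2000)
  rf <- ref_fixture()
  tp <- lapply(list(pre = sim$pre, post = sim$post), function(cm) {
    transfer_labels(list(embedding = rf$emb, labels = rf$labels), cm, k = 15)
  })
  leuk6 <- c("QSC", "PSP", "GMP", "PG", "promono", "mono")
  sh <- composition_shift(dplyr::filter(tp$pre, .data$state %in% leuk6),
                          dplyr::filter(tp$post, .data$state %in% leuk6))
  qsc <- sh$proportions[sh$proportions$state == "QSC", ]
  expect_lt(abs(qsc$pre - 0.055), 0.02)
  expect_lt(abs(qsc$post - 0.107), 0.02)
  psp <- sh$proportions[sh$proportions$state == "PSP", ]
  expect_lt(psp$delta, 0)   # PSPs decrease under treatment
})

test_that("state DE finds planted shifts and is quiet under the null", {
  # two pure-QSC pseudo-timepoints, 300 cells each
  st <- default_states(1000)[1, ]
  st$prop_hc <- 1; st$prop_aml <- 1
  cfg <- generator_config(n_genes = 1000, states = st, n_patients_aml = 1,
                          n_patients_hc = 1, cells_per_sample = 300,
                          patient_effect_sd = 0, seed = 41)
  sim <- simulate_cohort(cfg)
  norm <- normalize_log(qc_filter(sim$cells, min_genes = 50))
  meta <- sim$cells$cell_meta[match(colnames(norm), sim$cells$cell_meta$cell_id), ]
  pre <- which(meta$sample == meta$sample[1])
  post <- which(meta$sample != meta$sample[1])
  lab <- function(ids) tibble::tibble(cell_id = ids, state = "QSC")
  null_de <- state_de(norm[, pre], norm[, post], lab(colnames(norm)[pre]),
                      lab(colnames(norm)[post]), "QSC")
  expect_lte(nrow(null_de), 2)
  # plant a 2-fold linear-scale up-shift in 20 well-expressed genes
  avg <- Matrix::rowMeans(norm)
  cand <- names(sort(avg[!startsWith(names(avg), "MT-")], decreasing = TRUE))
  up_genes <- cand[101:120]
  shifted <- norm[, post]
  shifted[up_genes, ] <- log1p(2 * expm1(as.matrix(shifted[up_genes, ])))
  de <- state_de(norm[, pre], shifted, lab(colnames(norm)[pre]),
                 lab(colnames(shifted)), "QSC")
  expect_gte(sum(up_genes %in% de$gene), 18)
  expect_lte(sum(!de$gene %in% up_genes), 2)
  # gene order does not change the result
  set.seed(2); gperm <- sample(nrow(norm))
  de2 <- state_de(norm[gperm, pre], shifted[gperm, ], lab(colnames(norm)[pre]),
                  lab(colnames(shifted)), "QSC")
  expect_equal(as.data.frame(de), as.data.frame(de2))
  expect_error(state_de(norm[, pre[1:2]], norm[, post],
                        lab(colnames(norm)[pre[1:2]]), lab(colnames(norm)[post]),
                        "QSC"),
               "fewer than 3")
})

test_that("reprogramming index hits its endpoints and ignores non-DE genes", {
  fix <- small_cohort()
  tr <- fix$truth
  qsc <- fix$norm[, tr$state == "QSC"]
  psp <- fix$norm[, tr$state == "PSP"]
  de <- lineage_programs(fix$cfg)$stem
  r0 <- reprogramming_index(qsc, psp, psp, de)
  expect_equal(r0$R, 0)
  r1 <- reprogramming_index(qsc, psp, qsc, de)
  expect_equal(r1$R, 1)
  expect_error(reprogramming_index(qsc, qsc, psp, de), "coincide")
  # adding genes with identical group means leaves R unchanged
  base <- reprogramming_index(qsc, psp, psp[, 1:20], de)
  pad <- function(m) {
    flat <- Matrix::Matrix(1, 5, ncol(m), sparse = TRUE,
                           dimnames = list(sprintf("FLAT%d", 1:5), colnames(m)))
    rbind(m, flat)
  }
  more <- reprogramming_index(pad(qsc), pad(psp), pad(psp[, 1:20]),
                              c(de, sprintf("FLAT%d", 1:5)))
  expect_equal(base$R, more$R)
  expect_equal(nrow(tidy(base)), ncol(qsc) + ncol(psp) + 20)
  expect_equal(glance(base)$R, base$R)
})

test_that("R increases with the planted reprogramming coefficient", {
  lams <- c(0, 0.5, 1)
  rs <- vapply(lams, function(lam) {
    cfg <- generator_config(seed = 37)
    sim <- simulate_longitudinal(cfg, lam, cells_per_timepoint = 800)
    tc <- sim$truth$cells
    npre <- normalize_log(sim$pre); npost <- normalize_log(sim$post)
    pre_t <- tc[tc$timepoint == "pre", ]; post_t <- tc[tc$timepoint == "post", ]
    reprogramming_index(npre[, pre_t$state == "QSC"], npre[, pre_t$state == "PSP"],
                        npost[, post_t$state == "PSP"],
                        lineage_programs(cfg)$stem)$R
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_lt(rs[1], 0.2)
  expect_gt(rs[3], 0.8)
})
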