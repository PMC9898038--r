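make_cm <- function(counts, condition = rep("AML", ncol(counts))) {
  rownames(counts) <- rownames(counts) %||% sprintf("g%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE),
              tibble::tibble(cell_id = colnames(counts), sample = "s1",
                             condition = condition, patient = "p1"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("qc_filter applies each rule and reports it", {
  # no MT- genes: mito rule vacuously passes everything
  m <- matrix(rpois(50 * 20, 5), 50)
  cm <- make_cm(m)
  out <- qc_filter(cm, min_genes = 1, max_genes = Inf, max_mito_frac = 0.01)
  expect_equal(ncol(out$counts), 20)
  # cell expressing zero genes is removed by min_genes
  m2 <- matrix(5, 300, 3); m2[, 2] <- 0
  out2 <- qc_filter(make_cm(m2), min_genes = 200, max_genes = Inf,
                    max_mito_frac = 1, min_cells_per_gene = 1)
  expect_equal(ncol(out2$counts), 2)
  expect_false("c002" %in% out2$cell_ids)
  rep <- attr(out2, "qc_report")
  expect_equal(rep$cells_removed[rep$rule == "min_genes"], 1)
  # all cells removed names the binding rule
  expect_error(qc_filter(make_cm(m2), min_genes = 1000), "min_genes")
})

test_that("qc_filter removes exactly the planted high-mito cells", {
  cfg <- generator_config(n_patients_aml = 1, n_patients_hc = 2,
                          cells_per_sample = 400, mito_outlier_frac = 0.05,
                          mito_outlier_level = 0.5, dispersion = 10,
                          mito_conc = 300, seed = 21)
  sim <- simulate_cohort(cfg)
  planted <- sim$truth$cells$cell_id[sim$truth$cells$mito_outlier]
  expect_gt(length(planted), 0)
  out <- qc_filter(sim$cells, min_genes = 1, max_genes = Inf, max_mito_frac = 0.2)
  removed <- setdiff(sim$cells$cell_ids, out$cell_ids)
  expect_setequal(removed, planted)
})

test_that("normalize_log matches its closed form and preserves totals", {
  m <- matrix(0, 5, 2); m[1, 1] <- 10; m[2, 2] <- 3; m[3, 2] <- 1
  cm <- make_cm(m)
  norm <- normalize_log(cm)
  expect_equal(norm[1, 1], log1p(10000))
  tot <- Matrix::colSums(expm1(as.matrix(norm)))
  expect_equal(unname(tot), rep(10000, 2))
  # duplicate cells give identical columns
  m3 <- matrix(rpois(100, 4), 50, 2); m3[, 2] <- m3[, 1]
  n3 <- normalize_log(make_cm(m3))
  expect_equal(n3[, 1], n3[, 2])
  # zero-total cell is an error
  m4 <- matrix(0, 5, 1)
  expect_error(normalize_log(make_cm(m4)), "zero total")
})

test_that("wilcox_matrix agrees with stats::wilcox.test", {
  set.seed(4)
  x <- matrix(c(rpois(60, 3), rpois(60, 8)), nrow = 6,
              dimnames = list(letters[1:6], NULL))
  res <- lscape:::wilcox_matrix(x, 1:10, 11:20)
  for (i in 1:6) {
    ref <- suppressWarnings(wilcox.test(x[i, 1:10], x[i, 11:20],
                                        correct = TRUE, exact = FALSE))$p.value
    expect_equal(res$p[i], ref, tolerance = 1e-10)
  }
})

test_that("PCA separates planted populations and is deterministic", {
  fix <- small_cohort()
  emb2 <- reduce_and_graph(fix$norm)
  expect_identical(fix$emb$pcs, emb2$pcs)
  expect_identical(fix$emb$embedding2d, emb2$embedding2d)
  # two planted blob states alone: the first PC separates them
  st2 <- default_states(1500)[c(6, 10), ]   # mono and Tcell
  st2$prop_hc <- c(0.5, 0.5); st2$prop_aml <- c(0.5, 0.5)
  cfg2 <- generator_config(n_genes = 1500, states = st2, n_patients_aml = 1,
                           n_patients_hc = 1, cells_per_sample = 150, seed = 13)
  sim2 <- simulate_cohort(cfg2)
  n2 <- normalize_log(qc_filter(sim2$cells, min_genes = 50))
  e2 <- reduce_and_graph(n2, n_hvg = 300, d = 10)
  tr2 <- sim2$truth$cells[match(colnames(n2), sim2$truth$cells$cell_id), ]
  sil <- silhouette1d(e2$pcs[, 1], tr2$state)
  expect_gt(sil, 0.5)
  # duplicate cells land on identical PC rows
  m <- matrix(rpois(400, 5), 100, 4); m[, 4] <- m[, 1]
  nm <- normalize_log(make_cm(m))
  e <- reduce_and_graph(nm, n_hvg = 50, d = 2, k = 2)
  expect_equal(unname(e$pcs[1, ]), unname(e$pcs[4, ]))
  expect_error(reduce_and_graph(nm, n_hvg = 50, d = 100), "exceeds")
})

test_that("clustering recovers planted states at high purity", {
  fix <- small_cohort()
  purity <- tapply(seq_along(fix$cl$labels), fix$cl$labels, function(i) {
    max(table(fix$truth$state[i])) / length(i)
  })
  frac_pure <- sum(purity * table(fix$cl$labels)) / length(fix$cl$labels)
  expect_gte(length(unique(fix$cl$labels)), 6)
  expect_gte(frac_pure, 0.9)
})

test_that("near-zero resolution on a connected graph gives one cluster", {
  fix <- small_cohort()
  g <- igraph::make_ring(60)
  cl0 <- cluster_cells(g, fix$norm[, 1:60], resolution = 1e-5, seed = 1)
  expect_equal(length(unique(cl0$labels)), 1)
})

test_that("related states correlate more in the centroid tree", {
  fix <- small_cohort()
  # dominant truth state per cluster
  dom <- vapply(sort(unique(fix$cl$labels)), function(k) {
    names(which.max(table(fix$truth$state[fix$cl$labels == k])))
  }, character(1))
  cc <- cor(t(scale(fix$cl$centroids, center = TRUE, scale = FALSE)))
  # PSP and PG share the cycling program and most richness programs; PSP
  # and mono share almost nothing beyond baseline
  psp_cl <- which(dom == "PSP"); pg_cl <- which(dom == "PG")
  mono_cl <- which(dom == "mono")
  expect_true(length(psp_cl) > 0 && length(pg_cl) > 0 && length(mono_cl) > 0)
  expect_gt(mean(cc[psp_cl, pg_cl]), mean(cc[psp_cl, mono_cl]))
  expect_error(cluster_cells(igraph::make_empty_graph(0), fix$norm), "empty")
})

test_that("pipeline stages are deterministic end to end for a fixed seed", {
  fix <- small_cohort()
  cl2 <- cluster_cells(fix$emb, fix$norm, resolution = 3, seed = 1)
  expect_identical(fix$cl$labels, cl2$labels)
})
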