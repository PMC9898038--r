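# Shared small-cohort fixture, built once per session and memoised.
# 3 AML + 5 HC samples x 200 cells keeps every unit test fast while leaving
# all states represented with tens of cells each.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- generator_config(n_patients_aml = 3, n_patients_hc = 5,
                          cells_per_sample = 200, seed = 7)
  sim <- simulate_cohort(cfg)
  cells <- qc_filter(sim$cells)
  norm <- normalize_log(cells)
  emb <- reduce_and_graph(norm)
  cl <- cluster_cells(emb, norm, resolution = 3, seed = 1)
  mal <- classify_clusters(cl, cells$cell_meta)
  truth <- sim$truth$cells[match(cells$cell_ids, sim$truth$cells$cell_id), ]
  fix <- list(cfg = cfg, sim = sim, cells = cells, norm = norm, emb = emb,
              cl = cl, mal = mal, truth = truth)
  .fixture_env$small <- fix
  fix
}

# leukemia-cell submatrix with true state labels
leukemia_subset <- function(fix = small_cohort()) {
  leuk <- which(fix$truth$malignant)
  list(norm = fix$norm[, leuk, drop = FALSE],
       states = tibble::tibble(cell_id = fix$truth$cell_id[leuk],
                               state = fix$truth$state[leuk]))
}

# mean silhouette of a 1-D coordinate split by labels
silhouette1d <- function(x, labels) {
  d <- as.matrix(dist(x))
  sil <- vapply(seq_along(x), function(i) {
    own <- mean(d[i, labels == labels[i] & seq_along(x) != i])
    other <- min(vapply(setdiff(unique(labels), labels[i]),
                        function(l) mean(d[i, labels == l]), numeric(1)))
    (other - own) / max(own, other)
  }, numeric(1))
  mean(sil)
}
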