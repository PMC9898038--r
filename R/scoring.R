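#' Binned-control module score
#'
#' Mean expression of a gene set minus the mean of control genes sampled
#' from matching average-expression bins: genes are binned by their pooled
#' mean expression into `n_bins`, and for each set gene `n_ctrl` controls
#' are drawn (with replacement when the bin is small) from the non-set
#' genes of its bin (falling back to the whole bin when a bin holds only
#' set genes). Used for the proliferation and cell-cycle phase scores.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param gene_set character vector of gene names.
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed for the control draw.
#' @return numeric per-cell score, named by cell id.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) == 0) {
    abort_ls("no gene of the set is present in the matrix; missing: ",
             paste(head(gene_set, 10), collapse = ", "))
  }
  set.seed(seed)
  data_avg <- Matrix::rowMeans(normalized)
  bins <- cut(rank(data_avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(normalized)
  ctrl_counts <- integer(nrow(normalized))
  names(ctrl_counts) <- rownames(normalized)
  for (g in present) {
    pool <- setdiff(names(bins)[bins == bins[g]], present)
    if (length(pool) == 0) pool <- names(bins)[bins == bins[g]]
    draw <- sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    tab <- table(draw)
    ctrl_counts[names(tab)] <- ctrl_counts[names(tab)] + as.integer(tab)
  }
  ctrl_idx <- which(ctrl_counts > 0)
  w <- ctrl_counts[ctrl_idx] / sum(ctrl_counts)
  ctrl_mean <- as.numeric(w %*% normalized[ctrl_idx, , drop = FALSE])
  set_mean <- Matrix::colMeans(normalized[present, , drop = FALSE])
  setNames(as.numeric(set_mean - ctrl_mean), colnames(normalized))
}

#' Cell-cycle phase from S and G2M module scores
#'
#' `G1` when both scores are `<= 0`; otherwise the phase with the larger
#' score (exact ties go to S).
#'
#' @param s_score,g2m_score numeric per-cell module scores.
#' @return character vector of phases (`"G1"`, `"S"`, `"G2M"`).
#' @export
cycle_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score))
  out <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                ifelse(s_score >= g2m_score, "S", "G2M"))
  unname(out)
}

#' Transcriptional-diversity stemness score
#'
#' A rank-based stemness estimate in the spirit of gene-counts-based
#' differentiation scoring: (i) per-cell expressed-gene richness; (ii)
#' Pearson correlation of every gene with richness; (iii) raw score = mean
#' expression of the `top_k` most richness-correlated genes; (iv) diffusion
#' smoothing over the kNN graph, `s <- (1 - alpha) s + alpha A s` with
#' row-normalized adjacency `A`; (v) rank-scaling to `[0, 1]` (stem-most
#' cells near 1; an all-tied input maps to 0.5).
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param knn an `embedding_result` (its `knn_index` is used) or a cells x k
#'   integer neighbor-index matrix.
#' @param top_k genes to average (capped at the gene count, with a warning).
#' @param smooth_alpha,smooth_steps smoothing weight and iterations.
#' @return numeric per-cell score in `[0, 1]`, named by cell id.
#' @export
stemness_score <- function(normalized, knn, top_k = 200,
                           smooth_alpha = 0.5, smooth_steps = 3) {
  idx <- if (inherits(knn, "embedding_result")) knn$knn_index else as.matrix(knn)
  n <- ncol(normalized)
  stopifnot(nrow(idx) == n)
  gc <- Matrix::colSums(normalized > 0)
  mu_g <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  sd_g <- sqrt(pmax(ex2 - mu_g^2, 0))
  sxy <- as.numeric(normalized %*% gc) / n
  covar <- sxy - mu_g * mean(gc)
  sd_gc <- sqrt(mean(gc^2) - mean(gc)^2)
  r <- covar / (sd_g * sd_gc)
  r[!is.finite(r)] <- -Inf
  if (top_k > nrow(normalized)) {
    warning("top_k exceeds the number of genes; using all genes")
    top_k <- nrow(normalized)
  }
  top <- order(r, decreasing = TRUE)[seq_len(top_k)]
  s <- as.numeric(Matrix::colMeans(normalized[top, , drop = FALSE]))
  for (step in seq_len(smooth_steps)) {
    if (smooth_alpha == 0) break
    neigh <- matrix(s[idx], nrow = n)
    s <- (1 - smooth_alpha) * s + smooth_alpha * rowMeans(neigh)
  }
  setNames(rank_scale01(s), colnames(normalized))
}

#' Single-sample gene-set enrichment score
#'
#' Per cell, genes are ranked by expression (ties broken by gene order) and
#' weighted by `rank^exponent` (top ranks heaviest). The score is the sum
#' over the ranking of the difference between the weighted in-set and
#' out-set running ECDFs, each normalized by its expected total mass so
#' that a random gene set on a random ranking scores zero in expectation.
#' The sum is scaled by the range between the best (set entirely at the
#' top) and worst achievable values for a set of that size.
#'
#' @param normalized genes x cells matrix.
#' @param gene_set character vector (>= 2 present genes required).
#' @param exponent rank weight exponent.
#' @return numeric per-cell score, named by cell id.
#' @export
ssgsea_score <- function(normalized, gene_set, exponent = 0.75) {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) == 0) abort_ls("gene set shares no genes with the matrix")
  if (length(present) < 2) abort_ls("need at least 2 present set genes")
  x <- as.matrix(normalized)
  ng <- nrow(x)
  in_set <- rownames(x) %in% present
  ns <- sum(in_set)
  wts <- (ng:1)^exponent   # weight by descending-rank position
  w_tot <- sum(wts)
  es_for <- function(in_pos) {
    pin <- cumsum(wts * in_pos) / (w_tot * ns / ng)
    pout <- cumsum(wts * !in_pos) / (w_tot * (ng - ns) / ng)
    sum(pin - pout)
  }
  es_max <- es_for(c(rep(TRUE, ns), rep(FALSE, ng - ns)))
  es_min <- es_for(c(rep(FALSE, ng - ns), rep(TRUE, ns)))
  scores <- vapply(seq_len(ncol(x)), function(j) {
    ord <- order(x[, j], decreasing = TRUE)
    es_for(in_set[ord])
  }, numeric(1))
  setNames(scores / (es_max - es_min), colnames(x))
}
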