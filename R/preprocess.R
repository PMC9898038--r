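#' Quality-control filter for a cell matrix
#'
#' Removes cells outside the detected-gene bounds or above the mitochondrial
#' fraction threshold (mitochondrial genes are identified by the `MT-` name
#' prefix), then removes genes expressed in fewer than 3 remaining cells.
#' A per-rule filtering report is attached as attribute `"qc_report"`.
#'
#' @param m a [cell_matrix()].
#' @param min_genes,max_genes bounds on the number of detected genes per
#'   cell.
#' @param max_mito_frac maximum fraction of counts from `MT-` genes.
#' @param min_cells_per_gene genes expressed in fewer cells are dropped.
#' @return a filtered [cell_matrix()] with a `qc_report` attribute (tibble
#'   of cells removed per rule).
#' @export
qc_filter <- function(m, min_genes = 200, max_genes = 6000, max_mito_frac = 0.2,
                      min_cells_per_gene = 3) {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts
  n_detect <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), "MT-")
  mito_frac <- if (any(mito)) {
    tot <- Matrix::colSums(counts)
    ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  } else rep(0, ncol(counts))
  fail_low <- n_detect < min_genes
  fail_high <- n_detect > max_genes
  fail_mito <- mito_frac > max_mito_frac
  keep <- !(fail_low | fail_high | fail_mito)
  report <- tibble::tibble(
    rule = c("min_genes", "max_genes", "max_mito_frac"),
    threshold = c(min_genes, max_genes, max_mito_frac),
    cells_removed = c(sum(fail_low), sum(fail_high), sum(fail_mito))
  )
  if (!any(keep)) {
    worst <- report$rule[which.max(report$cells_removed)]
    abort_ls("QC removed all cells; binding rule: ", worst)
  }
  counts <- counts[, keep, drop = FALSE]
  gene_keep <- Matrix::rowSums(counts > 0) >= min_cells_per_gene
  counts <- counts[gene_keep, , drop = FALSE]
  out <- cell_matrix(counts, m$cell_meta[keep, , drop = FALSE])
  attr(out, "qc_report") <- dplyr::mutate(report,
    cells_in = ncol(m$counts), cells_out = ncol(counts),
    genes_removed = sum(!gene_keep))
  out
}

#' Log-normalize counts to counts-per-10k
#'
#' Scales each cell to 10,000 total counts and applies `log1p`; zeros stay
#' zero so sparsity is preserved.
#'
#' @param m a [cell_matrix()] or a sparse/dense genes x cells count matrix.
#' @return a sparse `dgCMatrix` of log-normalized values, genes x cells.
#' @export
normalize_log <- function(m) {
  counts <- if (inherits(m, "cell_matrix")) m$counts else m
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    abort_ls(sum(tot == 0), " cell(s) have zero total counts; run qc_filter first")
  }
  norm <- counts %*% Matrix::Diagonal(x = 1e4 / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

# HVG selection by mean-variance trend residual: fit a loess of log
# variance against log mean of the log-normalized values and rank genes by
# how far their variance exceeds the trend. Robust to many co-varying
# marker programs sharing one expression stratum (where within-bin
# z-scoring would cancel them out).
select_hvg <- function(normalized, n_hvg = 1000) {
  mu <- Matrix::rowMeans(normalized)
  ex2 <- Matrix::rowMeans(normalized^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(normalized) / max(1, ncol(normalized) - 1)
  ok <- mu > 0 & v > 0
  score <- rep(-Inf, length(mu))
  lm_ <- log10(mu[ok]); lv <- log10(v[ok])
  fit <- stats::loess(lv ~ lm_, span = 0.3, degree = 2,
                      family = "symmetric")
  score[ok] <- lv - fit$fitted
  order(score, decreasing = TRUE)[seq_len(min(n_hvg, sum(ok)))]
}

#' Reduce dimensionality and build the cell kNN graph
#'
#' Selects highly variable genes by their residual from a loess
#' mean-variance trend (normalized dispersion), z-scales them
#' (clipped at +/-10), computes principal components by exact
#' eigendecomposition of the gene crossproduct (deterministic, no RNG),
#' builds a Euclidean k-nearest-neighbor graph on the PCs, and exposes the
#' first two PCs as the 2D embedding. Gene means, scales and loadings are
#' stored so new cells can be projected (used by label transfer).
#'
#' @param normalized genes x cells log-normalized sparse matrix.
#' @param n_hvg number of highly variable genes.
#' @param d number of principal components.
#' @param k neighbors for the kNN graph.
#' @return an `embedding_result` list: `hvg` (gene names), `center`,
#'   `scale`, `rotation` (hvg x d), `pcs` (cells x d), `knn_index`
#'   (cells x k), `graph` (undirected igraph), `embedding2d` (cells x 2).
#' @export
reduce_and_graph <- function(normalized, n_hvg = 1500, d = 30, k = 15) {
  if (n_hvg > nrow(normalized)) abort_ls("n_hvg exceeds the number of genes")
  if (d > ncol(normalized)) abort_ls("d exceeds the number of cells")
  hvg_idx <- select_hvg(normalized, n_hvg)
  x <- as.matrix(Matrix::t(normalized[hvg_idx, , drop = FALSE]))  # cells x hvg
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  x[x > 10] <- 10; x[x < -10] <- -10
  cp <- crossprod(x)                       # hvg x hvg
  eig <- eigen(cp, symmetric = TRUE)
  d <- min(d, sum(eig$values > 1e-8))
  rot <- eig$vectors[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(d)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  pcs <- x %*% rot
  rownames(pcs) <- colnames(normalized)
  nn <- RANN::nn2(pcs, k = min(k + 1, nrow(pcs)))
  idx <- nn$nn.idx[, -1, drop = FALSE]     # drop self
  edges <- cbind(rep(seq_len(nrow(idx)), ncol(idx)), as.vector(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)                 # symmetricize (union) + dedupe
  structure(list(hvg = rownames(normalized)[hvg_idx], center = ctr, scale = scl,
                 rotation = rot, pcs = pcs, knn_index = idx, graph = g,
                 embedding2d = pcs[, 1:2, drop = FALSE]),
            class = "embedding_result")
}

#' Cluster cells by modularity-based community detection
#'
#' Runs Leiden community detection on the kNN graph at the given resolution
#' (default 3, deliberately over-clustered so that malignancy can be called
#' from cluster composition), then computes per-cluster mean log-expression
#' centroids and an average-linkage tree over centroid Pearson correlation.
#'
#' @param embedding an `embedding_result` from [reduce_and_graph()] (or an
#'   igraph graph).
#' @param normalized genes x cells log-normalized matrix (for centroids).
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed (community detection is stochastic).
#' @return a `cluster_result` list: `labels` (integer per cell),
#'   `resolution`, `centroids` (cluster x gene), `corr_tree` (hclust).
#' @export
cluster_cells <- function(embedding, normalized, resolution = 3, seed = 1L) {
  g <- if (inherits(embedding, "embedding_result")) embedding$graph else embedding
  if (igraph::vcount(g) == 0) abort_ls("empty graph")
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  labels <- as.integer(igraph::membership(comm))
  # relabel 1..K by first appearance for stable ids
  labels <- match(labels, unique(labels))
  cent <- centroid_matrix(normalized, labels)
  tree <- NULL
  if (nrow(cent) >= 3) {
    # correlate per-gene deviations from the across-cluster mean, so the
    # tree reflects shared programs rather than the common baseline
    dev <- scale(cent, center = TRUE, scale = FALSE)
    cc <- suppressWarnings(cor(Matrix::t(dev)))
    cc[is.na(cc)] <- 0
    tree <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  }
  structure(list(labels = labels, resolution = resolution,
                 centroids = cent, corr_tree = tree),
            class = "cluster_result")
}

# cluster x gene mean log-expression, rows ordered by cluster id
centroid_matrix <- function(normalized, labels) {
  ids <- sort(unique(labels))
  ind <- sparseMatrix(i = seq_along(labels), j = match(labels, ids),
                      x = 1, dims = c(length(labels), length(ids)))
  ind <- ind %*% Matrix::Diagonal(x = 1 / Matrix::colSums(ind))
  cent <- as.matrix(Matrix::t(normalized %*% ind))
  rownames(cent) <- ids
  colnames(cent) <- rownames(normalized)
  cent
}
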