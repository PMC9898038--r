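#' Transfer state labels onto new cells by projection and kNN vote
#'
#' Query cells are log-normalized, z-scaled with the reference HVG means
#' and scales, projected onto the reference PC loadings, and labeled by a
#' majority vote of their `k` nearest reference cells in PC space
#' (Euclidean). Ties are broken by the smaller mean neighbor distance, then
#' by a fixed state order.
#'
#' @param reference a labeled reference: list with `embedding` (an
#'   `embedding_result`) and `labels` (per-reference-cell states, aligned
#'   with the embedding rows).
#' @param query a [cell_matrix()] or a genes x cells count/normalized
#'   matrix (counts are detected by integrality and normalized).
#' @param k neighbors to vote (default 15).
#' @param state_order tie-break order; default alphabetical.
#' @return tibble: `cell_id`, `state`, `confidence` (winning vote
#'   fraction), class `transfer_result`.
#' @export
transfer_labels <- function(reference, query, k = 15, state_order = NULL) {
  emb <- reference$embedding
  labels <- as.character(reference$labels)
  stopifnot(inherits(emb, "embedding_result"), length(labels) == nrow(emb$pcs))
  if (length(labels) < k) abort_ls("fewer than k labeled reference cells")
  pcs_q <- transfer_project(emb, query)
  nn <- RANN::nn2(emb$pcs, pcs_q, k = k)
  state_order <- state_order %||% sort(unique(labels))
  vote <- function(i) {
    labs <- labels[nn$nn.idx[i, ]]
    d <- nn$nn.dists[i, ]
    tab <- sort(table(labs), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    if (length(winners) > 1) {
      md <- vapply(winners, function(w) mean(d[labs == w]), numeric(1))
      winners <- winners[md == min(md)]
      if (length(winners) > 1) {
        winners <- winners[order(match(winners, state_order))][1]
      }
    }
    c(winners[1], tab[winners[1]] / k)
  }
  v <- vapply(seq_len(nrow(pcs_q)), vote, character(2))
  out <- tibble::tibble(cell_id = rownames(pcs_q), state = v[1, ],
                        confidence = as.numeric(v[2, ]))
  class(out) <- c("transfer_result", class(out))
  out
}

# normalize (if counts), scale with the reference statistics and project a
# query matrix into the reference PC space; absent HVGs contribute the mean
transfer_project <- function(emb, query) {
  qx <- if (inherits(query, "cell_matrix")) normalize_log(query) else {
    q <- methods::as(methods::as(query, "CsparseMatrix"), "generalMatrix")
    if (length(q@x) && all(q@x >= 0) && all(q@x == round(q@x))) normalize_log(q) else q
  }
  shared <- intersect(emb$hvg, rownames(qx))
  if (length(shared) < min(200, length(emb$hvg))) {
    abort_ls("query shares fewer than 200 genes with the reference HVGs")
  }
  xq <- matrix(0, ncol(qx), length(emb$hvg),
               dimnames = list(colnames(qx), emb$hvg))
  xq[, shared] <- as.matrix(Matrix::t(qx[shared, , drop = FALSE]))
  xq <- sweep(sweep(xq, 2, emb$center), 2, emb$scale, "/")
  xq[xq > 10] <- 10; xq[xq < -10] <- -10
  xq %*% emb$rotation
}

#' Composition shift between two timepoints
#'
#' Proportion vectors at each timepoint, their deltas, and (when per-cell
#' flow labels are available) a state_pre -> state_post flow table for a
#' Sankey-style display.
#'
#' @param states_pre,states_post per-cell state labels at each timepoint
#'   (character vectors or tibbles with a `state` column).
#' @param state_levels composition universe.
#' @return a `shift_table` list: `proportions` (tibble `state`, `pre`,
#'   `post`, `delta`; `pre` and `post` each sum to 1) and `n_cells`.
#' @export
composition_shift <- function(states_pre, states_post,
                              state_levels = c("QSC", "PSP", "GMP", "PG",
                                               "promono", "mono")) {
  pv <- function(s) {
    if (is.data.frame(s)) s <- s$state
    if (length(s) == 0) abort_ls("a timepoint has no cells")
    tab <- table(factor(s, levels = state_levels))
    as.numeric(tab / sum(tab))
  }
  pre <- pv(states_pre); post <- pv(states_post)
  out <- list(proportions = tibble::tibble(state = state_levels, pre = pre,
                                           post = post, delta = post - pre),
              n_cells = c(pre = if (is.data.frame(states_pre)) nrow(states_pre)
                          else length(states_pre),
                          post = if (is.data.frame(states_post)) nrow(states_post)
                          else length(states_post)))
  class(out) <- "shift_table"
  out
}

#' Per-state differential expression between timepoints
#'
#' Within one cellular state, a per-gene Wilcoxon rank-sum test between
#' pre- and post-treatment cells, BH-corrected and filtered by
#' log-fold-change and FDR.
#'
#' @param norm_pre,norm_post genes x cells log-normalized matrices
#'   restricted to the two timepoints.
#' @param states_pre,states_post per-cell labels aligned with the columns.
#' @param state the state to test (>= 3 cells required at each timepoint).
#' @param min_logfc,max_fdr selection thresholds (absolute logfc).
#' @return tibble: `gene`, `logfc` (post minus pre), `p`, `fdr`.
#' @export
state_de <- function(norm_pre, norm_post, states_pre, states_post, state,
                     min_logfc = 0.25, max_fdr = 0.05) {
  i_pre <- which(state_labels_for(norm_pre, states_pre) == state)
  i_post <- which(state_labels_for(norm_post, states_post) == state)
  if (length(i_pre) < 3 || length(i_post) < 3) {
    abort_ls("state ", state, " has fewer than 3 cells at a timepoint")
  }
  shared <- intersect(rownames(norm_pre), rownames(norm_post))
  x <- cbind(norm_post[shared, i_post, drop = FALSE],
             norm_pre[shared, i_pre, drop = FALSE])
  tab <- wilcox_matrix(x, seq_along(i_post), length(i_post) + seq_along(i_pre))
  tab$fdr <- p.adjust(tab$p, "BH")
  tab |>
    dplyr::filter(abs(.data$logfc) >= min_logfc, .data$fdr <= max_fdr) |>
    dplyr::arrange(dplyr::desc(abs(.data$logfc)), .data$gene)
}

#' PSP-to-QSC reprogramming index
#'
#' Quantifies how far post-treatment PSP cells have moved toward the
#' pre-treatment QSC centroid: expression is restricted to a
#' differential-gene list, z-scaled with pooled pre-treatment statistics,
#' and `R = d(post-PSP, pre-PSP) / (d(post-PSP, pre-PSP) + d(post-PSP,
#' pre-QSC))` with Euclidean centroid distances. `R` is 0 when post-PSP
#' equals pre-PSP and tends to 1 as it reaches pre-QSC.
#'
#' @param norm_pre_qsc,norm_pre_psp,norm_post_psp genes x cells
#'   log-normalized matrices for the three groups (>= 3 cells each).
#' @param de_genes nonempty differential-gene list.
#' @return a `reprogramming_index` list: `R`, `centroids` (3 x genes
#'   matrix in z-space), `de_genes`, `pca` (2-PC coordinates of all cells
#'   for plotting).
#' @export
reprogramming_index <- function(norm_pre_qsc, norm_pre_psp, norm_post_psp, de_genes) {
  if (length(de_genes) == 0) abort_ls("de_genes must be nonempty")
  for (m in list(norm_pre_qsc, norm_pre_psp, norm_post_psp)) {
    if (ncol(m) < 3) abort_ls("each group needs at least 3 cells")
  }
  genes <- Reduce(intersect, list(de_genes, rownames(norm_pre_qsc),
                                  rownames(norm_pre_psp), rownames(norm_post_psp)))
  if (length(genes) == 0) abort_ls("no de_genes present in all groups")
  pre <- cbind(norm_pre_qsc[genes, , drop = FALSE], norm_pre_psp[genes, , drop = FALSE])
  mu <- Matrix::rowMeans(pre)
  sdv <- sqrt(pmax(Matrix::rowMeans(pre^2) - mu^2, 0))
  sdv[sdv == 0] <- 1
  zc <- function(m) (as.matrix(Matrix::rowMeans(m[genes, , drop = FALSE])) - mu) / sdv
  c_q <- zc(norm_pre_qsc); c_p <- zc(norm_pre_psp); c_x <- zc(norm_post_psp)
  d_qp <- sqrt(sum((c_q - c_p)^2))
  if (d_qp < 1e-12) abort_ls("pre-QSC and pre-PSP centroids coincide; axis undefined")
  d_xp <- sqrt(sum((c_x - c_p)^2)); d_xq <- sqrt(sum((c_x - c_q)^2))
  R <- d_xp / (d_xp + d_xq)
  all_z <- (as.matrix(cbind(norm_pre_qsc[genes, , drop = FALSE],
                            norm_pre_psp[genes, , drop = FALSE],
                            norm_post_psp[genes, , drop = FALSE])) - mu) / sdv
  pc <- stats::prcomp(Matrix::t(all_z), rank. = 2)
  grp <- c(rep("pre-QSC", ncol(norm_pre_qsc)), rep("pre-PSP", ncol(norm_pre_psp)),
           rep("post-PSP", ncol(norm_post_psp)))
  structure(list(R = R,
                 centroids = rbind(`pre-QSC` = c_q[, 1], `pre-PSP` = c_p[, 1],
                                   `post-PSP` = c_x[, 1]),
                 de_genes = genes,
                 pca = tibble::tibble(group = grp, PC1 = pc$x[, 1], PC2 = pc$x[, 2])),
            class = "reprogramming_index")
}

#' @export
print.reprogramming_index <- function(x, ...) {
  cat("Reprogramming index R =", format(x$R, digits = 4),
      "over", length(x$de_genes), "genes\n")
  invisible(x)
}
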