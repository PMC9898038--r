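#' Ligand-receptor interaction scoring with a permutation null
#'
#' For every (pair, sender state, receiver state) combination where both
#' genes are present and expressed in at least `min_frac` of the relevant
#' cells, the score is the mean of means: `(mean ligand expression in
#' sender + mean receptor expression in receiver) / 2`. The null
#' distribution is built by permuting state labels across all cells
#' `n_perm` times; `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param states per-cell state labels (vector or `cell_id`/`state`
#'   tibble).
#' @param pairs tibble with columns `ligand`, `receptor` (e.g.
#'   [default_lr_pairs()]).
#' @param min_frac minimum expressing-cell fraction on both sides.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @param senders,receivers optional restriction of the state combinations.
#' @return tibble: `ligand`, `receptor`, `sender`, `receiver`,
#'   `mean_score`, `expr_frac_sender`, `expr_frac_receiver`, `p_perm`,
#'   `n_perm`, class `lr_result`.
#' @export
score_lr <- function(normalized, states, pairs, min_frac = 0.1,
                     n_perm = 1000, seed = 1L, senders = NULL, receivers = NULL) {
  if (n_perm < 100) abort_ls("n_perm must be at least 100 for a stable p-value")
  if (nrow(pairs) == 0) abort_ls("pair table is empty")
  lab <- state_labels_for(normalized, states)
  keep <- !is.na(lab)
  lab <- lab[keep]
  sts <- sort(unique(lab))
  genes <- unique(c(pairs$ligand, pairs$receptor))
  genes <- intersect(genes, rownames(normalized))
  x <- as.matrix(normalized[genes, keep, drop = FALSE])
  ind <- sparseMatrix(i = seq_along(lab), j = match(lab, sts), x = 1,
                      dims = c(length(lab), length(sts)))
  sizes <- Matrix::colSums(ind)
  means_for <- function(indicator) {
    m <- (x %*% indicator) %*% Matrix::Diagonal(x = 1 / sizes)
    as.matrix(m)
  }
  obs_mean <- means_for(ind)
  obs_frac <- as.matrix(((x > 0) %*% ind) %*% Matrix::Diagonal(x = 1 / sizes))
  colnames(obs_mean) <- colnames(obs_frac) <- sts

  senders <- senders %||% sts; receivers <- receivers %||% sts
  combos <- tidyr::expand_grid(pair = seq_len(nrow(pairs)),
                               sender = senders, receiver = receivers) |>
    dplyr::mutate(ligand = pairs$ligand[.data$pair],
                  receptor = pairs$receptor[.data$pair]) |>
    dplyr::filter(.data$ligand %in% genes, .data$receptor %in% genes)
  if (nrow(combos) == 0) return(empty_lr())
  li <- match(combos$ligand, genes); ri <- match(combos$receptor, genes)
  si <- match(combos$sender, sts); ci <- match(combos$receiver, sts)
  combos$expr_frac_sender <- obs_frac[cbind(li, si)]
  combos$expr_frac_receiver <- obs_frac[cbind(ri, ci)]
  combos <- dplyr::filter(combos, .data$expr_frac_sender >= min_frac,
                          .data$expr_frac_receiver >= min_frac)
  if (nrow(combos) == 0) return(empty_lr())
  li <- match(combos$ligand, genes); ri <- match(combos$receptor, genes)
  si <- match(combos$sender, sts); ci <- match(combos$receiver, sts)
  obs <- (obs_mean[cbind(li, si)] + obs_mean[cbind(ri, ci)]) / 2

  set.seed(seed)
  ge <- integer(nrow(combos))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(length(lab))
    m <- means_for(ind[perm, , drop = FALSE])
    null <- (m[cbind(li, si)] + m[cbind(ri, ci)]) / 2
    ge <- ge + (null >= obs)
  }
  out <- tibble::tibble(ligand = combos$ligand, receptor = combos$receptor,
                        sender = combos$sender, receiver = combos$receiver,
                        mean_score = obs,
                        expr_frac_sender = combos$expr_frac_sender,
                        expr_frac_receiver = combos$expr_frac_receiver,
                        p_perm = (1 + ge) / (n_perm + 1), n_perm = n_perm)
  class(out) <- c("lr_result", class(out))
  out
}

empty_lr <- function() {
  out <- tibble::tibble(ligand = character(), receptor = character(),
                        sender = character(), receiver = character(),
                        mean_score = numeric(), expr_frac_sender = numeric(),
                        expr_frac_receiver = numeric(), p_perm = numeric(),
                        n_perm = integer())
  class(out) <- c("lr_result", class(out))
  out
}
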