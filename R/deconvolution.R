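#' Build a state signature matrix from labeled single cells
#'
#' Per state, a one-vs-rest Wilcoxon test over all genes selects candidates
#' with BH-FDR `<= max_fdr` and positive log-fold-change; candidates
#' significant in more than one state (e.g. a shared proliferation
#' program) are dropped as non-discriminating, the remaining genes are
#' ranked by log-fold-change and the `top_m` per state kept, and the
#' signature entries are the per-state mean linear-scale expression
#' (`expm1` of log-normalized values) over the union of the kept genes.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param states per-cell state labels (vector or `cell_id`/`state` tibble).
#' @param top_m markers kept per state.
#' @param max_fdr FDR cutoff for candidate markers.
#' @return a `signature_matrix`: genes x states numeric matrix with a
#'   `"markers"` attribute (tibble `state`, `gene`, `logfc`, `fdr`).
#' @export
build_signature <- function(normalized, states, top_m = 50, max_fdr = 0.05) {
  lab <- state_labels_for(normalized, states)
  keep <- !is.na(lab)
  x <- normalized[, keep, drop = FALSE]
  lab <- lab[keep]
  sts <- sort(unique(lab))
  if (sum(table(lab) >= 3) < 2) abort_ls("need at least 2 states with >= 3 cells")
  sel <- list()
  for (s in sts) {
    idx1 <- which(lab == s)
    if (length(idx1) < 3) next
    tab <- wilcox_matrix(x, idx1, which(lab != s))
    tab$fdr <- p.adjust(tab$p, "BH")
    tab <- dplyr::filter(tab, .data$fdr <= max_fdr, .data$logfc > 0) |>
      dplyr::arrange(dplyr::desc(.data$logfc), .data$gene)
    if (nrow(tab) == 0) {
      abort_ls("state ", s, " yields no significant marker genes; ",
               "lower stringency (max_fdr) or provide more cells")
    }
    sel[[s]] <- dplyr::mutate(tab, state = s)
  }
  cand <- dplyr::bind_rows(sel)
  shared_genes <- unique(cand$gene[duplicated(cand$gene)])
  markers <- cand |>
    dplyr::filter(!.data$gene %in% shared_genes) |>
    dplyr::group_by(.data$state) |>
    dplyr::slice_head(n = top_m) |>
    dplyr::ungroup()
  if (nrow(markers) == 0) abort_ls("no state-specific marker genes survive selection")
  if (any(!sts %in% markers$state)) {
    abort_ls("state ", paste(setdiff(sts, markers$state), collapse = ", "),
             " yields no state-specific marker genes; lower stringency")
  }
  genes <- sort(unique(markers$gene))
  lin <- x[genes, , drop = FALSE]
  lin@x <- expm1(lin@x)
  sig <- vapply(sts, function(s) {
    as.numeric(Matrix::rowMeans(lin[, lab == s, drop = FALSE]))
  }, numeric(length(genes)))
  rownames(sig) <- genes
  attr(sig, "markers") <- markers[, c("state", "gene", "logfc", "fdr")]
  class(sig) <- c("signature_matrix", class(sig))
  sig
}

#' Deconvolve bulk profiles against a signature matrix
#'
#' Each bulk sample is scaled to the signature's overall magnitude over the
#' shared genes, the mixing weights are solved by non-negative least
#' squares on relative errors (every gene's row is scaled by the inverse of
#' the observed bulk value, floored at its 5th positive percentile — the
#' GLS weighting for multiplicative noise, which stops a handful of
#' high-expression genes from dominating the fit), and the coefficients are
#' renormalized to sum to 1. The signature columns stay on their native
#' per-state expression scale, so a noiseless mixture
#' `0.7 * col1 + 0.3 * col2` is recovered as exactly (0.7, 0.3).
#' Proportions are invariant to positive rescaling of the bulk sample.
#'
#' @param bulk samples x genes matrix (or a single named vector).
#' @param sig a `signature_matrix` (genes x states).
#' @return tibble: `sample`, one `p_<state>` column per state, `residual`
#'   (relative least-squares residual norm), class `deconvolution_result`.
#' @export
deconvolve <- function(bulk, sig) {
  if (is.null(dim(bulk))) bulk <- matrix(bulk, nrow = 1, dimnames = list("bulk1", names(bulk)))
  bulk <- as.matrix(bulk)
  shared <- intersect(colnames(bulk), rownames(sig))
  if (length(shared) == 0) abort_ls("bulk and signature share no genes")
  if (length(shared) < 0.5 * nrow(sig)) {
    warning("fewer than 50% of signature genes present in bulk data")
  }
  a <- unclass(sig)[shared, , drop = FALSE]
  target <- sum(a) / ncol(a)
  res <- lapply(seq_len(nrow(bulk)), function(i) {
    b <- bulk[i, shared]
    if (all(b == 0)) abort_ls("bulk sample ", rownames(bulk)[i], " is all zero")
    b <- b / sum(b) * target
    w <- 1 / pmax(b, quantile(b[b > 0], 0.05))
    fit <- pracma::lsqnonneg(a * w, b * w)
    x <- fit$x
    if (sum(x) == 0) x <- rep(1 / length(x), length(x))
    p <- x / sum(x)
    resid <- sqrt(sum((w * (b - a %*% x))^2)) / sqrt(sum((w * b)^2))
    c(p, resid)
  })
  m <- do.call(rbind, res)
  out <- tibble::tibble(sample = rownames(bulk) %||% sprintf("bulk%03d", seq_len(nrow(bulk))))
  states <- colnames(sig)
  for (j in seq_along(states)) out[[paste0("p_", states[j])]] <- m[, j]
  out$residual <- m[, ncol(m)]
  class(out) <- c("deconvolution_result", class(out))
  out
}

#' Paired test for a state's proportion shift
#'
#' Wilcoxon signed-rank test on matched per-sample differences of one
#' state's proportion (exact distribution for `n <= 25` pairs when there
#' are no ties or zeros, normal approximation otherwise). All-zero
#' differences carry no information and are flagged rather than tested.
#'
#' @param pre,post numeric proportions for matched samples, same order.
#' @param state label used in the output (informational).
#' @return list: `statistic`, `p`, `n_pairs`, `state`, `note`.
#' @export
paired_shift_test <- function(pre, post, state = "state") {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  if (length(d) < 5) warning("fewer than 5 pairs: low power")
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = 1, n_pairs = length(d), state = state,
                note = "no-information: all paired differences are zero"))
  }
  ex <- length(d) <= 25 && !any(d == 0) && !anyDuplicated(abs(d))
  ht <- wilcox.test(post, pre, paired = TRUE, exact = ex, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value, n_pairs = length(d),
       state = state, note = NULL)
}
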