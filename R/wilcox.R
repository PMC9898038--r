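# Row-wise two-group Wilcoxon rank-sum test (normal approximation with
# continuity and tie correction), plus mean log-expression difference.
# Shared by surface-marker discovery, signature building and per-state DE.
wilcox_matrix <- function(x, idx1, idx2) {
  x <- x[, c(idx1, idx2), drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  if (n1 < 1 || n2 < 1) abort_ls("both groups must be nonempty")
  xd <- as.matrix(x)
  p <- numeric(nrow(xd)); lfc <- numeric(nrow(xd))
  g1 <- seq_len(n1)
  for (i in seq_len(nrow(xd))) {
    v <- xd[i, ]
    r <- rank(v)
    w <- sum(r[g1]) - n1 * (n1 + 1) / 2
    tie <- rle(sort(v))$lengths
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sig2 <= 0) { p[i] <- 1 } else {
      z <- w - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sig2)
      p[i] <- 2 * pnorm(-abs(z))
    }
    lfc[i] <- mean(v[g1]) - mean(v[-g1])
  }
  tibble::tibble(gene = rownames(x) %||% as.character(seq_len(nrow(xd))),
                 logfc = lfc, p = p)
}
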