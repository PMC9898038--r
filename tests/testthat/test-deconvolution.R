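test_that("signature recovers planted marker programs", {
  ls <- leukemia_subset()
  fix <- small_cohort()
  sig <- build_signature(ls$norm, ls$states)
  markers <- attr(sig, "markers")
  st <- fix$cfg$states
  for (s in c("QSC", "GMP", "mono")) {
    planted <- fix$cfg$layout$gene_names[st$marker_genes[[match(s, st$name)]]]
    found <- markers$gene[markers$state == s]
    expect_gte(mean(planted %in% found), 0.9)
  }
  expect_true(all(sig >= 0))
})

test_that("two identical states give no discriminating genes", {
  set.seed(3)
  m <- Matrix::Matrix(matrix(rpois(100 * 40, 3), 100, 40), sparse = TRUE)
  rownames(m) <- sprintf("g%03d", 1:100); colnames(m) <- sprintf("c%03d", 1:40)
  st <- tibble::tibble(cell_id = colnames(m), state = rep(c("A", "B"), 20))
  expect_error(build_signature(normalize_log(m), st), "no significant")
})

test_that("signature is invariant to cell order", {
  ls <- leukemia_subset()
  sig1 <- build_signature(ls$norm, ls$states)
  set.seed(2); perm <- sample(ncol(ls$norm))
  sig2 <- build_signature(ls$norm[, perm], ls$states)
  expect_equal(unclass(sig1), unclass(sig2))
})

test_that("deconvolution is exact on pure and noiseless mixed profiles", {
  ls <- leukemia_subset()
  sig <- build_signature(ls$norm, ls$states)
  k <- ncol(sig)
  pure <- deconvolve(t(sig[, 1]), sig)
  p <- unlist(pure[1, paste0("p_", colnames(sig))])
  expect_equal(unname(p), c(1, rep(0, k - 1)), tolerance = 1e-8)
  expect_lt(pure$residual, 1e-8)
  mix <- 0.7 * sig[, 1] + 0.3 * sig[, 2]
  est <- deconvolve(t(mix), sig)
  p2 <- unname(unlist(est[1, paste0("p_", colnames(sig))]))
  expect_equal(p2, c(0.7, 0.3, rep(0, k - 2)), tolerance = 1e-6)
})

test_that("proportions are invariant to positive rescaling of the bulk", {
  ls <- leukemia_subset()
  sig <- build_signature(ls$norm, ls$states)
  mix <- 0.4 * sig[, 1] + 0.6 * sig[, 3]
  a <- deconvolve(t(mix), sig)
  b <- deconvolve(t(137.5 * mix), sig)
  expect_equal(as.data.frame(a[, -1]), as.data.frame(b[, -1]), tolerance = 1e-10)
})

test_that("NNLS matches an exhaustive simplex grid search on small problems", {
  set.seed(6)
  for (rep in 1:3) {
    a <- matrix(rexp(6 * 3, 0.2), 6, 3,
                dimnames = list(sprintf("g%d", 1:6), c("A", "B", "C")))
    p_true <- c(0.55, 0.3, 0.15)
    b <- as.numeric(a %*% p_true) * exp(rnorm(6, 0, 0.05))
    class(a) <- c("signature_matrix", class(a))
    est <- deconvolve(t(`names<-`(b, rownames(a))), a)
    p_hat <- unname(unlist(est[1, c("p_A", "p_B", "p_C")]))
    # brute-force grid over the simplex, step 0.001, on the same
    # relative-error objective the solver uses
    step <- 0.001
    p1 <- seq(0, 1, step)
    best <- c(Inf, 0, 0, 0)
    a0 <- unclass(a)
    bn <- b / sum(b) * sum(a0) / ncol(a0)
    wt <- 1 / pmax(bn, quantile(bn[bn > 0], 0.05))
    bs <- bn * wt
    as <- a0 * wt
    for (x in p1) {
      y <- seq(0, 1 - x, step)
      r <- as[, 1] %o% rep(x, length(y)) + as[, 2] %o% y +
        as[, 3] %o% (1 - x - y)
      # scale-free comparison: project each candidate onto b
      sc <- colSums(r * bs) / colSums(r * r)
      err <- colSums((bs - sweep(r, 2, sc, "*"))^2)
      j <- which.min(err)
      if (err[j] < best[1]) best <- c(err[j], x, y[j], 1 - x - y[j])
    }
    expect_true(all(abs(p_hat - best[2:4]) <= 0.002 + 1e-9))
  }
})

test_that("adding an absent state's column barely shifts recovered proportions", {
  ls <- leukemia_subset()
  sig <- build_signature(ls$norm, ls$states)
  mix <- 0.5 * sig[, "QSC"] + 0.5 * sig[, "mono"]
  small_sig <- sig[, c("QSC", "mono")]
  class(small_sig) <- c("signature_matrix", class(small_sig))
  a <- deconvolve(t(mix), small_sig)
  b <- deconvolve(t(mix), sig)
  expect_lt(abs(a$p_QSC - b$p_QSC), 0.02)
  expect_lt(abs(a$p_mono - b$p_mono), 0.02)
})

test_that("noisy synthetic mixtures are recovered accurately", {
  ls <- leukemia_subset()
  sig <- build_signature(ls$norm, ls$states)
  prof <- empirical_state_profiles(ls$norm, ls$states)[, colnames(sig)]
  set.seed(4)
  P <- t(vapply(1:50, function(i) { x <- rgamma(6, 2); x / sum(x) }, numeric(6)))
  colnames(P) <- colnames(sig)
  bulk <- simulate_bulk_mixtures(prof, P, noise_sd = 0.1, seed = 9)
  est <- deconvolve(bulk, sig)
  E <- as.matrix(est[, paste0("p_", colnames(sig))])
  expect_lt(sqrt(mean((E - P)^2)), 0.05)
  # signature from ~70 cells/state; the full-cohort run holds r > 0.95
  for (j in seq_len(ncol(P))) expect_gt(cor(E[, j], P[, j]), 0.8)
})

test_that("paired shift test handles null, planted and sign-flipped inputs", {
  x <- c(0.1, 0.2, 0.15, 0.3, 0.25, 0.12)
  same <- paired_shift_test(x, x, "QSC")
  expect_equal(same$p, 1)
  expect_match(same$note, "no-information")
  set.seed(7)
  pre <- runif(12, 0.1, 0.3); post <- pre + 0.1 + rnorm(12, 0, 0.01)
  up <- paired_shift_test(pre, post, "QSC")
  expect_lt(up$p, 0.01)
  flip <- paired_shift_test(-pre, -post, "QSC")
  expect_equal(up$p, flip$p)
  expect_warning(paired_shift_test(pre[1:3], post[1:3]), "low power")
})
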