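#' Derive a per-stage seed from a global seed
#'
#' Each pipeline stage draws its own seed so that enabling or disabling an
#' optional downstream stage never perturbs the random stream of an earlier
#' one. The derivation is a polynomial string hash of the stage name folded
#' into the global seed, reduced modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1L, "cluster")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer(h)
}

`%||%` <- rlang::`%||%`

# stop() with a consistent prefix; cheap glue-free interpolation
abort_ls <- function(...) stop(paste0(...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort_ls(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}

# rank-scale a numeric vector to [0, 1]; all-tied input maps to 0.5
rank_scale01 <- function(x) {
  n <- length(x)
  if (n == 1L) return(0.5)
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) return(rep(0.5, n))
  (r - 1) / (n - 1)
}

# largest-remainder apportionment of n items to proportions p (sums to 1)
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, seq_along(p), decreasing = c(TRUE, FALSE), method = "radix")
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}
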