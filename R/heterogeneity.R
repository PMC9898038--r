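#' Per-sample cellular-state composition with Shannon-entropy ITH
#'
#' Computes each sample's proportion vector over the six leukemia states
#' from its assigned leukemia-like cells, and the Shannon entropy (base 2)
#' of that vector as the intratumoral-heterogeneity (ITH) score. Samples
#' without leukemia-like cells are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param states tibble of per-cell assignments with columns `cell_id`,
#'   `state` (from [assign_states()]).
#' @param sample_ids per-cell sample ids aligned with `states` rows, or a
#'   tibble with `cell_id`, `sample` to join on.
#' @param state_levels the state universe defining the composition vector.
#' @param normalize_entropy divide ITH by `log2(#states)` if `TRUE`.
#' @return tibble: `sample`, one `p_<state>` column per state,
#'   `n_leukemia_cells`, `ith`.
#' @export
composition <- function(states, sample_ids,
                        state_levels = c("QSC", "PSP", "GMP", "PG", "promono", "mono"),
                        normalize_entropy = FALSE) {
  df <- tibble::as_tibble(states)
  if (is.data.frame(sample_ids)) {
    df <- dplyr::left_join(df, sample_ids[, c("cell_id", "sample")], by = "cell_id")
  } else {
    stopifnot(length(sample_ids) == nrow(df))
    df$sample <- sample_ids
  }
  df <- dplyr::filter(df, .data$state %in% state_levels)
  counts <- df |>
    dplyr::count(.data$sample, state = factor(.data$state, levels = state_levels),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n", values_fill = 0)
  out <- counts |>
    dplyr::mutate(n_leukemia_cells = rowSums(dplyr::pick(dplyr::all_of(state_levels))))
  excluded <- out$sample[out$n_leukemia_cells == 0]
  out <- dplyr::filter(out, .data$n_leukemia_cells > 0)
  pm <- as.matrix(out[, state_levels]) / out$n_leukemia_cells
  out[, state_levels] <- pm
  names(out)[match(state_levels, names(out))] <- paste0("p_", state_levels)
  out$ith <- apply(pm, 1, shannon_ith)
  if (normalize_entropy) out$ith <- out$ith / log2(length(state_levels))
  attr(out, "excluded") <- excluded
  out
}

#' Shannon-entropy intratumoral heterogeneity
#'
#' `H = -sum p_k log2 p_k` with the convention `0 * log2(0) = 0`.
#'
#' @param p probability vector (nonnegative, sums to 1 within 1e-6).
#' @return entropy in bits; between 0 (degenerate) and `log2(length(p))`
#'   (uniform).
#' @export
#' @examples
#' shannon_ith(rep(1 / 6, 6))   # log2(6)
#' shannon_ith(c(0.5, 0.25, 0.25, 0, 0, 0))   # 1.5
shannon_ith <- function(p) {
  if (any(p < 0)) abort_ls("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6) abort_ls("proportions must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Median split of per-sample values into High and Low groups
#'
#' Values strictly above the median go to `"High"`, ties and below to
#' `"Low"`. Degenerate inputs (all equal, or an empty group) are an error.
#'
#' @param values numeric vector (>= 2 values).
#' @return character vector of `"High"`/`"Low"`, same length and names.
#' @export
median_split <- function(values) {
  if (length(values) < 2) abort_ls("need at least 2 samples to split")
  m <- median(values)
  g <- ifelse(values > m, "High", "Low")
  if (length(unique(g)) < 2) abort_ls("degenerate split: all values on one side of the median")
  setNames(g, names(values))
}

#' Two-variable median cross-split
#'
#' Crosses the median splits of two per-sample variables, e.g. to contrast
#' QSC-high/PSP-low with QSC-low/PSP-high samples.
#'
#' @param a,b numeric vectors of equal length.
#' @param labels names of the two variables, used in the group label.
#' @return character vector like `"QSC_High.PSP_Low"`.
#' @export
median_cross_split <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) == length(b))
  paste0(labels[1], "_", median_split(a), ".", labels[2], "_", median_split(b))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator via [survival::survfit()], returned as a tidy
#' step table. With no events the curve is flat at 1 (with a warning).
#'
#' @param table data frame with columns `time`, `event` and optionally
#'   `group`.
#' @return a `km_fit`: tibble with `group`, `time`, `n_risk`, `n_event`,
#'   `surv`; the underlying `survfit` is kept in attribute `"fit"`.
#' @export
km_estimate <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("time", "event") %in% names(table)))
  if (any(table$time <= 0)) abort_ls("times must be positive")
  if (!all(table$event %in% c(0, 1))) abort_ls("event must be 0/1")
  if (sum(table$event) == 0) warning("no events: survival curve is flat at 1")
  if (!"group" %in% names(table)) table$group <- "all"
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = table)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  out <- tibble::tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                        n_event = sm$n.event, surv = sm$surv)
  attr(out, "fit") <- fit
  class(out) <- c("km_fit", class(out))
  out
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a `km_fit` from [km_estimate()].
#' @param t time at which to evaluate.
#' @param group group label (default the first).
#' @return the estimated survival probability at `t`.
#' @export
km_surv_at <- function(km, t, group = km$group[1]) {
  steps <- dplyr::filter(km, .data$group == !!group, .data$time <= t, .data$n_event > 0)
  if (nrow(steps) == 0) return(1)
  min(steps$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square via [survival::survdiff()]:
#' `chi2 = (sum O - E)^2 / V`, p from a 1-df chi-square.
#'
#' @param table data frame with `time`, `event`, `group` (two levels).
#' @return a `logrank_test` list: `chi2`, `p`, `n`, `groups`.
#' @export
logrank_test <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("time", "event", "group") %in% names(table)))
  groups <- unique(table$group)
  if (length(groups) != 2) abort_ls("exactly two groups required")
  if (sum(table$event) == 0) abort_ls("no events: log-rank variance is zero")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = table)
  chi2 <- unname(sd$chisq)
  structure(list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 n = nrow(table), groups = sort(as.character(groups))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi2 =", format(x$chi2, digits = 4),
      " p =", format(x$p, digits = 4), " (n =", x$n, ")\n")
  invisible(x)
}
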