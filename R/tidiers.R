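#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a log-rank test
#' @param x a `logrank_test`.
#' @param ... unused.
#' @return one-row tibble with `statistic`, `p.value`, `df`, `n`.
#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, p.value = x$p, df = 1, n = x$n)
}

#' @rdname tidy.logrank_test
#' @export
glance.logrank_test <- function(x, ...) tidy.logrank_test(x)

#' Tidy a malignancy call into its per-cluster table
#' @param x a `malignancy_call`.
#' @param ... unused.
#' @return the per-cluster tibble.
#' @export
tidy.malignancy_call <- function(x, ...) x$clusters

#' One-row summary of a malignancy call
#' @param x a `malignancy_call`.
#' @param ... unused.
#' @return tibble with cluster counts and the global AML fraction.
#' @export
glance.malignancy_call <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_leukemia_clusters = sum(x$clusters$call == "leukemia-like"),
                 global_aml_fraction = x$global_aml_fraction,
                 theta_high = x$theta_high)
}

#' Tidy a reprogramming index into its PCA coordinates
#' @param x a `reprogramming_index`.
#' @param ... unused.
#' @return per-cell tibble `group`, `PC1`, `PC2`.
#' @export
tidy.reprogramming_index <- function(x, ...) x$pca

#' One-row summary of a reprogramming index
#' @param x a `reprogramming_index`.
#' @param ... unused.
#' @return tibble with `R` and the gene count used.
#' @export
glance.reprogramming_index <- function(x, ...) {
  tibble::tibble(R = x$R, n_genes = length(x$de_genes))
}

#' Tidy a shift table
#' @param x a `shift_table`.
#' @param ... unused.
#' @return the per-state proportions tibble.
#' @export
tidy.shift_table <- function(x, ...) x$proportions
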