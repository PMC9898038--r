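#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_step geom_col
#'   geom_point scale_fill_gradient2 labs theme_minimal
NULL

#' Plot a condition density-ratio grid
#'
#' Tile map of the per-bin log2 AML/HC density ratio.
#'
#' @param object a `density_grid` from [density_ratio_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.density_grid <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, fill = .data$log2_ratio)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "grey95", high = "#B2182B") +
    labs(x = "embedding 1", y = "embedding 2",
         fill = "log2 AML/HC density") +
    theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object a `km_fit` from [km_estimate()].
#' @param ... unused.
#' @return a ggplot of the per-group step functions.
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- dplyr::distinct(object, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  df <- dplyr::bind_rows(start, object[, c("group", "time", "surv")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability", colour = NULL) +
    theme_minimal()
}

#' Stacked state-composition bars per sample
#'
#' @param comp a composition tibble from [composition()].
#' @return a ggplot.
#' @export
plot_composition <- function(comp) {
  long <- comp |>
    dplyr::select("sample", dplyr::starts_with("p_")) |>
    tidyr::pivot_longer(-"sample", names_to = "state", values_to = "proportion",
                        names_prefix = "p_")
  ggplot(long, aes(x = .data$sample, y = .data$proportion, fill = .data$state)) +
    geom_col() +
    labs(x = NULL, y = "proportion of leukemia-like cells", fill = "state") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bubble plot of ligand-receptor interaction scores
#'
#' @param object an `lr_result` from [score_lr()].
#' @param ... unused.
#' @return a ggplot; point size is the mean score, colour the permutation
#'   p-value.
#' @export
autoplot.lr_result <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pair = paste(.data$ligand, .data$receptor, sep = "-"),
                      combo = paste(.data$sender, .data$receiver, sep = " → "))
  ggplot(df, aes(x = .data$combo, y = .data$pair,
                 size = .data$mean_score, colour = -log10(.data$p_perm))) +
    geom_point() +
    labs(x = "sender → receiver", y = NULL,
         colour = "-log10 p", size = "mean score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
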