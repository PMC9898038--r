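#' Call leukemia-like vs normal-like cells from cluster composition
#'
#' A cluster is leukemia-like when its fraction of AML-patient cells
#' `f_k` reaches `theta_high` (default 0.9), or, in `mode = "enrichment"`,
#' when `f_k / global AML fraction >= rho`. AML-patient cells inherit their
#' cluster's call; healthy-control cells are never labeled leukemia-like
#' regardless of the cluster they sit in.
#'
#' @param clusters a `cluster_result` from [cluster_cells()] or an integer
#'   vector of per-cell cluster labels.
#' @param meta per-cell metadata with columns `cell_id`, `sample`,
#'   `condition`, `patient` (same order as the labels).
#' @param theta_high AML-fraction threshold for the leukemia-like call.
#' @param mode `"threshold"` or `"enrichment"`.
#' @param rho enrichment ratio used when `mode = "enrichment"`.
#' @return a `malignancy_call` list: `clusters` (per-cluster tibble with
#'   `cluster`, `n_cells`, `n_aml_cells`, `aml_fraction`, `call`), `cells`
#'   (per-cell tibble with `cell_id`, `cluster`, `call`), `per_patient`
#'   (AML patients' predicted leukemia-like percentage) and
#'   `global_aml_fraction`.
#' @export
classify_clusters <- function(clusters, meta, theta_high = 0.9,
                              mode = c("threshold", "enrichment"), rho = 2) {
  mode <- match.arg(mode)
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else clusters
  meta <- tibble::as_tibble(meta)
  if (!"condition" %in% names(meta)) abort_ls("meta must contain a condition column")
  if (length(labels) != nrow(meta)) abort_ls("labels and meta disagree in length")
  if (!any(meta$condition == "AML")) abort_ls("no AML cells present")
  assert_prob(theta_high, "theta_high")
  global_aml <- mean(meta$condition == "AML")
  per_cluster <- tibble::tibble(cluster = labels, is_aml = meta$condition == "AML") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(), n_aml_cells = sum(.data$is_aml),
                     .groups = "drop") |>
    dplyr::mutate(aml_fraction = .data$n_aml_cells / .data$n_cells,
                  call = dplyr::if_else(
                    if (mode == "threshold") .data$aml_fraction >= theta_high
                    else .data$aml_fraction / global_aml >= rho,
                    "leukemia-like", "normal-like")) |>
    dplyr::arrange(.data$cluster)
  cell_call <- per_cluster$call[match(labels, per_cluster$cluster)]
  cell_call[meta$condition == "HC"] <- "normal-like"
  cells <- tibble::tibble(cell_id = meta$cell_id, cluster = labels,
                          condition = meta$condition, call = cell_call)
  per_patient <- cells |>
    dplyr::mutate(patient = meta$patient) |>
    dplyr::filter(.data$condition == "AML") |>
    dplyr::group_by(.data$patient) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     leukemia_pct = 100 * mean(.data$call == "leukemia-like"),
                     .groups = "drop")
  structure(list(clusters = per_cluster, cells = cells, per_patient = per_patient,
                 global_aml_fraction = global_aml, theta_high = theta_high,
                 mode = mode),
            class = "malignancy_call")
}

#' Condition density-ratio map on a binned 2D embedding
#'
#' Splits the joint bounding box of the embedding into a `B x B` grid
#' (default 400), normalizes each condition's bin counts to densities
#' summing to 1, and reports `log2((d_AML + eps) / (d_HC + eps))` per bin.
#' Bins are half-open `[lo, hi)` except the last, which is closed.
#'
#' @param embedding2d cells x 2 coordinate matrix.
#' @param condition per-cell factor with levels `"HC"`/`"AML"`.
#' @param B bins per axis (>= 2).
#' @param eps pseudocount; default `1 / max(condition totals)`.
#' @return a tibble of occupied bins (`bin_x`, `bin_y`, `x`, `y` bin
#'   centers, `n_aml`, `n_hc`, `log2_ratio`), class `density_grid`, with
#'   attributes `B` and `eps`.
#' @export
density_ratio_map <- function(embedding2d, condition, B = 400, eps = NULL) {
  if (B < 2) abort_ls("B must be at least 2")
  embedding2d <- as.matrix(embedding2d)
  stopifnot(ncol(embedding2d) == 2, nrow(embedding2d) == length(condition))
  n_aml_tot <- sum(condition == "AML"); n_hc_tot <- sum(condition == "HC")
  if (n_aml_tot == 0 || n_hc_tot == 0) abort_ls("need at least one cell per condition")
  eps <- eps %||% (1 / max(n_aml_tot, n_hc_tot))
  bin_axis <- function(v) {
    br <- seq(min(v), max(v), length.out = B + 1)
    i <- findInterval(v, br, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), B)
  }
  bx <- bin_axis(embedding2d[, 1]); by <- bin_axis(embedding2d[, 2])
  key <- (bx - 1L) * B + by
  tab <- tibble::tibble(key = key, is_aml = condition == "AML") |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_aml = sum(.data$is_aml), n_hc = sum(!.data$is_aml),
                     .groups = "drop")
  xr <- range(embedding2d[, 1]); yr <- range(embedding2d[, 2])
  cx <- function(i) xr[1] + (i - 0.5) * diff(xr) / B
  cy <- function(i) yr[1] + (i - 0.5) * diff(yr) / B
  out <- tab |>
    dplyr::mutate(bin_x = (.data$key - 1L) %/% B + 1L,
                  bin_y = (.data$key - 1L) %% B + 1L,
                  x = cx(.data$bin_x), y = cy(.data$bin_y),
                  log2_ratio = log2((.data$n_aml / n_aml_tot + eps) /
                                    (.data$n_hc / n_hc_tot + eps))) |>
    dplyr::select("bin_x", "bin_y", "x", "y", "n_aml", "n_hc", "log2_ratio")
  attr(out, "B") <- B
  attr(out, "eps") <- eps
  class(out) <- c("density_grid", class(out))
  out
}
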