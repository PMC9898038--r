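#' Score all per-cell quantities needed for state assignment
#'
#' Convenience wrapper computing the proliferation score, S/G2M scores and
#' phase, stemness, and one module score per lineage program.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param embedding an `embedding_result` (for stemness smoothing).
#' @param programs named list of lineage gene sets
#'   (`stem`, `GMP`, `granulocyte`, `promono`, `mono`).
#' @param cycle_sets list with `S` and `G2M` gene sets.
#' @param proliferation_set proliferation gene program.
#' @param seed integer seed for control-gene sampling.
#' @return tibble with `cell_id`, `proliferation`, `s_score`, `g2m_score`,
#'   `phase`, `stemness`, and one column per lineage program.
#' @export
score_cells <- function(normalized, embedding, programs, cycle_sets,
                        proliferation_set, seed = 1L) {
  out <- tibble::tibble(
    cell_id = colnames(normalized),
    proliferation = module_score(normalized, proliferation_set,
                                 seed = stage_seed(seed, "proliferation")),
    s_score = module_score(normalized, cycle_sets$S, seed = stage_seed(seed, "S")),
    g2m_score = module_score(normalized, cycle_sets$G2M, seed = stage_seed(seed, "G2M")),
    stemness = stemness_score(normalized, embedding)
  )
  out$phase <- cycle_phase(out$s_score, out$g2m_score)
  for (p in names(programs)) {
    out[[p]] <- module_score(normalized, programs[[p]],
                             seed = stage_seed(seed, paste0("lineage_", p)))
  }
  out
}

#' Assign leukemia-like cells to the six cellular states
#'
#' Deterministic rule-based typing: the winning lineage is the argmax of the
#' lineage module scores (exact ties broken in the fixed order stem > GMP >
#' granulocyte > promono > mono); stem cells split into QSC (proliferation
#' `<= tau`) vs PSP (`> tau`); granulocyte-lineage cells in S or G2M phase
#' are proliferating granulocytes (PG), otherwise they fall back to GMP.
#'
#' @param scores tibble from [score_cells()] (needs `cell_id`,
#'   `proliferation`, `phase` and the five lineage columns).
#' @param malignancy a `malignancy_call` from [classify_clusters()], or a
#'   tibble with `cell_id` and `call`.
#' @param tau proliferation threshold separating QSC from PSP.
#' @return tibble: `cell_id`, `state`, `lineage`, plus the input scores,
#'   restricted to leukemia-like cells.
#' @export
assign_states <- function(scores, malignancy, tau = 0) {
  calls <- if (inherits(malignancy, "malignancy_call")) malignancy$cells else
    tibble::as_tibble(malignancy)
  leuk_ids <- calls$cell_id[calls$call == "leukemia-like"]
  sc <- dplyr::filter(scores, .data$cell_id %in% leuk_ids)
  if (nrow(sc) == 0) abort_ls("no leukemia-like cells to assign")
  lineages <- c("stem", "GMP", "granulocyte", "promono", "mono")
  miss <- setdiff(lineages, names(sc))
  if (length(miss)) abort_ls("missing lineage score columns: ", paste(miss, collapse = ", "))
  lm <- as.matrix(sc[, lineages])
  win <- apply(lm, 1, which.max)           # which.max: first max wins = fixed order
  lineage <- lineages[win]
  state <- character(nrow(sc))
  state[lineage == "stem"] <- ifelse(sc$proliferation[lineage == "stem"] <= tau,
                                     "QSC", "PSP")
  state[lineage == "GMP"] <- "GMP"
  state[lineage == "granulocyte"] <- ifelse(sc$phase[lineage == "granulocyte"] %in%
                                              c("S", "G2M"), "PG", "GMP")
  state[lineage == "promono"] <- "promono"
  state[lineage == "mono"] <- "mono"
  dplyr::mutate(sc, lineage = lineage, state = state)
}

#' State-specific surface markers by one-vs-rest testing
#'
#' For each state, a one-vs-rest Wilcoxon rank-sum test (normal
#' approximation, tie- and continuity-corrected) restricted to a provided
#' surface-gene list; genes pass with log-fold-change `>= min_logfc`
#' (difference of mean log-normalized expression) and Benjamini-Hochberg
#' FDR `<= max_fdr` within the state. States with fewer than 3 cells are
#' skipped with a warning.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param states per-cell state labels (vector aligned with columns, or a
#'   tibble with `cell_id`, `state`).
#' @param surface_list character vector of surface gene names.
#' @param min_logfc,max_fdr selection thresholds.
#' @return tibble: `state`, `gene`, `logfc`, `p`, `fdr`, sorted by state
#'   then decreasing logfc.
#' @export
surface_markers <- function(normalized, states, surface_list,
                            min_logfc = 0.25, max_fdr = 0.05) {
  if (length(surface_list) == 0) abort_ls("surface_list must be nonempty")
  lab <- state_labels_for(normalized, states)
  keep <- !is.na(lab)
  x <- normalized[intersect(surface_list, rownames(normalized)), keep, drop = FALSE]
  if (nrow(x) == 0) abort_ls("no surface-list gene present in the matrix")
  lab <- lab[keep]
  res <- list()
  for (s in sort(unique(lab))) {
    idx1 <- which(lab == s)
    if (length(idx1) < 3) {
      warning("state ", s, " has fewer than 3 cells; skipped")
      next
    }
    tab <- wilcox_matrix(x, idx1, which(lab != s))
    tab$fdr <- p.adjust(tab$p, "BH")
    tab <- dplyr::filter(tab, .data$logfc >= min_logfc, .data$fdr <= max_fdr)
    if (nrow(tab)) res[[s]] <- dplyr::mutate(tab, state = s)
  }
  if (!length(res)) return(tibble::tibble(state = character(), gene = character(),
                                          logfc = numeric(), p = numeric(),
                                          fdr = numeric()))
  dplyr::bind_rows(res) |>
    dplyr::arrange(.data$state, dplyr::desc(.data$logfc), .data$gene) |>
    dplyr::select("state", "gene", "logfc", "p", "fdr")
}

# resolve a labels argument (vector or cell_id/state tibble) against the
# columns of a matrix; NA where no label
state_labels_for <- function(normalized, states) {
  if (is.data.frame(states)) {
    lab <- states$state[match(colnames(normalized), states$cell_id)]
  } else {
    stopifnot(length(states) == ncol(normalized))
    lab <- as.character(states)
  }
  lab
}
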