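#' Default end-to-end run configuration
#'
#' Nested list of every stage's parameters, with the defaults used
#' throughout the package. Optional stages carry an `enabled` flag;
#' disabling one never changes an earlier stage's results because each
#' stage derives its own seed via [stage_seed()].
#'
#' @param seed global integer seed.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, n_genes = 2000, n_patients_aml = 7,
                    n_patients_hc = 20, cells_per_sample = 500),
    input_dir = NULL,
    qc = list(min_genes = 200, max_genes = 6000, max_mito_frac = 0.2),
    reduce = list(n_hvg = 1500, d = 30, k = 15),
    cluster = list(resolution = 3),
    malignancy = list(theta_high = 0.9, mode = "threshold", rho = 2,
                      grid_bins = 400),
    states = list(tau = 0, min_logfc = 0.25, max_fdr = 0.05),
    ith = list(normalize = FALSE),
    survival = list(enabled = TRUE, beta_ith = log(2), beta_qsc = 0,
                    baseline_rate = 0.002, censor_rate = 5e-4),
    deconvolution = list(enabled = TRUE, n_mixtures = 50, noise_sd = 0.1,
                         top_m = 50),
    longitudinal = list(enabled = TRUE, lambda = 0.5,
                        cells_per_timepoint = 1000, k = 15),
    interactions = list(enabled = TRUE, min_frac = 0.1, n_perm = 200)
  ), class = "run_config")
}

validate_run_config <- function(config) {
  template <- default_run_config()
  check <- function(cfg, tmpl, path = "") {
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown)) {
      abort_ls("unknown config key", if (length(unknown) > 1) "s" else "", ": ",
               paste0(path, unknown, collapse = ", "))
    }
    for (nm in names(cfg)) {
      if (is.list(tmpl[[nm]]) && is.list(cfg[[nm]])) {
        check(cfg[[nm]], tmpl[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check(unclass(config), unclass(template))
  # fill unset keys from defaults
  merge2 <- function(cfg, tmpl) {
    for (nm in names(tmpl)) {
      if (!nm %in% names(cfg)) cfg[nm] <- tmpl[nm]
      else if (is.list(tmpl[[nm]]) && is.list(cfg[[nm]])) {
        cfg[[nm]] <- merge2(cfg[[nm]], tmpl[[nm]])
      }
    }
    cfg
  }
  structure(merge2(unclass(config), unclass(template)), class = "run_config")
}

#' Run the full pipeline end to end
#'
#' Simulate (or read) a cohort, then QC, normalize, reduce, cluster, call
#' malignancy, score and assign the six states, compute per-sample
#' composition and ITH, and optionally simulate/analyze survival,
#' deconvolve synthetic bulk mixtures, run the longitudinal label-transfer
#' and reprogramming analysis, and score ligand-receptor interactions.
#' Returns a machine-readable report; any stage error aborts naming the
#' stage. The report carries no timestamps, so identical `(config, seed)`
#' runs produce identical reports.
#'
#' @param config a `run_config` (see [default_run_config()]); partial lists
#'   are filled with defaults, unknown keys are rejected before any
#'   computation.
#' @param out_dir optional directory; if given, the report is written to
#'   `report.json` and the resolved config to `config.json` there.
#' @return a `run_report` list.
#' @export
run_all <- function(config = default_run_config(), out_dir = NULL) {
  config <- validate_run_config(config)
  seed <- config$seed
  report <- list(seed = seed, parameters = unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_ls("stage '", name, "' failed: ", conditionMessage(e),
               "\nreproduce with: run_all(config) at seed ", seed)
    })
  }

  gcfg <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim <- stage("simulate", {
      gcfg <- generator_config(n_genes = config$simulate$n_genes,
                               n_patients_aml = config$simulate$n_patients_aml,
                               n_patients_hc = config$simulate$n_patients_hc,
                               cells_per_sample = config$simulate$cells_per_sample,
                               seed = stage_seed(seed, "simulate"))
      c(simulate_cohort(gcfg), list(gcfg = gcfg))
    })
    gcfg <- sim$gcfg
    cells <- sim$cells; truth <- sim$truth
  } else {
    if (is.null(config$input_dir)) abort_ls("either enable simulate or set input_dir")
    cells <- stage("read", read_cellmatrix(config$input_dir))
    truth <- NULL
    gcfg <- generator_config(seed = stage_seed(seed, "simulate"))  # for bundled gene sets
  }

  cells <- stage("qc", qc_filter(cells, config$qc$min_genes, config$qc$max_genes,
                                 config$qc$max_mito_frac))
  norm <- stage("normalize", normalize_log(cells))
  emb <- stage("reduce", reduce_and_graph(norm, config$reduce$n_hvg,
                                          config$reduce$d, config$reduce$k))
  cl <- stage("cluster", cluster_cells(emb, norm, config$cluster$resolution,
                                       seed = stage_seed(seed, "cluster")))
  mal <- stage("malignancy", classify_clusters(cl, cells$cell_meta,
                                               config$malignancy$theta_high,
                                               config$malignancy$mode,
                                               config$malignancy$rho))
  grid <- stage("malignancy", density_ratio_map(emb$embedding2d,
                                                cells$cell_meta$condition,
                                                B = config$malignancy$grid_bins))
  programs <- lineage_programs(gcfg)
  cycles <- cycle_gene_sets(gcfg)
  scores <- stage("states", score_cells(norm, emb, programs, cycles,
                                        proliferation_genes(gcfg),
                                        seed = stage_seed(seed, "states")))
  assigned <- stage("states", assign_states(scores, mal, config$states$tau))
  comp <- stage("ith", composition(assigned, cells$cell_meta,
                                   normalize_entropy = config$ith$normalize))

  report$n_cells <- ncol(norm)
  report$n_clusters <- nrow(mal$clusters)
  report$malignancy <- as.data.frame(mal$per_patient)
  report$density_grid_occupied_bins <- nrow(grid)
  report$state_composition <- as.data.frame(comp)
  report$ith <- as.data.frame(comp[, c("sample", "ith")])

  if (isTRUE(config$survival$enabled) && nrow(comp) >= 4) {
    surv <- stage("survival", {
      tab <- simulate_survival(comp,
                               betas = c(ith = config$survival$beta_ith,
                                         qsc = config$survival$beta_qsc),
                               baseline_rate = config$survival$baseline_rate,
                               censor_rate = config$survival$censor_rate,
                               seed = stage_seed(seed, "survival"))
      tab$group <- tryCatch(median_split(comp$ith), error = function(e) NULL)
      lr <- if (!is.null(tab$group) && sum(tab$event) > 0 &&
                length(unique(tab$group)) == 2) {
        tryCatch(logrank_test(tab), error = function(e) NULL)
      } else NULL
      list(table = tab, logrank = lr)
    })
    report$survival <- list(
      table = as.data.frame(surv$table),
      logrank = if (!is.null(surv$logrank)) {
        list(chi2 = surv$logrank$chi2, p = surv$logrank$p)
      } else NULL)
  }

  if (isTRUE(config$deconvolution$enabled)) {
    dec <- stage("deconvolve", {
      sig <- build_signature(norm[, assigned$cell_id, drop = FALSE],
                             assigned, top_m = config$deconvolution$top_m)
      set.seed(stage_seed(seed, "deconvolve"))
      k <- ncol(sig)
      props <- t(vapply(seq_len(config$deconvolution$n_mixtures),
                        function(i) rdirichlet1(rep(2, k)), numeric(k)))
      colnames(props) <- colnames(sig)
      prof <- empirical_state_profiles(norm[, assigned$cell_id, drop = FALSE],
                                       assigned)[, colnames(sig), drop = FALSE]
      bulk <- simulate_bulk_mixtures(prof, props,
                                     noise_sd = config$deconvolution$noise_sd,
                                     seed = stage_seed(seed, "bulkmix"))
      est <- deconvolve(bulk, sig)
      rmse <- sqrt(mean((as.matrix(est[, paste0("p_", colnames(sig))]) - props)^2))
      list(estimates = est, truth = props, rmse = rmse)
    })
    report$deconvolution <- list(rmse = dec$rmse,
                                 estimates = as.data.frame(dec$estimates))
  }

  if (isTRUE(config$longitudinal$enabled)) {
    lon <- stage("longitudinal", {
      lcfg <- generator_config(n_genes = gcfg$n_genes,
                               cells_per_sample = config$longitudinal$cells_per_timepoint,
                               seed = stage_seed(seed, "longitudinal"))
      sim2 <- simulate_longitudinal(lcfg, lambda = config$longitudinal$lambda,
                                    cells_per_timepoint = config$longitudinal$cells_per_timepoint)
      ref_labels <- assigned$state[match(rownames(emb$pcs), assigned$cell_id)]
      ref_labels[is.na(ref_labels)] <- "normal"
      tp <- lapply(list(pre = sim2$pre, post = sim2$post), function(cmx) {
        transfer_labels(list(embedding = emb, labels = ref_labels), cmx,
                        k = config$longitudinal$k)
      })
      shift <- composition_shift(dplyr::filter(tp$pre, .data$state != "normal"),
                                 dplyr::filter(tp$post, .data$state != "normal"))
      npre <- normalize_log(sim2$pre); npost <- normalize_log(sim2$post)
      pre_truth <- sim2$truth$cells[sim2$truth$cells$timepoint == "pre", ]
      post_truth <- sim2$truth$cells[sim2$truth$cells$timepoint == "post", ]
      de_genes <- unique(c(lineage_programs(lcfg)$stem))
      ri <- reprogramming_index(
        npre[, pre_truth$state == "QSC", drop = FALSE],
        npre[, pre_truth$state == "PSP", drop = FALSE],
        npost[, post_truth$state == "PSP", drop = FALSE],
        de_genes)
      list(shift = shift, R = ri$R, lambda = config$longitudinal$lambda)
    })
    report$longitudinal <- list(lambda = lon$lambda, R = lon$R,
                                shift = as.data.frame(lon$shift$proportions))
  }

  if (isTRUE(config$interactions$enabled)) {
    lr <- stage("interactions", {
      score_lr(norm[, assigned$cell_id, drop = FALSE], assigned,
               default_lr_pairs(), min_frac = config$interactions$min_frac,
               n_perm = config$interactions$n_perm,
               seed = stage_seed(seed, "interactions"))
    })
    report$interactions <- as.data.frame(lr)
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "-", x$n_cells, "cells,",
      x$n_clusters, "clusters\n")
  if (!is.null(x$ith)) {
    cat("per-sample ITH:\n"); print(utils::head(x$ith, 10))
  }
  invisible(x)
}
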