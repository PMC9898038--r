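#' Specify the cellular states of a synthetic bone-marrow cohort
#'
#' Builds the default state table: six leukemia-like states (QSC, PSP, GMP,
#' PG, promono, mono) that occur only in AML samples, and six normal lineages
#' (HSC, Ery, MonoN, Tcell, Bcell, NK) shared by both conditions. Each state
#' owns a disjoint block of marker genes; stem-like states additionally
#' activate more low-level "richness" programs than differentiated states,
#' which is what a transcriptional-diversity stemness score detects.
#'
#' @param n_genes total number of genes (>= 800).
#' @param marker_log_effect natural-log fold effect of a state on its own
#'   marker genes (default 2, about 7.4-fold).
#' @return a tibble with one row per state: `name`, `malignant`, `cycling`,
#'   `diversity_rank` (number of active richness programs; stem states
#'   highest), `marker_log_effect`, `prop_hc`, `prop_aml`, and list-columns
#'   `marker_genes` and `surface_flagged` of gene indices.
#' @export
default_states <- function(n_genes = 2000, marker_log_effect = 2) {
  lay <- gene_layout(n_genes)
  nm <- c("QSC", "PSP", "GMP", "PG", "promono", "mono",
          "HSC", "Ery", "MonoN", "Tcell", "Bcell", "NK")
  tibble::tibble(
    name = nm,
    malignant = c(rep(TRUE, 6), rep(FALSE, 6)),
    cycling = nm %in% c("PSP", "PG"),
    diversity_rank = c(12L, 12L, 8L, 6L, 4L, 2L, 12L, 3L, 3L, 3L, 3L, 3L),
    marker_log_effect = marker_log_effect,
    marker_genes = lapply(seq_along(nm), function(i) lay$marker_blocks[[i]]),
    surface_flagged = lapply(seq_along(nm), function(i) lay$marker_blocks[[i]][1:6]),
    prop_hc  = c(rep(0, 6), 0.05, 0.20, 0.20, 0.30, 0.15, 0.10),
    prop_aml = c(0.07, 0.14, 0.14, 0.105, 0.105, 0.14,
                 0.02, 0.05, 0.06, 0.09, 0.05, 0.03)
  )
}

# deterministic allocation of gene indices to roles; no RNG
gene_layout <- function(n_genes) {
  if (n_genes < 800) abort_ls("n_genes must be at least 800")
  n_states <- 12L; n_marker <- 30L; n_prog <- 12L; prog_size <- 25L; n_cc <- 40L
  marker_idx <- seq_len(n_states * n_marker)
  marker_blocks <- split(marker_idx, rep(seq_len(n_states), each = n_marker))
  prog_start <- n_states * n_marker
  prog_blocks <- split(prog_start + seq_len(n_prog * prog_size),
                       rep(seq_len(n_prog), each = prog_size))
  cc_start <- prog_start + n_prog * prog_size
  s_genes <- cc_start + seq_len(n_cc)
  g2m_genes <- cc_start + n_cc + seq_len(n_cc)
  mito <- (n_genes - 12L):n_genes
  background <- setdiff(seq_len(n_genes), c(marker_idx, unlist(prog_blocks),
                                            s_genes, g2m_genes, mito))
  names <- sprintf("G%04d", seq_len(n_genes))
  # real gene names where the study's markers matter: QSC surface program and
  # the monocyte receptors of the bundled ligand-receptor pairs
  names[marker_blocks[[1]][1:6]] <- c("CD52", "LGALS1", "CD47", "CD99", "ITGA4", "PDLIM1")
  names[marker_blocks[[6]][1:3]] <- c("SIGLEC10", "SIRPA", "CD14")
  names[mito] <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
                   "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB")
  list(n_genes = n_genes, marker_blocks = marker_blocks, prog_blocks = prog_blocks,
       s_genes = s_genes, g2m_genes = g2m_genes, mito = mito,
       background = background, gene_names = names)
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the study setting: 7 AML patients and 20 healthy
#' controls, one sample each, 500 cells per sample, 2,000 genes, a shared
#' negative-binomial noise model with multiplicative log-normal patient
#' effects, and mild uniform extra dropout.
#'
#' @param n_genes number of genes.
#' @param states state table as from [default_states()].
#' @param n_patients_aml,n_patients_hc number of AML / healthy patients
#'   (one sample per patient).
#' @param cells_per_sample cells per sample.
#' @param patient_effect_sd sd of the per-patient log-normal gene effect.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param libsize_log_mean,libsize_log_sd log-normal library-size factor
#'   (multiplies a baseline of ~2,500 counts/cell).
#' @param dropout_extra probability of Bernoulli zeroing applied on top of
#'   the count sampling.
#' @param composition_alpha Dirichlet concentration for per-sample
#'   composition variation around the condition baseline.
#' @param cycle_log_effect natural-log effect of the active cell-cycle
#'   program (S or G2M) in cycling cells.
#' @param program_log_effect natural-log effect of an active richness
#'   program.
#' @param mito_frac_mean,mito_conc Beta mean/concentration of the per-cell
#'   mitochondrial fraction.
#' @param mito_outlier_frac,mito_outlier_level fraction of cells planted as
#'   high-mito outliers and their mito fraction (for exercising QC).
#' @param seed integer seed governing all generator randomness.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(n_genes = 2000,
                             states = default_states(n_genes),
                             n_patients_aml = 7, n_patients_hc = 20,
                             cells_per_sample = 500,
                             patient_effect_sd = 0.15,
                             dispersion = 2,
                             libsize_log_mean = 0, libsize_log_sd = 0.25,
                             dropout_extra = 0.05,
                             composition_alpha = 60,
                             cycle_log_effect = 7,
                             program_log_effect = log(25),
                             mito_frac_mean = 0.05, mito_conc = 50,
                             mito_outlier_frac = 0, mito_outlier_level = 0.5,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), states = tibble::as_tibble(states),
              n_patients_aml = as.integer(n_patients_aml),
              n_patients_hc = as.integer(n_patients_hc),
              cells_per_sample = as.integer(cells_per_sample),
              patient_effect_sd = patient_effect_sd, dispersion = dispersion,
              libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
              dropout_extra = dropout_extra, composition_alpha = composition_alpha,
              cycle_log_effect = cycle_log_effect,
              program_log_effect = program_log_effect,
              mito_frac_mean = mito_frac_mean, mito_conc = mito_conc,
              mito_outlier_frac = mito_outlier_frac,
              mito_outlier_level = mito_outlier_level,
              seed = as.integer(seed))
  cfg$layout <- gene_layout(cfg$n_genes)
  validate_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_config <- function(cfg) {
  st <- cfg$states
  if (nrow(st) == 0) abort_ls("states must be nonempty")
  if (anyDuplicated(st$name)) abort_ls("state names must be unique")
  for (f in c("n_genes", "n_patients_aml", "n_patients_hc", "cells_per_sample")) {
    if (cfg[[f]] < 1) abort_ls(f, " must be >= 1")
  }
  if (cfg$patient_effect_sd < 0) abort_ls("patient_effect_sd must be nonnegative")
  if (cfg$dispersion <= 0) abort_ls("dispersion must be positive")
  assert_prob(cfg$dropout_extra, "dropout_extra")
  assert_prob(cfg$mito_outlier_frac, "mito_outlier_frac")
  assert_prob(st$prop_hc, "prop_hc")
  assert_prob(st$prop_aml, "prop_aml")
  if (abs(sum(st$prop_hc) - 1) > 1e-8 || abs(sum(st$prop_aml) - 1) > 1e-8) {
    abort_ls("per-condition state proportions must sum to 1")
  }
  all_markers <- unlist(st$marker_genes)
  if (any(all_markers < 1) || any(all_markers > cfg$n_genes)) {
    abort_ls("marker gene indices exceed n_genes")
  }
  if (anyDuplicated(all_markers)) abort_ls("marker sets must be disjoint across states")
  if ("QSC" %in% st$name && st$cycling[st$name == "QSC"]) {
    abort_ls("QSC must be non-cycling")
  }
  if (any(!st$cycling[st$name %in% c("PSP", "PG")])) {
    abort_ls("PSP and PG must be cycling")
  }
  invisible(cfg)
}

# --- model construction -----------------------------------------------------

# Draws the gene-level parameters (baseline log-means, patient effects) and
# precomputes per-state linear mean profiles. Consumes RNG; callers are
# responsible for set.seed.
build_model <- function(cfg, target_libsize = 2500) {
  lay <- cfg$layout
  r <- numeric(cfg$n_genes)
  r[lay$background] <- exp(rnorm(length(lay$background), 0, 1.25))
  r[unlist(lay$marker_blocks)] <- 0.5
  r[unlist(lay$prog_blocks)] <- 0.02
  # cycle genes are essentially off outside their phase and strongly induced
  # in phase (like MKI67/TOP2A); the induction must lift their POOLED mean
  # into bins of moderately expressed genes, so that a non-cycling cell
  # scores its (unexpressed) set clearly below its expression-matched
  # controls -- the sign margin cycle_phase and the QSC/PSP split rely on
  r[c(lay$s_genes, lay$g2m_genes)] <- 0.05
  r[lay$mito] <- 0                           # mito means set per cell
  mito_w <- exp(rnorm(length(lay$mito), 0, 0.5))
  beta <- log(pmax(r, 1e-12) * target_libsize / sum(r))

  st <- cfg$states
  n_states <- nrow(st)
  delta <- matrix(0, cfg$n_genes, n_states, dimnames = list(NULL, st$name))
  n_prog <- length(lay$prog_blocks)
  for (k in seq_len(n_states)) {
    delta[st$marker_genes[[k]], k] <- st$marker_log_effect[k]
    n_act <- min(st$diversity_rank[k], n_prog)
    if (n_act > 0) {
      delta[unlist(lay$prog_blocks[seq_len(n_act)]), k] <- cfg$program_log_effect
    }
  }
  profiles <- exp(beta + delta)              # genes x states, G1 phase
  rownames(profiles) <- lay$gene_names

  n_pat <- cfg$n_patients_aml + cfg$n_patients_hc
  pat_ids <- c(sprintf("AML%02d", seq_len(cfg$n_patients_aml)),
               sprintf("HC%02d", seq_len(cfg$n_patients_hc)))
  u <- matrix(rnorm(cfg$n_genes * n_pat, 0, cfg$patient_effect_sd),
              cfg$n_genes, n_pat, dimnames = list(NULL, pat_ids))
  u[lay$mito, ] <- 0
  list(beta = beta, delta = delta, profiles = profiles, mito_w = mito_w,
       patient_effect = exp(u), patients = pat_ids, target_libsize = target_libsize)
}

# expected linear mean profile of a state averaged over its phase mix
phase_averaged_profile <- function(cfg, model, state) {
  st <- cfg$states
  k <- match(state, st$name)
  prof <- model$profiles[, k]
  if (st$cycling[k]) {
    lay <- cfg$layout
    s_prof <- prof; s_prof[lay$s_genes] <- s_prof[lay$s_genes] * exp(cfg$cycle_log_effect)
    g_prof <- prof; g_prof[lay$g2m_genes] <- g_prof[lay$g2m_genes] * exp(cfg$cycle_log_effect)
    prof <- 0.5 * s_prof + 0.5 * g_prof
  }
  prof
}

#' Expected expression profiles of the generator's states
#'
#' Returns the genes-by-states matrix of expected mean expression under a
#' config, averaging cycling states over their phase mix, with every column
#' scaled to 10,000 total counts (the counts-per-10k scale all normalized
#' quantities in the package live on). Useful as the truth profile input of
#' [simulate_bulk_mixtures()].
#'
#' @param config a [generator_config()].
#' @param states which states (default: the malignant six).
#' @param scale_to total each column is scaled to (default counts-per-10k);
#'   `NULL` returns the raw model means.
#' @return numeric matrix, genes x states, rownames = gene names.
#' @export
state_profiles <- function(config, states = config$states$name[config$states$malignant],
                           scale_to = 1e4) {
  set.seed(config$seed)
  model <- build_model(config)
  out <- vapply(states, function(s) phase_averaged_profile(config, model, s),
                numeric(config$n_genes))
  rownames(out) <- config$layout$gene_names
  if (is.null(scale_to)) out else sweep(out, 2, colSums(out), "/") * scale_to
}

#' Empirical state expression profiles from labeled single cells
#'
#' Per-state mean linear-scale (counts-per-10k) expression over all genes —
#' the cohort's own reference profiles, e.g. to compose synthetic bulk
#' mixtures consistent with a signature built from the same cells.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param states per-cell state labels (vector or `cell_id`/`state`
#'   tibble).
#' @return numeric matrix, genes x states.
#' @export
empirical_state_profiles <- function(normalized, states) {
  lab <- state_labels_for(normalized, states)
  keep <- !is.na(lab)
  lin <- normalized[, keep, drop = FALSE]
  lin@x <- expm1(lin@x)
  lab <- lab[keep]
  sts <- sort(unique(lab))
  out <- vapply(sts, function(s) {
    as.numeric(Matrix::rowMeans(lin[, lab == s, drop = FALSE]))
  }, numeric(nrow(lin)))
  rownames(out) <- rownames(normalized)
  out
}

# sample per-cell counts for one block of cells sharing state/phase/patient
sample_block <- function(cfg, model, state_k, phase, patient, n_cells) {
  lay <- cfg$layout
  m <- model$profiles[, state_k] * model$patient_effect[, patient]
  if (phase == "S")  m[lay$s_genes]  <- m[lay$s_genes]  * exp(cfg$cycle_log_effect)
  if (phase == "G2M") m[lay$g2m_genes] <- m[lay$g2m_genes] * exp(cfg$cycle_log_effect)
  s_c <- exp(rnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd))
  mu <- outer(m, s_c)
  # per-cell mitochondrial fraction
  a <- cfg$mito_frac_mean * cfg$mito_conc
  b <- (1 - cfg$mito_frac_mean) * cfg$mito_conc
  f <- stats::rbeta(n_cells, a, b)
  if (cfg$mito_outlier_frac > 0) {
    out_idx <- runif(n_cells) < cfg$mito_outlier_frac
    f[out_idx] <- cfg$mito_outlier_level
  } else out_idx <- rep(FALSE, n_cells)
  tot <- Matrix::colSums(mu)
  mu[lay$mito, ] <- outer(model$mito_w / sum(model$mito_w), f / (1 - f) * tot)
  x <- rnbinom(length(mu), size = cfg$dispersion, mu = as.vector(mu))
  if (cfg$dropout_extra > 0) {
    x[runif(length(x)) < cfg$dropout_extra] <- 0L
  }
  list(counts = matrix(x, nrow = cfg$n_genes), mito_outlier = out_idx)
}

# Dirichlet draw via gammas; zero-probability states stay exactly zero
rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) g <- as.numeric(alpha > 0)
  g / sum(g)
}

simulate_sample <- function(cfg, model, sample_id, patient, condition,
                            proportions = NULL, n_cells = cfg$cells_per_sample) {
  st <- cfg$states
  base <- if (condition == "AML") st$prop_aml else st$prop_hc
  p <- proportions %||% rdirichlet1(cfg$composition_alpha * base)
  ncells_k <- apportion(n_cells, p)
  blocks <- list(); meta <- list(); bi <- 0
  for (k in seq_len(nrow(st))) {
    nk <- ncells_k[k]
    if (nk == 0) next
    if (st$cycling[k]) {
      n_s <- apportion(nk, c(0.5, 0.5))
      phases <- c(rep("S", n_s[1]), rep("G2M", n_s[2]))
    } else phases <- rep("G1", nk)
    for (ph in unique(phases)) {
      npc <- sum(phases == ph)
      blk <- sample_block(cfg, model, k, ph, patient, npc)
      bi <- bi + 1
      blocks[[bi]] <- blk$counts
      meta[[bi]] <- tibble::tibble(state = st$name[k], phase = ph, n = npc,
                                   mito_outlier = list(blk$mito_outlier))
    }
  }
  counts <- do.call(cbind, blocks)
  md <- dplyr::bind_rows(meta)
  cell_truth <- tibble::tibble(
    sample = sample_id, patient = patient, condition = condition,
    state = rep(md$state, md$n), phase = rep(md$phase, md$n),
    mito_outlier = unlist(md$mito_outlier),
    malignant = rep(st$malignant[match(md$state, st$name)], md$n)
  )
  list(counts = counts, cell_truth = cell_truth,
       composition = setNames(ncells_k / n_cells, st$name))
}

#' Simulate a two-condition bone-marrow single-cell cohort
#'
#' Generates counts for `n_patients_hc` healthy and `n_patients_aml` AML
#' samples. Counts are negative-binomial with mean
#' `s_c * exp(beta_g + delta_{g,state} + u_{g,patient})` (log-normal library
#' size `s_c`, marker/program effects `delta`, log-normal patient effect
#' `u`), followed by Bernoulli extra dropout. Leukemia states occur only in
#' AML samples; stem-like states activate more low-level gene programs than
#' differentiated states (higher expressed-gene richness); cycling states
#' additionally express the bundled S or G2M program; a designated `MT-`
#' gene block realizes a per-cell mitochondrial fraction. The planted
#' per-sample composition equals the realized true-state frequencies
#' exactly (labels are assigned by largest-remainder apportionment).
#'
#' @param config a [generator_config()].
#' @return a list with `cells` (a [cell_matrix()]) and `truth` (list with
#'   per-cell tibble `cells`, per-sample tibble `samples` of realized
#'   compositions, and the `config`).
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  model <- build_model(config)
  pats <- model$patients
  conds <- c(rep("AML", config$n_patients_aml), rep("HC", config$n_patients_hc))
  res <- vector("list", length(pats)); comps <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    sm <- simulate_sample(config, model, sample_id = pats[i], patient = pats[i],
                          condition = conds[i])
    res[[i]] <- sm
    comps[[i]] <- tibble::tibble(sample = pats[i], condition = conds[i],
                                 state = names(sm$composition),
                                 proportion = unname(sm$composition))
  }
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  cell_truth <- dplyr::bind_rows(lapply(res, `[[`, "cell_truth"))
  cell_truth$cell_id <- sprintf("cell%06d", seq_len(nrow(cell_truth)))
  rownames(counts) <- config$layout$gene_names
  colnames(counts) <- cell_truth$cell_id
  meta <- tibble::tibble(cell_id = cell_truth$cell_id, sample = cell_truth$sample,
                         condition = cell_truth$condition, patient = cell_truth$patient,
                         timepoint = "T0")
  cm <- cell_matrix(Matrix::Matrix(counts, sparse = TRUE), meta)
  truth <- list(cells = cell_truth, samples = dplyr::bind_rows(comps),
                config = config)
  list(cells = cm, truth = truth)
}

#' Simulate a matched pre/post-treatment leukemia sample pair
#'
#' One patient's leukemia compartment at diagnosis and after chemotherapy.
#' The post sample has a lower PSP and higher QSC proportion (defaults
#' follow the 5.5% to 10.7% QSC rise reported for the refractory exemplar
#' patient), and every post-treatment PSP cell is drawn from the mean
#' profile `(1 - lambda) * PSP + lambda * QSC`, with its probability of
#' actively cycling likewise reduced to `1 - lambda`. `lambda` is the
#' planted reprogramming coefficient.
#'
#' @param config a [generator_config()].
#' @param lambda reprogramming coefficient in `[0, 1]`.
#' @param cells_per_timepoint cells per timepoint sample.
#' @param prop_pre,prop_post named proportions over the six leukemia states
#'   (each sums to 1).
#' @return list with `pre` and `post` ([cell_matrix()]s) and `truth`
#'   (per-cell tibbles, planted compositions, `lambda`, and the linear-scale
#'   state profiles incl. the mixed post-PSP profile).
#' @export
simulate_longitudinal <- function(config, lambda,
                                  cells_per_timepoint = 2000,
                                  prop_pre = c(QSC = 0.055, PSP = 0.32, GMP = 0.20,
                                               PG = 0.125, promono = 0.125, mono = 0.175),
                                  prop_post = c(QSC = 0.107, PSP = 0.16, GMP = 0.21,
                                                PG = 0.123, promono = 0.15, mono = 0.25)) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    abort_ls("lambda must be a single value in [0, 1]")
  }
  validate_config(config)
  st <- config$states
  leuk <- st$name[st$malignant]
  stopifnot(all(names(prop_pre) %in% leuk), all(names(prop_post) %in% leuk))
  set.seed(config$seed)
  model <- build_model(config)
  patient <- "AML01"

  expand_props <- function(p) {
    full <- setNames(numeric(nrow(st)), st$name)
    full[names(p)] <- p
    full / sum(full)
  }

  draw_tp <- function(props, tp, mix_psp) {
    cfg2 <- config
    model2 <- model
    if (mix_psp && lambda > 0) {
      kp <- match("PSP", st$name); kq <- match("QSC", st$name)
      model2$profiles[, kp] <- (1 - lambda) * model$profiles[, kp] +
        lambda * model$profiles[, kq]
      # cycling probability shrinks with lambda: split planted PSP cells
      # into a still-cycling and a reprogrammed non-cycling fraction
    }
    sm <- simulate_sample_long(cfg2, model2, tp, patient, expand_props(props),
                               cells_per_timepoint,
                               psp_cycling_frac = if (mix_psp) 1 - lambda else 1)
    sm
  }

  pre <- draw_tp(prop_pre, "pre", mix_psp = FALSE)
  post <- draw_tp(prop_post, "post", mix_psp = TRUE)

  mk <- function(sm, tp) {
    counts <- sm$counts
    rownames(counts) <- config$layout$gene_names
    ids <- sprintf("%s_cell%05d", tp, seq_len(ncol(counts)))
    colnames(counts) <- ids
    meta <- tibble::tibble(cell_id = ids, sample = paste0(patient, "_", tp),
                           condition = "AML", patient = patient, timepoint = tp)
    list(cm = cell_matrix(Matrix::Matrix(counts, sparse = TRUE), meta),
         truth = dplyr::mutate(sm$cell_truth, cell_id = ids, timepoint = tp))
  }
  pre_o <- mk(pre, "pre"); post_o <- mk(post, "post")
  kq <- match("QSC", st$name); kp <- match("PSP", st$name)
  list(pre = pre_o$cm, post = post_o$cm,
       truth = list(cells = dplyr::bind_rows(pre_o$truth, post_o$truth),
                    lambda = lambda,
                    prop_pre = prop_pre, prop_post = prop_post,
                    profiles = model$profiles[, st$malignant],
                    post_psp_profile = (1 - lambda) * model$profiles[, kp] +
                      lambda * model$profiles[, kq]))
}

# like simulate_sample but with explicit proportions and a tunable fraction
# of PSP cells that still cycle (used by the longitudinal generator)
simulate_sample_long <- function(cfg, model, sample_id, patient, p, n_cells,
                                 psp_cycling_frac = 1) {
  st <- cfg$states
  ncells_k <- apportion(n_cells, p)
  blocks <- list(); meta <- list(); bi <- 0
  for (k in seq_len(nrow(st))) {
    nk <- ncells_k[k]
    if (nk == 0) next
    cyc <- st$cycling[k]
    frac_cyc <- if (st$name[k] == "PSP") psp_cycling_frac else 1
    if (cyc && frac_cyc > 0) {
      n_cyc <- apportion(nk, c(frac_cyc, 1 - frac_cyc))[1]
    } else n_cyc <- 0
    n_s <- if (n_cyc > 0) apportion(n_cyc, c(0.5, 0.5)) else c(0L, 0L)
    phases <- c(rep("S", n_s[1]), rep("G2M", n_s[2]), rep("G1", nk - n_cyc))
    for (ph in unique(phases)) {
      npc <- sum(phases == ph)
      blk <- sample_block(cfg, model, k, ph, patient, npc)
      bi <- bi + 1
      blocks[[bi]] <- blk$counts
      meta[[bi]] <- tibble::tibble(state = st$name[k], phase = ph, n = npc,
                                   mito_outlier = list(blk$mito_outlier))
    }
  }
  counts <- do.call(cbind, blocks)
  md <- dplyr::bind_rows(meta)
  cell_truth <- tibble::tibble(
    sample = sample_id, patient = patient, condition = "AML",
    state = rep(md$state, md$n), phase = rep(md$phase, md$n),
    mito_outlier = unlist(md$mito_outlier),
    malignant = rep(st$malignant[match(md$state, st$name)], md$n)
  )
  list(counts = counts, cell_truth = cell_truth,
       composition = setNames(ncells_k / n_cells, st$name))
}

#' Simulate bulk expression as known mixtures of state profiles
#'
#' `bulk_s = sum_k p_sk * profile_k`, multiplied elementwise by log-normal
#' noise `exp(N(0, noise_sd))`.
#'
#' @param profiles genes x states nonnegative matrix (e.g.
#'   [state_profiles()]).
#' @param proportions samples x states matrix; every row sums to 1
#'   (tolerance 1e-8).
#' @param noise_sd log-normal noise sd (0 = exact mixtures).
#' @param seed integer seed.
#' @return samples x genes matrix with dimnames preserved.
#' @export
simulate_bulk_mixtures <- function(profiles, proportions, noise_sd = 0.1, seed = 1L) {
  profiles <- as.matrix(profiles); proportions <- as.matrix(proportions)
  if (any(profiles < 0)) abort_ls("profiles must be nonnegative")
  if (ncol(profiles) != ncol(proportions)) {
    abort_ls("proportions must have one column per profile state")
  }
  bad <- abs(rowSums(proportions) - 1) > 1e-8
  if (any(bad)) abort_ls("proportion rows must sum to 1 (rows ",
                         paste(which(bad), collapse = ", "), " do not)")
  set.seed(seed)
  bulk <- proportions %*% Matrix::t(profiles)       # samples x genes
  if (noise_sd < 0) abort_ls("noise_sd must be nonnegative")
  if (noise_sd > 0) bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noise_sd), nrow(bulk)))
  if (is.null(rownames(bulk))) rownames(bulk) <- sprintf("bulk%03d", seq_len(nrow(bulk)))
  colnames(bulk) <- rownames(profiles)
  as.matrix(bulk)
}

#' Simulate survival times whose hazard depends on composition
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(beta_ith * ITH + beta_qsc * p_QSC)`; censoring is an
#' independent exponential.
#'
#' @param compositions data frame with columns `sample`, `ith` and
#'   optionally `p_QSC` (missing columns are treated as zero covariates).
#' @param betas named vector with elements `ith` and/or `qsc`.
#' @param baseline_rate,censor_rate positive event / censor hazards (per
#'   day).
#' @param seed integer seed.
#' @return tibble: `sample`, `time` (days), `event` (0/1).
#' @export
simulate_survival <- function(compositions, betas = c(ith = log(2), qsc = 0),
                              baseline_rate = 0.002, censor_rate = 5e-4,
                              seed = 1L) {
  compositions <- tibble::as_tibble(compositions)
  if (nrow(compositions) == 0) abort_ls("compositions must be nonempty")
  if (baseline_rate <= 0 || censor_rate < 0) abort_ls("rates must be positive")
  ith <- if ("ith" %in% names(compositions)) compositions$ith else rep(0, nrow(compositions))
  qsc <- if ("p_QSC" %in% names(compositions)) compositions$p_QSC else rep(0, nrow(compositions))
  b_ith <- unname(betas["ith"] %||% 0); if (is.na(b_ith)) b_ith <- 0
  b_qsc <- unname(betas["qsc"] %||% 0); if (is.na(b_qsc)) b_qsc <- 0
  set.seed(seed)
  rate <- baseline_rate * exp(b_ith * ith + b_qsc * qsc)
  t_event <- rexp(length(rate), rate)
  t_cens <- if (censor_rate > 0) rexp(length(rate), censor_rate) else rep(Inf, length(rate))
  tibble::tibble(sample = compositions$sample,
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
}

# --- bundled gene sets ------------------------------------------------------

#' Bundled cell-cycle gene sets of a generator config
#'
#' @param config a [generator_config()].
#' @return list with character vectors `S` and `G2M`.
#' @export
cycle_gene_sets <- function(config) {
  lay <- config$layout
  list(S = lay$gene_names[lay$s_genes], G2M = lay$gene_names[lay$g2m_genes])
}

#' Proliferation gene program (union of the S and G2M sets)
#' @param config a [generator_config()].
#' @return character vector of gene names.
#' @export
proliferation_genes <- function(config) {
  unlist(cycle_gene_sets(config), use.names = FALSE)
}

#' Lineage programs used for six-state assignment
#'
#' The stem program is the union of QSC and PSP markers; the granulocyte
#' program is the PG marker block; GMP, promono and mono use their own
#' marker blocks.
#'
#' @param config a [generator_config()].
#' @return named list of character vectors
#'   (`stem`, `GMP`, `granulocyte`, `promono`, `mono`).
#' @export
lineage_programs <- function(config) {
  st <- config$states; g <- config$layout$gene_names
  mk <- function(s) g[unlist(st$marker_genes[st$name %in% s])]
  list(stem = mk(c("QSC", "PSP")), GMP = mk("GMP"), granulocyte = mk("PG"),
       promono = mk("promono"), mono = mk("mono"))
}

#' Surface-gene list bundled with the generator
#'
#' Union of every state's surface-flagged markers plus a block of background
#' genes, emulating a cell-surface-protein annotation source.
#'
#' @param config a [generator_config()].
#' @return character vector of gene names.
#' @export
surface_gene_list <- function(config) {
  st <- config$states; lay <- config$layout
  flagged <- unlist(st$surface_flagged)
  extra <- lay$background[seq_len(min(50, length(lay$background)))]
  lay$gene_names[sort(unique(c(flagged, extra)))]
}

#' Default ligand-receptor pair table
#'
#' Contains the CD52-SIGLEC10 and CD47-SIRPA pairs; under the default
#' generator CD52/CD47 are QSC markers and SIGLEC10/SIRPA monocyte markers,
#' planting a QSC-to-monocyte interaction.
#'
#' @return tibble with columns `ligand`, `receptor`.
#' @export
default_lr_pairs <- function() {
  tibble::tibble(ligand = c("CD52", "CD47"), receptor = c("SIGLEC10", "SIRPA"))
}
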