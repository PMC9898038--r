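---
title: "Models and methods behind lscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the rules, and the design
choices in `lscape`, in the spirit of a methods section: what each stage
assumes, which parameters matter, and what the synthetic generator does and
does not emulate.

## The analysis problem

Relapsed/refractory AML bone marrow contains a mixture of malignant cells —
spanning a differentiation hierarchy from quiescent stem-like cells (QSC)
through proliferating stem/progenitors (PSP), granulocyte–monocyte
progenitors (GMP), proliferating granulocytes (PG), promonocytes and
monocytes — and residual normal hematopoiesis. The pipeline answers, in
order: which cells are leukemia-like; which of six states each is in; how
diverse each patient's leukemia is (intratumoral heterogeneity, ITH); how
that composition relates to survival and to bulk transcriptomes; how states
shift and reprogram under chemotherapy; and which ligand–receptor pairs
connect states.

## Identifying leukemia-like cells from cluster composition

Malignant AML cells occupy expression states that healthy marrow does not,
while residual normal cells in a patient co-embed with their healthy
counterparts. Deliberate *over*-clustering (Leiden at resolution 3 on a
k = 15 nearest-neighbor graph over 30 PCs) therefore isolates
condition-specific clusters, and the fraction of AML-patient cells
`f_k` in cluster `k` is a direct malignancy readout: a cluster is
leukemia-like when `f_k >= theta_high` (default 0.9). The assumptions are
(i) enough healthy cells to anchor the shared states (the default cohort
has ~2.8 healthy cells per AML cell) and (ii) clusters small enough to be
state-pure; resolution is the knob that buys (ii) at no statistical cost,
since downstream statistics never depend on cluster identity beyond the
binary call. Two deliberate policies: healthy-control cells are never
labeled leukemia-like, whatever their cluster; and an alternative
enrichment rule (`f_k /` global AML fraction `>= rho`) is available behind
`mode = "enrichment"` because the single-threshold reading is not the only
defensible one. The density-ratio map bins the 2D embedding into a
`B x B` grid (default 400), normalizes each condition's bin counts to sum
to 1, and reports `log2((d_AML + eps)/(d_HC + eps))` with
`eps = 1/max(condition totals)`; bins are half-open `[lo, hi)` except the
last. It is a visualization; no downstream statistic consumes it.

## Preprocessing and embedding choices

QC keeps cells with 200–6,000 detected genes and a mitochondrial
(`MT-`-prefixed) count fraction at most 0.2, then drops genes seen in fewer
than 3 cells — conventional thresholds, all configurable. Normalization is
counts-per-10k with `log1p`. Highly variable genes are ranked by their
residual from a loess mean–variance trend of the log-normalized values
(a normalized-dispersion criterion robust to many co-varying marker
programs sharing one expression stratum); the default keeps 1,500 genes.
Scaled values are clipped at ±10. PCA is computed by exact
eigendecomposition of the HVG crossproduct with a fixed sign convention, so
the embedding involves no randomness at all; the 2D embedding is simply the
first two PCs, which is sufficient because nothing quantitative depends on
the embedding's aesthetics. No batch/sample integration is performed: the
generator's patient effect is mild by design, and correction is orthogonal
to the statistics defined here; externally corrected PCs can be supplied to
`cluster_cells()` via a custom graph.

## Per-cell scores and the six-state rules

**Module scores** (proliferation, S, G2M, lineage programs) follow the
binned-control construction: genes are binned (24 bins) by pooled average
expression, and each set gene contributes 100 control genes drawn from the
non-set genes of its bin; the score is mean(set) − mean(controls). The
reference point is therefore "genes with the same pooled abundance", which
makes a non-expressing cell score *negative* whenever the set's pooled
abundance is inflated by an expressing subpopulation — exactly the property
the phase and quiescence rules lean on.

**Cell-cycle phase** is `G1` if both S and G2M scores are ≤ 0, otherwise
the larger score's phase (ties to S).

**Stemness** is a transcriptional-diversity score: per-cell expressed-gene
richness; per-gene Pearson correlation with richness; the raw score is the
mean expression of the 200 most richness-correlated genes; three rounds of
kNN-graph smoothing `s <- 0.5 s + 0.5 A s` (row-normalized adjacency);
rank-scaling to [0, 1] (an all-tied vector maps to 0.5). It is validated by
rank correlation with the generator's planted differentiation order, not by
equality with any external tool — there is no NMF step.

**State assignment** is rule-based and pure: the winning lineage is the
argmax of the five lineage module scores (exact ties resolved in the fixed
order stem > GMP > granulocyte > promono > mono); stem cells split into QSC
(proliferation ≤ τ, default τ = 0) vs PSP; granulocyte-lineage cells in
S/G2M are PG, otherwise they fall back to GMP. τ = 0 is this package's
convention for the quiescent/proliferating boundary: with binned controls,
0 is the natural "no proliferation program" point. Pseudotime-based state
definitions are intentionally out of scope; the rules use the same three
ingredients (lineage, stemness/diversity ordering, proliferation) that
define the states biologically.

**Surface markers** per state are one-vs-rest Wilcoxon rank-sum tests
(normal approximation with continuity and tie correction — checked against
`stats::wilcox.test` in the tests) restricted to a surface-gene list, kept
at log-fold-change ≥ 0.25 (difference of mean log-normalized expression)
and Benjamini–Hochberg FDR ≤ 0.05 within state.

**Single-sample enrichment** ranks a cell's genes, weights positions by
`rank^0.75`, and sums the difference between the in-set and out-set running
ECDFs, each normalized by its expected mass, scaled by the best/worst
achievable range. The expected-mass normalization makes the score exactly
zero-mean for a random set on a random ranking — the property the null
Monte-Carlo test asserts — while keeping the usual extremal behavior (a
cell's own top genes achieve the maximum for their set size).

## Heterogeneity and survival

Per-sample composition over the six states uses exact counts;
`shannon_ith()` is `H = -sum p_k log2 p_k` with `0 log 0 = 0`, so
`H ∈ [0, log2 6 ≈ 2.585]` bits. Base 2, unnormalized, is the package
default (the normalized variant `H/log2 6` sits behind
`normalize_entropy = TRUE`) — entropy in bits is the convention easiest to
compare across state counts. Median splits send ties to "Low" (a
deterministic reading of "split at the median") and refuse degenerate
inputs; a two-variable cross-split (`median_cross_split`) covers
QSC-high/PSP-low style groupings. The Kaplan–Meier estimator and the
log-rank test wrap `survival::survfit`/`survdiff`; the product-limit
arithmetic is pinned in the tests by a hand-computed toy
(`S(4) = (4/5)(3/4)(1/2) = 0.3`) and by the exactness of KM under no
censoring.

## Signature-matrix deconvolution

`build_signature()` runs one-vs-rest Wilcoxon tests per state over all
genes, keeps candidates with FDR ≤ 0.05 and positive log-fold-change,
*drops genes significant in more than one state* (a shared proliferation
program is not a state marker — keeping such genes makes the two cycling
states' columns nearly collinear and their proportions unidentifiable),
and retains the top 50 per state by log-fold-change; entries are per-state
mean linear-scale (counts-per-10k) expression. `deconvolve()` scales the
bulk vector to the signature's overall magnitude over shared genes and
solves non-negative least squares *on relative errors*: each gene's row is
weighted by the inverse of its observed bulk value (floored at the 5th
positive percentile), the GLS weighting implied by multiplicative
(log-normal) measurement noise, without which a handful of high-expression
genes dominate the fit. Coefficients are renormalized to the simplex; the
reported residual is the weighted relative residual norm. Signature columns
are *not* individually rescaled — this preserves the identity that a bulk
profile equal to `0.7·col1 + 0.3·col2` is recovered as exactly (0.7, 0.3)
— and proportions are invariant to rescaling the bulk sample. The solver is
cross-checked in the tests against an exhaustive simplex grid search
(step 0.001) on the same weighted objective. No quantile normalization and
no cross-platform ("S-mode") correction are applied: the intended use is a
signature and bulk data on compatible scales, as in the synthetic setting
where bulk mixtures are composed from the cohort's own empirical state
profiles (`empirical_state_profiles()`).

## Longitudinal label transfer and the reprogramming index

Label transfer projects query cells into the reference PC space (reference
HVG means/scales/loadings; absent genes fall at the mean) and takes a
majority vote of the k = 15 nearest reference cells, breaking ties by mean
neighbor distance and then a fixed state order — chosen over anchor-based
integration for exact determinism. Composition shifts report per-state
pre/post proportions and deltas. Per-state differential expression between
timepoints is the same Wilcoxon machinery with BH correction. The
reprogramming index restricts expression to a differential-gene list,
z-scales with pooled *pre-treatment* statistics (so a global post-treatment
shift cannot masquerade as reprogramming), computes the three centroids,
and reports `R = d(X,P)/(d(X,P) + d(X,Q))` for post-PSP centroid X,
pre-PSP P, pre-QSC Q. R is 0 when post-PSP equals pre-PSP and 1 when it
reaches pre-QSC; under the generator's λ-mixing it tracks λ closely. The
natural gene list for the index is the set distinguishing QSC from PSP at
diagnosis (the package uses the stem lineage program on synthetic data);
PCA coordinates over the same genes are returned for plotting.

## Ligand–receptor permutation test

For each (pair, sender, receiver) with both genes expressed in at least 10%
of the respective cells, the score is the CellPhoneDB-style mean of means.
The null permutes state labels across all cells (matching the
single-patient framing of the analysis), and
`p = (1 + #{null ≥ observed})/(n_perm + 1)`, which cannot be zero. The
default 1,000 permutations give a p floor of ~0.001; fewer than 100 is
refused.

## The synthetic cohort generator

The generator is the package's ground truth and defines the study
conditions: 7 AML patients and 20 healthy controls, one 500-cell sample
each, 2,000 genes. Counts are negative-binomial,
`x ~ NB(mean = s_c · exp(beta_g + delta_{g,state} + u_{g,patient}), size = 2)`,
with log-normal library size (sd 0.25 around ~2,500 counts), a per-patient
log-normal gene effect (sd 0.15 — mild, since integration is out of scope),
and 5% extra Bernoulli dropout. Six leukemia states occur only in AML
samples (70% of an AML sample on average) over six shared normal lineages;
per-sample compositions are Dirichlet-distributed around the condition
baseline (concentration 60) and realized by largest-remainder
apportionment, so the recorded truth composition equals the empirical state
frequencies exactly.

Structure planted for each downstream stage:

* **Markers.** Each state owns 30 disjoint marker genes at e² (~7.4-fold).
  QSC's surface-flagged markers carry the names CD52, LGALS1, CD47, CD99,
  ITGA4, PDLIM1 and the monocyte block SIGLEC10, SIRPA, CD14, so the
  surface-marker and ligand–receptor stages have named truth.
* **Stemness gradient.** Twelve 25-gene low-abundance "richness" programs;
  a state's diversity rank (QSC/PSP/HSC 12 … mono 2) sets how many are
  active, so stem states express more distinct genes at matched library
  size — the signal a diversity-based stemness score detects, deliberately
  not confounded with depth.
* **Cell cycle.** Two 40-gene S and G2M sets, essentially silent outside
  their phase and strongly induced (e⁷) in it, MKI67-like. The induction
  level is what lifts the sets' pooled abundance into bins of moderately
  expressed genes, giving non-cycling cells the clear negative
  binned-control margin the phase and QSC/PSP rules require; weaker
  settings leave the sign of those scores at chance. Cycling states (PSP,
  PG) draw phases 50/50 S/G2M; all other cells are G1.
* **QC truth.** Thirteen `MT-` genes realize a per-cell Beta-distributed
  mitochondrial fraction (mean 0.05), with an optional planted
  high-mito outlier fraction for exercising the filter.
* **Longitudinal.** `simulate_longitudinal()` draws one patient's leukemia
  compartment at two timepoints (QSC 5.5% → 10.7%, PSP decreasing, matching
  the refractory exemplar pattern); each post-treatment PSP cell's mean is
  `(1−λ)·PSP + λ·QSC` and its cycling probability `1−λ`, with λ recorded.
* **Bulk and survival.** Mixtures are exact linear combinations of state
  profiles under log-normal noise; survival times are exponential with
  hazard `baseline · exp(beta_ITH·ITH + beta_QSC·p_QSC)` under independent
  exponential censoring.

What the generator does **not** emulate: mutational genotypes, doublets,
ambient RNA, chemistry/batch effects, realistic gene–gene correlation
beyond the planted programs, or continuous differentiation trajectories
(states are discrete). Passing tests therefore demonstrate that each
algorithm recovers the structure it targets under a faithful noise model —
not that the pipeline is robust to artifacts it was never shown.

## Determinism and problem sizes

Every stochastic step takes a seed; `run_all()` derives per-stage seeds by
hashing the stage name into the global seed (`stage_seed()`), so toggling
an optional stage never changes an earlier stage's stream, and identical
configurations produce bit-identical reports. The test suite exercises the
full default cohort (27 samples × 500 cells) for the malignancy, typing,
stemness, deconvolution, interaction and transfer checks; development-scale
fixtures (8 samples × 200 cells) back the unit tests; the reprogramming
sweep uses 2,000 cells per timepoint at five λ values plus 20-seed endpoint
averages at 600 cells; log-rank calibration uses 500 null and 200
alternative replicates at 100 samples per arm. These sizes were chosen so
the whole suite runs in a few minutes while keeping every Monte-Carlo
margin several standard errors wide.

## Known limitations

* The malignancy call needs healthy cells of every shared lineage; a
  lineage absent from controls would be called leukemia-like.
* θ = 0.9 assumes residual normal cells co-cluster with controls; heavy
  batch effects would break this before it breaks anything else.
* The six-state rules presume the lineage programs are provided (bundled
  for synthetic data); on real data they must come from curated markers.
* NNLS deconvolution estimates *RNA-mass* proportions; converting to cell
  fractions would need per-state RNA content, which is not modeled.
* The permutation null for ligand–receptor scores exchanges labels across
  all cells; with strong per-sample structure a within-sample permutation
  would be more conservative.
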