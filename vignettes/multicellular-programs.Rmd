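---
title: "Multicellular programs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicellular programs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcprogram)
```

# The scientific problem

Systemic lupus erythematosus (SLE) is driven by coordinated activation of
many immune cell types at once: interferon signalling, for instance, is not
a property of one population but a patient-level state that monocytes, T
cells, B cells and dendritic cells enter together. `mcprogram` implements a
pipeline for inferring such *multicellular programs* — latent factors whose
gene loadings span several cell types and whose per-sample scores place each
patient on a continuous axis of immune activation — and for following those
programs across data modalities: pseudobulk single-cell cohorts, cell-type
dependency networks, ligand–receptor communication, single-cell archetype
geometry, longitudinal bulk visits with flare outcomes, and spot-based
spatial slides of kidney tissue.

Every stage is exercised against synthetic cohorts with planted ground
truth, so recovery, calibration, and error behaviour are measurable rather
than anecdotal.

# The factor model

## Input convention

Pseudobulk counts are sums of UMI counts over the cells of one type in one
sample. Counts are multiplicative in the underlying programs (an
exponential mean model is the natural generative picture), so the factor
model operates on `log1p`-transformed expression
(`normalize_pseudobulk()`), after two quality-control filters taken
directly from standard practice:

* samples: at least 10 cells **and** at least 1,000 summed counts per cell
  type (inclusive thresholds, applied per view so different cell types may
  retain different sample subsets);
* genes: at least 10 counts in one sample **and** at least 15 in total
  (a 5/10 parameterization serves differential-expression prefiltering).

## Decomposition

`fit_factors()` is a deterministic multi-group, multi-view factorization.
Per view, genes are centred within each group (batch), scaled to unit
variance, and the view is scaled to unit total variance so that gene-rich
cell types do not dominate. Factors are the right singular vectors of the
column-concatenated views; group-wise sample scores are least-squares
projections on the shared loadings; factors contributing less than
`drop_r2 = 0.001` incremental explained variance are dropped; signs are
made canonical (largest-|loading| gene positive). Missing
(cell type, sample) rows are excluded from that view's least squares, not
zero-imputed.

A Bayesian multi-group factor analysis with sparsity priors could occupy
the same interface; the deterministic substitute was chosen because its
output is exactly reproducible, its variance decomposition
`r2(group, celltype, factor) = 1 - SS_res/SS_tot` is verifiable against a
brute-force residual oracle, and the package's validation surface is
recovery of planted structure rather than posterior replication. Group
centring is precisely what removes the planted batch offsets, which is why
recovery is measured against group-centred true scores: correlating against
raw scores would conflate recovery with batch removal.

Programs are selected when they explain **strictly** more than 10% of
variance in at least one (cell type, group) block.

## Covariate association

Per covariate, a multivariate linear model on all factor scores yields a
global R²; per (factor, covariate) pair a univariate model yields the
ANOVA F-test p-value, η², and the slope t for direction, with Bonferroni
adjustment across factors within each covariate. For categorical
covariates the global R² is a redundancy index over indicator columns.

# Downstream stages

## Activity scoring (ULM)

All weighted gene-set scoring uses the univariate linear model: regress a
sample's profile on the weight vector (0 for non-members, over the whole
gene universe); the slope t-statistic is the activity. The identity
`t = r·sqrt(m−2)/sqrt(1−r²)` against the profile–weight Pearson r holds to
1e-8 and is enforced by test. Perfect fits are capped at a large finite t.

## Dependency networks

Per target cell type, ridge regression of its activity on all other cell
types. The penalty is chosen per target by generalized cross-validation
over the grid 10^(−2..2); `cv_r2` is the mean held-out R² over 5 folds at
that penalty, with fold assignment seeded and anchored to sorted sample ids
so the network is invariant to input row order; coefficients come from a
final full fit. Edges are compared between conditions with the rule:
opposite signs or |Δβ| < 0.1 ⇒ shared; otherwise enriched in the condition
with the larger β (boundary |Δβ| = 0.1 is classified; sign(0) counts as
positive). The planted validation scenario is a weak baseline coupling
(β ≈ 0.25) that strengthens in disease (β ≈ 0.95): a literal "zero in
controls" dependency is unidentifiable under the sign rule, because a
near-zero control coefficient flips sign at random.

## Coordinated signatures and bulk mapping

A program's signature takes cell types that are network-coordinated
(CV R² ≥ 0.8) or carry >10% explained variance — or only the single cell
type when the program is restricted to one — then keeps genes with
|w| ≥ 0.5 in at least one selected cell type, averaging only the retained
loadings. The absolute threshold presumes loadings on a bounded
interpretable scale; for unit-norm SVD loading columns `rescale = TRUE`
first rescales each (cell type, factor) column to max |w| = 1. Bulk
mapping scores each (factor, cell type) loading set per sample and averages
across cell types with weights proportional to the summed variance
explained, normalized per factor — hence invariant to weight rescaling.

## Ligand–receptor interactions

Interaction magnitude per sample and quadruplet is the geometric mean of
ligand (sender) and receptor (receiver) mean expression, gated at a 10%
detection fraction in both populations. Views are filtered (rows nonzero
in ≥30% of samples; per-view median nonzero-interaction count, LR-pair
count and covered-sample count thresholds; zero-fill of missing values)
and restricted to dependency-network edges; interactions with Pearson
r > 0.3 and p < 0.05 against the program score are retained. "≥20
interactions per sample" is operationalized as the median over samples of
the view's nonzero-interaction count; it is a configurable argument.

## Archetypes

`fit_archetypes()` solves the principal-convex-hull problem
min ‖X − S·A‖² with S rows on the simplex and A = B·X, B rows on the
simplex, by alternating projected-gradient block updates with backtracking
from a furthest-point initialization — RSS is non-increasing by
construction, and noiseless vertex data is recovered exactly. The k scan
reports an RSS elbow (maximum second difference) because no specific
information criterion is canonical here; k is small in practice (3–7 per
cell type, with per-cell-type embedding dimensionalities stored as
defaults from common practice). Cell weights use an RBF kernel with
length scale ℓ = ½·median(centroid→archetype distance); weights are not
normalized across archetypes — the profile step normalizes instead.
Patient means are averaged in embedding space (distances live there) and
projected on the archetype hull by exact active-set enumeration
(minimal-norm tie-break), which is feasible because k is small and is
verified against a long-run projected-gradient oracle.

Association of archetype distance with program scores uses OLS with HC3
standard errors (one independent observation per patient), BH correction
across archetypes, and classes SLE (negative slope, fdr < 0.05), HC
(positive), neutral; optional permutation p-values use plain score
permutation, or Freedman–Lane residual permutation when covariates are
adjusted for.

## Longitudinal flare risk

Remission visits (SLEDAI < 3) are labelled `short_term` when the next
visit flares (ΔSLEDAI ≥ 4 relative to the index) within the window —
"3 months" is operationalized as 91 days, "6 months" as 182 — and
`long_term` when no flare occurs in the window, the patient's last SLEDAI
is below 2, and total follow-up exceeds 90 days; everything else is
excluded. When several visits fall inside the window the first subsequent
visit decides. The follow-up reference (the patient's total observed
span) is one of two defensible readings and is configurable by
preprocessing. Pre-flare differences use Welch t-tests with Holm
correction. Cox models are fitted by partial likelihood with Breslow tie
handling via the survival package (the standard implementation in this
field), with Harrell's C and likelihood-ratio tests against nested models;
an independent brute-force partial-likelihood optimizer serves as the test
oracle. The textbook two-observation instance has a monotone partial
likelihood (no finite optimum), so the oracle comparison uses a
four-observation instance with a finite maximizer.

## Spatial co-localization

The spatial weight matrix is binary k-nearest-neighbour (k = 6, ties to
the lower spot index), deliberately left row-unnormalized; the bivariate
Moran's I includes the n/S0 factor that makes it scale-correct, and with
x = y it reduces exactly to univariate Moran's I. Significance is a
two-tailed permutation test in the Davison–Hinkley form
p = (1 + #{|I*| ≥ |I|})/(n_perms + 1), floor 1/101 at 100 permutations;
per-slide p-values are combined with Fisher's method (χ², 2k df), BH
adjusted, and significance additionally requires |mean I| ≥ 0.10.
Neighbourhood modelling CLRs compositions after zeroing entries < 0.05 and
adding a 1e-31 pseudocount; the paraview is a Gaussian distance-weighted
neighbour mean with radius twice the lattice spacing (spacing = mode of
per-spot nearest-neighbour distances) and bandwidth r/2; the learner is a
random forest behind a fit/predict/importance contract, with view
contributions attributed as intraview R² plus the combined-model gain.

# The synthetic-data generator

The generator defines the study conditions; its defaults were chosen once,
on generative grounds:

* **Cohort**: 3 groups × 20 samples, 5 cell types × 300 genes, Poisson
  counts around `exp(baseline + w·z + ε)` with baselines log-uniform on
  20–200 counts, loadings ±U(0.5, 1)·0.5 on 25% of genes, ε ~ N(0, 0.3).
  One planted factor loads in every cell type with a +1.5 SD case shift;
  one is restricted to a single cell type. Group offsets (SD 0.3) are the
  only batch effect. SLEDAI is a clipped rounded linear function of the
  multicellular score (0–19), weakly positive in controls.
* **Cells**: Dirichlet mixtures of k archetype vertices (pairwise
  separation 3·√2 in embedding units) plus isotropic noise; the
  concentration of archetype 1 is tilted by exp(coupling·score).
* **Visits**: patient random effect plus visit noise; flare times are
  exponential with hazard `0.003·exp(β·activity)` per day; a flare
  triggers an early next visit (so recorded times are true event times)
  and a SLEDAI jump ≥ 4.
* **Slides**: 20×20 lattices with 3 disk niches; case slides elevate both
  program score and immune abundance inside niches (strength 1, noise
  SD 0.5); control slides are independent noise.

What the generator does *not* emulate: ambient RNA, doublets, realistic
gene symbols, overdispersion beyond Poisson (a dispersion flag would be
the natural extension), cohort-specific depth differences, or spatial
platform artefacts. Passing tests therefore demonstrate correctness of
the statistical machinery and recoverability under clean planted
structure, not performance on real cohorts.

# Numerical choices

* Multiplicative zero replacement in CLR uses δ = 1e-6 × the row's minimum
  nonzero proportion (the method, not δ, is standard; δ only needs to be
  far below real proportions).
* Simplex projections use the exact sort-based algorithm, vectorized over
  rows; archetype block updates backtrack until the objective decreases,
  so descent is guaranteed, and steps that cannot decrease it are
  rejected.
* Ties in kNN neighbour selection go to the lower spot index; fold
  assignment in ridge CV is anchored to sorted sample ids; the random
  forest is fitted single-threaded with a fixed seed and sorted spot
  order. These three conventions make every pipeline stage reproducible
  bit-for-bit under a fixed seed.
* ULM p-values are two-sided t with m−2 df; perfect fits are capped at
  t = 1e8 before the p-value floor.

# Problem sizes used in validation

The packaged tests and the acceptance script run the cohort stage at
60 samples × 5 views × 300 genes, archetype stages at 600 cells, Cox
recovery at 300 patients × 4 visits, and spatial stages at 400-spot
slides, with 10–200 seed replicates per property. These sizes were chosen
so that every planted effect is comfortably identifiable while a full
validation pass stays interactive on a laptop.

# Worked example

```{r example, eval = FALSE}
library(mcprogram)
res <- run_patient_map_pipeline(seed = 1)
res$recovery$r_multicellular   # fitted vs planted program score
res$programs                   # factors explaining >10% variance somewhere
res$edges[res$edges$class != "shared", ]
res$longitudinal$cox           # flare hazard of program activity
res$spatial$colocalization     # Moran's I by condition
```

# Known limitations

* The factorization is linear; programs that manifest only in count
  overdispersion or nonlinear combinations are out of reach.
* CCC scoring is a magnitude score (geometric mean expression with a
  detection gate), not a consensus over multiple inference methods; the
  selection logic downstream of the score is the validated part.
* The Fisher combination across slides assumes independent slides.
* Archetype stability is measured by coordinate agreement after optimal
  matching; label-switching across k is not resolved automatically.
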