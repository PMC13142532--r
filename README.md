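# mcprogram

Inference and cross-modality mapping of **multicellular transcriptional
programs** — patient-level axes of coordinated immune activation — for
systemic lupus erythematosus (SLE) and similar autoimmune settings.

Single-cell cohorts show that disease activation is not confined to one
cell type: interferon and NF-κB responses, cytotoxic expansion, and
naive/effector shifts engage many immune populations at once. This package
provides the full analytical chain for studying such programs, for
computational immunologists and methodologists who want a tested,
deterministic, desk-scale implementation:

1. **Pseudobulk construction and QC** — aggregate cell × gene counts per
   (cell type, sample); retain samples with ≥ 10 cells and ≥ 1,000 counts,
   genes with ≥ 10 counts in one sample and ≥ 15 total; batch-aware
   highly-variable-gene selection with marker-gene removal; CLR-transformed
   cell-type compositions with multiplicative zero replacement.
2. **Multi-group factor model** — per cell type *t*, gene loadings
   `w_t` shared across groups and sample scores `z_g` per group, fitted by
   truncated SVD of the standardized, concatenated views:
   `X_t ≈ z w_tᵀ`, with variance explained
   `R²(g, t, f) = 1 − SS_res/SS_tot` per factor, programs selected at
   `R² > 10%`, and covariate association (global R², per-factor η², F and
   t statistics, Bonferroni).
3. **Activity scoring (ULM)** — the activity of a weighted gene set in a
   profile is the slope *t*-statistic of the regression of the profile on
   the weight vector; `t = r√(m−2)/√(1−r²)`.
4. **Cell-type dependency networks** — ridge regression of each cell
   type's activity on all others (penalty by GCV, 5-fold held-out R²);
   directed edges are the β coefficients; condition comparison labels
   edges shared / HC-enriched / SLE-enriched with the opposite-sign and
   `|Δβ| < 0.1` rules.
5. **Coordinated signatures & ligand–receptor selection** — per-program
   gene signatures (`|w| ≥ 0.5` in coordinated or high-variance cell
   types, retained loadings averaged); LR quadruplet scores
   `√(ligand · receptor)` gated at 10% detection, filtered to network
   edges, kept at Pearson `r > 0.3`, `p < 0.05` against the program.
6. **Archetypal analysis** — principal-convex-hull archetypes
   (`min ‖X − S·A‖²`, simplex-constrained, monotone-descent solver),
   RBF cell weights with `ℓ = ½·median(centroid→archetype)`, convex-hull
   projection of patient means, OLS association with HC3 errors and
   BH-classified SLE/HC/neutral archetypes, cytokine-activity deltas and
   blood-protein linkage (`z > 0.2` in an SLE archetype and no HC one).
7. **Longitudinal flare risk** — remission-visit labelling
   (SLEDAI < 3; flare = ΔSLEDAI ≥ 4 within 91/182 days), Welch/Holm
   pre-flare testing, Cox proportional-hazards models (Breslow ties,
   Harrell's C, likelihood-ratio tests), per-gene hazard screens.
8. **Spatial co-localization** — binary 6-nearest-neighbour weights,
   bivariate global Moran's
   `I = (n/S0)·Σ wᵢⱼ(xᵢ−x̄)(yⱼ−ȳ)/√(Σ(xᵢ−x̄)²·Σ(yᵢ−ȳ)²)`,
   Davison–Hinkley permutation p (floor 1/101 at 100 permutations),
   Fisher combination across slides with a `|mean I| ≥ 0.10` gate,
   intra/para neighbourhood views with a random-forest learner, and
   glomerular enrichment tests.

A first-class **synthetic-data generator** (`sim_config()`,
`generate_*()`) plants known programs, dependencies, archetype couplings,
flare hazards, and spatial niches, so every stage is validated by
recovery and calibration rather than by inspection.

## Worked example

```r
library(mcprogram)
res <- run_patient_map_pipeline(seed = 1)
```

The pipeline simulates a 3-group, 60-sample cohort with one multicellular
and one cell-type-restricted planted program, then runs every stage:

```
> print(res$model)
factor_model: 10 factors, 5 views, 60 samples, 3 groups
> res$programs
[1] "Factor1" "Factor2"
> res$recovery[c("r_multicellular", "r_restricted")]
$r_multicellular  0.999
$r_restricted     0.986
```

Both planted programs are selected (strictly >10% variance explained in at
least one cell type), and the fitted scores correlate with the planted
group-centred scores at r = 0.999 and 0.986. The condition-specific
dependency networks recover the disease-gained coupling:

```
> head(res$edges[res$edges$class != "shared", ], 3)
  source target   beta_hc   beta_sle      delta        class
4    ct1    ct5 0.2115814 0.01053482 -0.2010466  HC_enriched
5    ct2    ct1 0.2676928 0.54028655  0.2725937 SLE_enriched
```

Program activity at a visit predicts time to the next flare
(planted log-hazard 1 per activity unit; the fitted coefficient is
attenuated because activity is re-estimated from noisy expression):

```
> res$longitudinal$cox
  covariate      beta       hr  lower95  upper95         se            p
1  activity 0.3173961 1.373546 1.246211 1.513893 0.04963781 1.613475e-10
loglik = -232.987, C-index = 0.758
```

And immune abundance co-localizes with program activity only on case
slides:

```
> res$spatial$colocalization[, c("condition", "mean_I", "p_combined", "significant")]
  condition      mean_I  p_combined significant
1      case  0.23661137 0.001002866        TRUE
2   control -0.01780734 0.420789802       FALSE
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mcprogram",
                               load_package = "installed")'
```

The suite contains per-module unit tests, property-style invariants
(aggregation conservation, filter idempotence, CLR identities, descent of
the archetype solver, projection idempotence, classification partitions),
independent oracles (brute-force Moran double sums, hat-matrix HC3,
partial-likelihood optimization, simplex-regression QP), and an
acceptance file covering planted-truth recovery and calibration for every
stage.

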