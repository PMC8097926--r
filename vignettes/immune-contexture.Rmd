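---
title: "Quantifying the immune contexture of tumor metastases from multiplex IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the immune contexture of tumor metastases from multiplex IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contexture)
library(tibble)
```

## The problem

Multiplex immunofluorescence immunohistochemistry (mIHC) stains several
markers on a single FFPE tissue section and, after spectral unmixing, cell
segmentation and phenotyping (all upstream of this package), yields one
record per cell: its position in micrometres, the tissue compartment it
lies in (tumor vs peri-tumoral stroma, delineated by a melanoma-cocktail
pseudo-marker), and a positivity call for each marker. In metastatic uveal
melanoma — where checkpoint inhibitors largely fail and no prognostic model
is in clinical use — the density, functional state and *spatial
arrangement* of T cells and macrophages around tumor cells carry prognostic
information that simple per-slide counts miss.

`contexture` implements the downstream quantitative layer of such a study
as a reusable, tested pipeline:

1. **IO**: read/validate per-cell tables (inForm-style headers via a column
   mapping) with per-field tumor/stroma areas, and assemble per-patient
   sample sets.
2. **Phenotyping and densities**: marker-combination rules (e.g. Treg =
   CD4+FoxP3+), compartment densities in cells/mm² and percentage metrics,
   aggregated per patient as the unweighted mean over fields.
3. **Spatial metrics**: mean nearest-neighbor distance between phenotype
   pairs and the fraction of reference cells within a fixed radius of a
   target phenotype.
4. **Prognostic constructions**: median dichotomization, CD8/CD4 and
   Treg/CTL ratios, the intra-/peri-tumoral (I/P) ratio, a four-indicator
   CD3/CD8 Immunoscore, CD3/CD68 concordance groups, and RECIST
   disease-control classification.
5. **Statistics**: Mann-Whitney comparisons, Spearman correlations with
   Fisher-z confidence intervals, Kaplan-Meier estimation, log-rank
   (Mantel-Cox) tests and univariable Cox hazard ratios.
6. **Synthetic cohorts**: a generator with known ground truth so that every
   stage is testable end to end without patient data.

## Per-patient aggregation

Every metric is computed **per field** and averaged, unweighted, over the
(at least 20) fields of the same slide. Fields can be invalid for one
metric and valid for another: a field with no tumor region is excluded from
intra-tumoral densities but still contributes stromal metrics; a field with
no parent cells is excluded from a percentage. Exclusions are always
tallied (`n_fields_excluded`) and an all-excluded metric is a flagged
missing value, never silently zero. The "total area" variant of a density
pools counts and areas — `(n_tumor + n_stroma) / (a_tumor + a_stroma)` per
field — rather than averaging the two compartment densities, so fields
dominated by one compartment are weighted by area, not by compartment.

Percentage metrics need a denominator. Where a parent phenotype is explicit
(activated CTL among CD8+ cells) we use it; for panel-composition plots the
parent defaults to *all phenotyped immune cells of the panel in the
compartment* (`parent = "any_immune"`), a configurable choice since
"% of cells" axes in this field are often ambiguous about their
denominator.

Cells positive for the melanoma cocktail are labelled `tumor` and never
receive immune labels: the cocktail exists to outline tumor cells, so
double-positives (e.g. melanoma+CD8+) are treated as tumor. All other
phenotyping is multi-label — a CD8+GranzymeB+ cell counts in both the
`CD8` and the `CD8_GrzB` populations, which keeps densities additive
across disjoint rules.

## Spatial metrics

Both statistics are 2-D, center-to-center, Euclidean, and confined to a
single field (fields are acquired without overlap, so cross-field
distances are undefined by design):

* `nearest_neighbor_mean_distance(field, ref, target)` — for each
  reference cell the distance to its nearest target cell, averaged over
  reference cells (µm).
* `fraction_within_radius(field, ref, target, r)` — the percentage of
  reference cells with **at least one** target cell at distance ≤ r. The
  boundary counts as *within* (≤), and target absence is a valid 0 %,
  not an exclusion. Preset radii are 20, 25 and 30 µm — the distance range
  at which two cells of lymphocyte/melanoma size have an enhanced
  probability of direct contact.

A cell is never its own neighbor when reference and target phenotypes
overlap. No edge-effect correction is applied; reference cells near the
field border therefore see a censored neighborhood, a small conservative
bias shared by both metrics and by the study design this package mirrors.
The implementation (vectorized distance matrix) is contractually required
to agree *exactly* — to floating-point equality — with an O(n·m)
brute-force loop, which the test suite enforces on 100+ random fields.

## Prognostic constructions

* **Median dichotomization**: high = strictly above the cohort median,
  low = at or below. The tie policy (median → low) makes "high" mean
  *strictly above the median*; with an odd cohort the median patient is
  low, and a degenerate all-equal metric yields all-low with a warning.
  Medians are recomputed on whatever cohort is passed in, so subgroup
  analyses (e.g. immunotherapy-treated patients only) automatically use
  subgroup medians.
* **Immunoscore (metastatic-melanoma variant)**: CD3 and CD8 densities in
  tumor and stroma, each dichotomized by its own median; the score is the
  number of high indicators, with classes I0 (0), I4 (4) and IntI (1-3).
  CD3 comes from panel 1 and CD8 from panel 2 — consecutive sections, so
  the four inputs are per-patient summaries, never merged cell tables.
  The colorectal percentile-based consensus Immunoscore is deliberately
  out of scope.
* **Concordance groups**: equal CD3/CD68 intra-tumoral labels
  (high/high or low/low) are "concordant", unequal "discordant".
* **Ratios** return missing (never ±Inf) on a zero denominator, because
  downstream rank tests cannot order infinities meaningfully.
* **DCR**: disease control = CR, PR or SD under RECIST 1.1.

## Statistical layer

The tests mirror small-cohort practice: raw two-sided p-values with no
multiple-testing correction, significance at p ≤ 0.05.

* Mann-Whitney: exact enumeration when n₁+n₂ ≤ 12 without ties (at most
  924 arrangements, deterministic); otherwise normal approximation with
  tie and continuity corrections.
* Spearman CI: Fisher z-transform with variance 1.06/(n−3), the standard
  adjustment for rank correlations. Published CIs from unspecified
  software may differ in the third decimal; we verify sign and nesting,
  not equality.
* Kaplan-Meier: product-limit estimator; events precede censorings at
  tied times; the median is the smallest time with S(t) ≤ 0.5 and is
  explicitly *undefined* when the curve never reaches 0.5.
* Log-rank: Mantel-Cox with hypergeometric variance, χ² on 1 df.
* Cox: univariable, Efron tie handling (median splits produce heavy
  ties), Wald 95 % CI on the log scale; monotone-likelihood separation is
  flagged with an unbounded CI rather than reported as a finite estimate.
  Multivariable models and proportionality diagnostics are out of scope.

## The synthetic-data generator

`sim_config()` defaults encode the emulated study design: 21 patients,
20 fields per slide and panel at 20X, tumor/stroma compartments, two
panels, a proportional-hazards link from patient features to overall
survival. Field dimensions default to 669 × 500 µm, a convention typical
of 20X multispectral platforms (the true dimensions are
platform-dependent and not part of the emulated design).

* **Geometry**: disc-shaped tumor nests with uniformly random centers;
  overlapping nests are unioned and discs are clipped at the field
  border. Compartment areas are computed analytically (disjoint,
  fully-interior discs) or by ~1 µm rasterization, so density
  denominators are exact and the realized density `count / area` is an
  unbiased estimator of the configured intensity — a property the tests
  check over replicate fields.
* **Placement**: independent homogeneous Poisson processes per
  (phenotype, compartment); marker columns are generated directly from
  the phenotype identity (noise-free by default; an optional
  misclassification rate swaps phenotypes before marker generation).
* **Proximity structure**: each target cell is independently re-placed,
  with probability `attracted_fraction`, uniformly within the placement
  radius of a random anchor cell. With background intensity near zero the
  recovered fraction-within-radius equals 100·f in expectation up to a
  small chance-proximity term (unmoved targets can still fall near an
  anchor by chance: probability ≈ 1 − exp(−λ_anchor·πr²), under 3 % at
  the intensities used in the tests).
* **Survival**: exponential event times with hazard
  h₀·exp(Σβ·feature); censoring is independent uniform over
  [0, horizon] applied to a Bernoulli-thinned subset of patients
  (probability = the configured rate) plus administrative censoring at
  the horizon, so the realized censoring fraction is at most slightly
  above the requested rate. This keeps the proportional-hazards structure
  intact.
* **Reproducibility**: one cohort seed; per-field seeds are a fixed
  arithmetic function of seed, patient index, panel and field index
  (kept below 2³¹), so any single field regenerates identically in
  isolation and cohorts are byte-identical across runs.

What the generator does *not* emulate — and hence what green tests do not
establish about real tissue: marker-intensity noise and segmentation
errors, spatial inhomogeneity of immune infiltration beyond the
nest/stroma dichotomy (no hotspots, no gradients), anisotropic or
membrane-to-membrane distances, correlated staining across consecutive
sections, and real cohort-level covariate structure. Recovery tests show
the estimators are correct under the stated model, not that the model is
tissue.

## Numerical and design choices

* Distances compared with ≤ at the radius boundary ("within a radius").
* Percentages and fractions are computed as `100·hits/n` in exact
  rational order so results match brute-force enumeration bit for bit.
* Coordinates are serialized with 6 decimals (sub-nanometre); compartment
  areas at full double precision in the file header, so IO round trips
  preserve all metrics.
* The reader is locale-independent: decimal points only, comma-decimal
  input is rejected with a row-indexed error instead of being misparsed;
  unknown tissue categories are rejected rather than guessed (upstream
  exports occasionally carry blank/glass classes).
* Problem sizes in the test suite are the package's own choices for tight
  feedback: oracle equivalence on 100 random fields of up to 500 cells,
  density recovery over 20 fields, Cox recovery at 200 patients per arm,
  type-I calibration over 250 log-rank replicates, and a scaled-down
  8-patient pipeline run for end-to-end checks; the full 21 × 20 × 2
  preset is exercised by `scripts/acceptance.R`.
* The exponential-median check averages the KM medians of three n = 500
  cohorts: at n = 500 a single cohort's median has ≈ 6.5 % relative
  sampling error, so averaging keeps the 10 % closed-form bound a ~3σ
  test instead of a coin flip.

## Known limitations

* No Ripley's K, pair-correlation functions or permutation null models —
  the proximity statistics are the two the emulated study uses.
* No edge correction (documented bias near field borders).
* Single-field analysis only; no slide-level stitching of coordinates.
* The Immunoscore here is the median-split variant; group sizes and
  survival contrasts from the 21-patient study itself depend on the
  unavailable clinical dataset and are not reproducible from synthetic
  cohorts.
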