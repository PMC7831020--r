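---
title: "Methods: voxel-wise mapping and outcome analysis of brain metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise mapping and outcome analysis of brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r}
library(bmmap)
```

This vignette documents the statistical methods implemented in **bmmap**,
the design of the synthetic-cohort generator used to exercise them, the
numerical conventions and tie-breaking rules, and the limitations of the
approach. All analyses assume binary lesion-segmentation masks that have
been registered to one common template grid.

## 1. Data model

A *grid* (`grid_spec()`) is the shared voxel lattice: an integer shape,
a per-voxel volume in mm^3^ (default 0.08 mm^3^, i.e. an isotropic
high-resolution template), and a 4x4 affine carried through to NIfTI
output. Every mask, map, and atlas in a run must live on the same grid;
mismatches are hard errors (`same_grid()`), never silent resampling.

A *lesion mask* (`lesion_mask()`, `read_mask()`) is one patient's binary
segmentation: any strictly positive voxel is lesioned. A *region atlas*
(`region_atlas()`, `read_atlas()`) is an integer label volume plus a
region table with `region_id`, `name`, `laterality`
(left/right/midline), and `compartment`
(supratentorial/infratentorial).

## 2. Lesion-level metrics

### 2.1 Connected components

Individual metastases are recovered from a binary mask by 3-D
connected-component labeling (`label_components()`), implemented as a
breadth-first search in C++. Connectivity may be 6 (faces), 18 (faces +
edges), or 26 (faces + edges + corners); labels are assigned
consecutively in column-major scan order, so labeling is deterministic.

The default is 26-connectivity, the most inclusive neighborhood: two
segmented voxels touching even at a corner are treated as one
metastasis. This matches the common `bwlabeln`-style convention for
lesion counting, but it is a genuine modeling choice: 26-connectivity
merges lesions that 6- or 18-connectivity would keep apart, which shifts
patients between number-of-metastases groups and changes per-lesion
volumes. Whether corner-touching components are one lesion or two is not
decidable from a binary mask alone; we therefore expose `connectivity`
as an argument throughout (`label_components()`, `simulate_cohort()`,
`extract_clusters()`) and treat the 26 vs 18 choice as an open question
a user can test on their own data rather than a settled fact.

### 2.2 Localization

Each component's centroid is the mean of its voxel coordinates
(voxel-center convention: voxel `(i, j, k)` spans
`[i-1, i) x [j-1, j) x [k-1, k)` in continuous coordinates). The
centroid is mapped to the voxel that contains it via
`ceiling(centroid - 0.5)`, with exact half-way ties resolved toward the
lower index. If that voxel is atlas background (possible for crescent-
or ring-shaped lesions), the lesion is assigned to the *nearest labeled
voxel* by Euclidean distance, with ties broken by lowest `region_id`
then lowest linear index. Assignment is therefore total and
deterministic: every lesion gets exactly one region.

`summarize_patient()` / `summarize_cohort()` derive, per patient: the
number of metastases, the number group (`1`, `2`, `3+`), total tumor
volume (TV), volume per single lesion (VSL = TV / count), and
infratentorial involvement (any lesion assigned to an infratentorial
region).

### 2.3 Group comparisons

`compare_groups()` compares a continuous lesion metric across patient
groups with the Mann-Whitney U test (2 groups) or the Kruskal-Wallis
test (3+), via `stats::wilcox.test()` / `stats::kruskal.test()`. For 3+
groups, Dunn's post-hoc test on mean ranks is applied with a tie
correction and Bonferroni adjustment by default (`dunn_test()`); Dunn's
test is implemented in-package because no installed dependency provides
it, and it is validated in the test suite against the Kruskal-Wallis
machinery and hand-computed cases.

## 3. Voxel-wise mapping statistics

### 3.1 Frequency maps

`frequency_map()` sums the binary masks of a cohort voxel-wise,
yielding the number of patients lesioned at each voxel.

### 3.2 ADIFFI: analysis of differential involvement

For two phenotype groups A (n~A~ patients) and B (n~B~ patients),
`adiffi_map()` builds, at every voxel x, the 2x2 table

|            | lesioned at x | lesion-free at x |
|------------|---------------|------------------|
| group A    | a             | n~A~ - a         |
| group B    | b             | n~B~ - b         |

and computes a two-sided Fisher exact test. The two-sided p-value uses
the *point-probability rule*: with the hypergeometric point
probabilities `dhyper(k, nA, nB, a + b)`, it sums all outcomes whose
probability does not exceed that of the observed table, using a
relative tolerance of `1e-7` on the observed probability so that
floating-point noise cannot drop exactly-tied tables. This is the same
convention as `stats::fisher.test()`, but the per-voxel computation is
vectorized over the unique `(a, b)` pairs actually present in the maps,
which makes whole-brain maps cheap (the number of distinct tables is at
most `(nA + 1)(nB + 1)`, regardless of grid size). Degenerate voxels
(`a + b == 0`, or every patient lesioned) are defined to have p = 1 and
direction 0. Each voxel also gets a direction:
`sign(a/nA - b/nB)`, i.e. which group is relatively more often
lesioned there. Optional Benjamini-Hochberg adjustment across
non-degenerate voxels is available (`fdr = TRUE`).

`extract_clusters()` thresholds the p-map at `alpha`, splits the
surviving voxels by direction, labels connected clusters per direction,
and reports for each cluster its size, peak voxel (minimum p, ties to
the lowest linear index), dominant atlas region, and the fraction of its
voxels in infratentorial / supratentorial / background territory,
ordered by decreasing size.

### 3.3 Relative metastatic risk (RMR)

For region x with volume V~x~, let N~x~ be the number of *patients*
(not lesions) with at least one centroid-assigned lesion in x, and N~p~
the cohort size. With R regions,

RMR~x~ = (N~x~ / N~p~ / V~x~) / ( (1/R) * sum~i~ N~i~ / N~p~ / V~i~ ),

i.e. each region's patient-level involvement density, normalized so
that the mean RMR over regions is exactly 1. Values above 1 indicate
more involvement than expected for the region's size. The mean-1
invariant is exact by construction and is asserted over random cohorts
in the test suite. Regions with zero volume, or a cohort with no
lesions at all, are errors rather than NaN propagation.

## 4. Survival analysis

`km_estimate()`, `logrank_test()`, and `cox_regression()` wrap the
**survival** package (`survfit`, `survdiff`, `coxph` with Efron tie
handling) and return tidy tables (hazard ratios, 95% CIs, p-values) in
both univariate and multivariate modes. `build_strata()` converts
patient records and lesion summaries into analysis strata:

* continuous variables (age, TV, VSL, Ki-67) are split at the cohort
  median, with values *equal to* the median going to the upper group;
  external medians can be supplied to reproduce a fixed stratification;
* reference levels are the a-priori lower-risk categories: younger,
  female, lung primary, one metastasis, smaller TV, no infratentorial
  involvement, no radiotherapy;
* radiotherapy means any WBRT or SRS component in the treatment string;
* an all-missing Ki-67 column yields a warning and an omitted stratum
  rather than an error.

A covariate that is constant in the data is a hard error in
`cox_regression()` (the model is unidentifiable), and `coxph` warnings
(e.g. monotone likelihood) are passed through, not suppressed.

## 5. The synthetic cohort generator

The generator exists so that every statistical routine above can be
tested end-to-end, at realistic scale, with *known* ground truth. It is
deliberately simple; it emulates the data-generating structure the
statistics assume, not brain anatomy.

### 5.1 Toy atlas

`build_toy_atlas()` places an ellipsoidal "brain" on the grid (default
24^3^). Axial slices with `z < floor(fraction * shape[3])` (default
fraction 0.25) form the infratentorial compartment. Within the
infratentorial zone a midline slab (`|x - cx| < max(1, shape[1]/12)`)
is split into the requested midline regions (default 2, a vermis- and
brainstem-like pair); the remaining foreground is divided into
left/right lateral region pairs (default 8), allocated to the two
compartments proportionally to their voxel counts with at least one
infratentorial pair when the cut is positive. The default therefore
yields 18 regions with mirror-symmetric lateral pairs and exact
left/right homologues, so laterality contrasts have a ground truth.

### 5.2 Lesion counts, placement, and geometry

`cohort_spec()` collects all generator parameters; defaults and their
rationale:

* **Counts.** Number of metastases per patient is 1 or 2 with
  probabilities 0.494 and 0.170; with probability 0.336 the patient
  has `3 + rgeom(p = 0.137)` lesions. `tail_geom_p = 0.137` was chosen
  so the expected count is about 3.96 lesions/patient, matching large
  clinical brain-metastasis cohorts (on the order of 4 x 10^3^ lesions
  per ~1.1 x 10^3^ patients); the geometric tail gives the long right
  tail such cohorts show.
* **Placement.** Each lesion center is drawn voxel-wise with
  probability proportional to its region's weight
  (`region_weights`, default uniform), so the chance of landing in
  region r is `w_r V_r / sum_i w_i V_i`. Weights let tests plant a
  known topographic preference (e.g. an infratentorial excess) and
  verify that ADIFFI and RMR recover it.
* **Geometry.** Lesions are spheres with radius drawn from
  `radius_range` (default 2-4 voxels), rasterized by the Euclidean rule
  and clipped to the *placeable* foreground (the union of
  positive-weight regions). Clipping makes zero-weight contracts exact:
  with zero infratentorial weight no voxel below the tentorial cut is
  ever lesioned. The 2-4 voxel default on a 24^3^ grid was fixed a
  priori by a power argument: it keeps the lesion-to-brain volume ratio
  in the range of real metastases while leaving enough per-voxel
  overlap across 100-patient groups for the planted-effect detection
  checks to be well powered. It was not tuned against test outcomes.
  Overlapping spheres from one patient merge into a single connected
  component, exactly as overlapping real lesions would in a binary
  mask; the generator therefore also returns the drawn placements so
  that drawn and measured distributions can be compared.
* **Covariates.** Sex, primary tumor class, lung subtype, Ki-67
  fractions (Beta-distributed), and treatment categories are drawn from
  published-cohort-like categorical distributions (`p_male = 0.605`,
  86.1% lung primaries, treatment known for 36.5%, etc.); they give the
  demographic and survival machinery realistic inputs.

### 5.3 Survival times

Overall survival is exponential with baseline hazard
`log(2)/12` per month (12-month median for the reference patient),
multiplied by `exp(log-HR)` terms: 1.473 for infratentorial
involvement, 1.142 for exactly two metastases, 2.132 for three or more.
Crucially, the hazard is computed from the *measured* covariates — the
number group and infratentorial flag obtained after rasterization,
merging, and labeling — not from the drawn placements. This keeps
parameter recovery well defined: the hazard ratio the Cox model
estimates is exactly the one that generated the data, even when sphere
merging changes a patient's lesion count. Censoring is uniform on
`[0, censor_horizon]` (default 60 months), the standard uniform-accrual
model whose single parameter is the administrative horizon; it yields a
censoring fraction comparable to multi-year clinical cohorts.

### 5.4 What the generator does and does not emulate

It emulates: a shared template grid, multifocal binary lesion masks,
region-structured placement preferences, count/volume distributions
with realistic scale, covariates with clinical marginals, and survival
with known proportional hazards. It does **not** emulate: brain
anatomy beyond an ellipsoid with a tentorial cut, non-spherical or
infiltrative lesion shapes, registration or segmentation error,
correlated lesion locations within a patient, covariate-dependent
placement, time-varying hazards, or informative censoring. Results on
synthetic data validate the *software and statistics*, not any clinical
claim.

## 6. Pipeline and reproducibility

`run_pipeline()` executes the full analysis — simulate, lesion metrics,
frequency map, ADIFFI (between a covariate split, default sex), RMR,
survival, demographic summary — from a single `run_config()` (or a YAML
file via `read_run_config()`), writing CSV tables, uncompressed NIfTI
volumes (masks as uint8), and a `manifest.json` with MD5 hashes of every
output. One seed determines the entire run; reruns with the same
configuration are byte-identical, which the test suite asserts.
Uncompressed NIfTI is deliberate: gzip output embeds no byte-level
determinism guarantee worth relying on. Demographic percentages are
rounded half-up to one decimal (`round_half_up()`), the convention of
clinical tables, rather than R's banker's rounding.

```{r, eval = FALSE}
cfg <- run_config(out_dir = "run1", seed = 17, n_patients = 60)
manifest <- run_pipeline(cfg)
```

A command-line entry point with per-stage subcommands ships at
`system.file("cli", "bmmap.R", package = "bmmap")`.

## 7. A small end-to-end example

```{r}
atlas <- build_toy_atlas(c(16, 16, 16), n_lateral_pairs = 3,
                         n_midline = 1, voxel_volume = 1)
co <- simulate_cohort(cohort_spec(n_patients = 30, radius_range = c(1, 2),
                                  seed = 7), atlas)
head(co$summaries[, c("patient_id", "n_lesions", "number_group",
                      "tv_mm3", "infratentorial_involvement")])
rmr <- relative_metastatic_risk(co$lesions, atlas, nrow(co$records))
mean(rmr$rmr)  # exactly 1 by construction
st <- build_strata(co$records, co$summaries)
cox_regression(st, "infratentorial", mode = "univariate")
```

## 8. Limitations

* Centroid-based region assignment attributes a large lesion to a
  single region; lesions straddling boundaries are not apportioned.
* ADIFFI tests each voxel marginally; the cluster step controls nothing
  beyond the per-voxel level unless `fdr = TRUE` is used, and no
  spatial permutation-based cluster inference is implemented.
* RMR uses patient-level involvement, so a region seeded many times by
  one patient counts once; this is intentional but differs from
  lesion-density measures.
* The connectivity convention (Section 2.1) materially affects lesion
  counts; analyses should report which was used.
* The generator's independence assumptions (Section 5.4) make it
  unsuitable for estimating clinical effect sizes; it is a test harness.
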