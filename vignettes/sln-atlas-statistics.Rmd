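---
title: "Drainage, prevalence and CTV-coverage methods for breast SLN cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drainage, prevalence and CTV-coverage methods for breast SLN cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnatlas)
```

## The data model

The unit of analysis is the **tumour**, not the patient. A cohort row
carries a patient id, side, clockface breast region (0 = retroareolar,
1–12 o'clock), tumour-to-nipple distance in cm, and the set of node fields
containing SLNs (semicolon-separated over a closed 12-label vocabulary,
`node_fields()`). A patient id may appear twice — bilateral tumours on
opposite sides — and the two drainage systems are analysed independently;
the bootstrap, however, resamples *patients*, so a bilateral patient's two
tumours always travel together.

Preprocessing applies, in order:

1. **Retroareolar rule** — tumours at most 1 cm from the nipple are
   reassigned to region 0, boundary inclusive.
2. **Reflection** — drainage and prevalence are left–right symmetric, so
   right-sided records are mirrored into the left-breast frame:
   `h → 12 − h` for `h` in 1–11; 0 and 12 lie on the mirror axis. Node
   field labels are side-agnostic.
3. **Enrolment filter** — tumours with no drained fields (no SLNs seen on
   planar imaging, so no SPECT/CT) are dropped.

`build_contingency()` reduces a cohort to the 13 × 12 table of per-region
field counts plus region totals. Drainage is multi-label: a tumour
draining to three fields increments three cells but its region total by
one, so column sums may exceed the number of tumours.

### The bundled reference table and its record-level reconstruction

`anmu_contingency()` ships the reference cohort's marginals (869 tumours,
861 patients). Because the underlying patient-level drainage sets are not
available, `anmu_cohort()` provides a deterministic *synthetic
reconstruction*: each region's field memberships are laid down cyclically
so every marginal cell is matched exactly and every record keeps at least
one drained field (possible because every region's column sum is at least
its region total). Every single-field statistic — all drainage and
prevalence estimates in this package — depends only on these marginals and
is therefore exact. Joint-drainage quantities (co-occurrence of two
fields) are *not* identified by the marginals and must not be read off the
reconstruction.

## Interval methods

All three drainage methods consume the same `(n, N)` cell counts:

* **Conjugate Bayesian.** Uniform `Beta(1, 1)` prior, binomial likelihood,
  posterior `Beta(n + 1, N − n + 1)`; the point estimate is the posterior
  mean and the interval the equal-tailed 95% credible interval, evaluated
  in closed form with `qbeta`. Computing the posterior exactly rather than
  by MCMC removes Monte-Carlo error and makes the output deterministic;
  the identical model is retained.
* **Patient-level bootstrap.** `B = 10,000` replicates by default; each
  replicate resamples the patient list with replacement and recomputes the
  proportion among the replicate's tumours (a ratio estimator, since
  bilateral patients change the denominator). The interval is the simple
  2.5/97.5 percentile interval — no bias correction or acceleration — and
  the point estimate the mean over replicates. A tumour-level resampling
  unit is available for sensitivity checks. Every call takes an explicit
  seed.
* **Logit-scale Wald.** The saturated logistic fit reproduces the observed
  proportion per cell, so the interval is
  `logit(p̂) ± z·√(1/n + 1/(N − n))` back-transformed. Building the
  interval on the log-odds scale (rather than `p̂ ± z·SE`) keeps bounds
  inside `[0, 1]` and matches the reference results. Cells with `n = 0` or
  `n = N` have undefined log-odds; the defined-side bound is replaced by
  the exact one-sided Clopper–Pearson binomial bound and the row is
  flagged `degenerate`.

For tumour prevalence the trio is the flat-Dirichlet conjugate posterior
(marginal `Beta(n_r + 1, N − n_r + 12)` intervals), the same patient-level
bootstrap applied to the full 13-vector of proportions, and
**Sison–Glaz simultaneous intervals**. The Sison–Glaz procedure
approximates the probability that every category count of a multinomial
draw stays within `± c` of its observed value, by representing the
multinomial as independent Poissons conditioned on their sum: the
truncated-Poisson moments are computed exactly by direct summation over
each truncation range, the conditioned-sum probability by a fourth-order
Edgeworth expansion. The smallest integer `c` whose approximate coverage
reaches the level is found by scanning upward from 1 (the fixture needs
`c ≈ 25`, so the scan is cheap); the deficit is interpolated linearly,
giving every category the interval `[p̂_r − c/N, p̂_r + c/N + 2γ/N]`
clamped to `[0, 1]`. All 13 pre-clamp widths are identical by
construction; low-count regions clamp their lower bound at 0. Fully
degenerate inputs (all mass in one category) reach the level at `c = 0`
and get zero widening rather than a division-by-zero.

For well-populated cells (at least ~20 events in ~100 tumours) the three
methods agree to within one percentage point in mean and bounds, which the
test suite asserts; they diverge, as expected, for rare fields where prior
mass (Bayesian), resampling discreteness (bootstrap) and the Wald
approximation (regression) behave differently.

### Rounding

Reported tables round half-up at 1 decimal place in percent, at the
presentation layer only (`round_half_up()`); every internal value is kept
at full precision. Comparisons against reference cells are made at the
printed precision at the final step.

## CTV coverage geometry

Masks are binary voxel labelmaps with physical metadata (anisotropic
spacing in mm, origin, orthonormal direction matrix), read and written as
NIfTI via RNifti in their stored orientation. SLNs are 5 mm-diameter
spheres at annotated centroids in the masks' physical frame.

* **Volume fraction.** A fixed symmetric cubic lattice (20 points per
  axis, ~4,200 points after restriction to the sphere) is rotated once by
  a fixed generic rotation and mapped through the physical-to-index
  transform with nearest-neighbour lookup; the fraction is the share of
  lattice points inside the mask union. The generic rotation prevents the
  lattice planes from aligning with voxel-grid planes, so the estimate
  varies smoothly with the cut position; against analytic spherical-cap
  truth the error stays below 0.02, and refining the lattice (20 → 32 per
  axis) moves any fraction by less than 0.01. The estimate is seed-free
  and bit-reproducible.
* **Classification.** Covered means *strictly* more than half the volume
  inside; a fraction of exactly 0.5 is not covered.
* **Distance.** Non-covered SLN centroids report the minimum, over the
  scope's masks, of the physical-space distance to the nearest foreground
  voxel centre (zero if the containing voxel is foreground). For an
  outside point the nearest foreground voxel is a boundary voxel, so this
  is the boundary distance at voxel resolution (half-voxel accuracy); the
  test suite checks exact agreement with an exhaustive voxel search. A
  non-covered SLN whose centroid nevertheless falls inside a mask (the
  fraction can be ≤ 0.5 with the centre inside for thin structures)
  contributes distance 0 and is counted separately in the report.
* **Scopes and sides.** Each SLN is scored against the CTVs corresponding
  to its node field (`default_correspondence()`: the four non-
  interpectoral axilla level I subfields → L1, interpectoral → INTPECT,
  axilla II/III → L2/L3, supraclavicular → L4, internal mammary →
  IMN + IC4) and against all CTVs on its side; left and right are scored
  independently and merged for the "both" rows. Mediastinal, interval and
  contralateral fields have no corresponding CTV and are excluded from
  scoring (counted in the report's `excluded` attribute). The SD of
  non-covered distances is omitted when exactly one SLN is non-covered,
  and distances are omitted entirely when none is.

## Registration QC

`landmark_errors()` computes Euclidean distances between same-named
landmarks of two sets in a common frame (typically 13 skeletal landmarks;
the name list is configuration, not code). `interobserver_summary()`
pools per-landmark distances over shared subjects for every observer pair.
The pooled aggregation (all distances together) is the default; per-
subject means can be derived from the per-landmark output if wanted.
`select_reference_by_scapula()` picks the subject with the median scapula
length — a body-height predictor — using the lower middle value for even
counts so a real subject is always chosen, with lexicographic tie-breaks.

## The synthetic-data generator

`simulate_cohort()` is the generative counterpart of the estimation
models: patient sides are Bernoulli(right fraction ≈ 0.48), a patient is
bilateral with probability 8/861, tumour regions are multinomial over the
13 regions, and drainage to each of the 12 fields is an independent
region-conditional Bernoulli. Defaults equal the reference cohort's
observed conditions (861 patients; region probabilities and the 13 × 12
drainage matrix taken from the bundled contingency proportions). Tumours
drawing zero drained fields are redrawn, encoding the enrolment filter;
consequently the *effective* per-field probability is the matrix entry
divided by the region's enrolment probability `1 − Π(1 − p_rf)`, and the
parameter-recovery study evaluates interval coverage against these
conditional values. Cells whose true probability is exactly zero are
excluded from the coverage study: an equal-tailed `Beta(1 + x, n − x + 1)`
interval has a strictly positive lower bound for every `x`, so zero can
never be covered — a property of equal-tailed intervals at boundary
parameters, not an implementation artefact.

Two structural simplifications matter when reading test results. First,
field-wise independence within a tumour is an assumption — only marginals
are identified by the reference data, so the generator's joint structure
is a knob that defaults to independent; passing recovery tests therefore
validate marginal estimation only. Second, geometric CTVs are boxes,
spheres and half-spaces rather than anatomical contours; the analytic
ground truth (nearest-surface spherical-cap fraction, exact surface
distances) is exact for half-spaces and for placements where at most one
face cuts the sphere, which the bundled scenarios respect. Neither
simplification affects real-data use, where masks and points are supplied
by the user.

`simulate_geometry()` rasterises the primitives to labelmaps while
computing truth from the primitives themselves, so the voxel pipeline is
validated against an oracle that never touches the rasterisation. SLNs
whose analytic fraction falls within ±0.03 of the 0.5 threshold are
excluded from classification comparisons — there the voxel and analytic
answers may legitimately differ.

## Problem sizes and runtimes

The test suite uses the cohort-scale defaults throughout: the full
869-tumour fixture for table reproduction, `B = 10,000` bootstrap
replicates for the reference columns (smaller `B` for pure-property
checks), 2,000 multinomial draws for the Sison–Glaz simultaneous-coverage
check, 500 simulated cohorts for the Bayesian parameter-recovery study,
and 64³-or-smaller voxel grids for geometry. The complete suite runs in
about two minutes on a single CPU.

## Known limitations

* The bundled record-level cohort is a marginal-matching reconstruction;
  joint-drainage statistics computed from it are meaningless.
* Sison–Glaz coverage is an Edgeworth approximation; its simultaneous
  coverage is near-nominal (the suite checks ≥ 0.93 at the fixture's
  parameters) but not exact.
* Boundary distances are reported at voxel resolution (half-voxel
  accuracy); subvoxel surface models are out of scope.
* Image registration itself (linear/deformable), segmentation, and
  DICOM/SPECT ingestion are out of scope; masks, points and landmark
  tables are the input contracts.
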