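---
title: "Dental crown shape at the enamel-dentine junction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental crown shape at the enamel-dentine junction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edjmorph)
```

## What the package models

A tooth crown is described by three landmark sets digitised per specimen: the
apices of the dentine horns (fixed landmarks; two in premolars, four in
molars, none in anterior teeth), an ordered ring of samples along the EDJ
marginal ridges, and an ordered ring along the cervix (CEJ). The analysis
requires *geometric homology*: the same number of landmarks in corresponding
positions on every specimen of a tooth class. `edjmorph` establishes it in two
stages — deterministic resampling, then statistical sliding — and provides the
group-comparison statistics used downstream.

### Curve homology

Each raw ring is interpolated by a periodic cubic spline (one spline per
coordinate, chord-length knot spacing, `stats::splinefun(method =
"periodic")`). Homology is expressed in arc length:

* The ridge ring is split at the arc-length projections of the fixed
  landmarks, taken in cusp order. The fixed landmarks themselves are **not**
  moved onto the curve; only their projections define section boundaries, so
  digitised apices are preserved exactly. Projections that do not follow the
  cusp order raise a "section order violation" error rather than silently
  producing crossed sections.
* Each section is resampled at equal arc-length spacing with the boundary
  points *excluded* (spacing `L/(n+1)`); the fixed landmarks own the
  boundaries, and exclusion keeps the totals exactly at 87 (premolar),
  124 (molar) and 40 (anterior).
* The CEJ ring is resampled to 40 points at spacing `L/40` *including* the
  digitised start point as landmark 1: the protocol fixes a biologically
  meaningful start location (mid-buccal, or the mesiobuccal corner in lower
  molars), so the start point is itself treated as homologous.

Arc length is tabulated on a dense 4096-sample polyline per curve. On
crown-scale rings this keeps arc-length errors well under 0.1% (the test suite
checks an 8-point circle's circumference to 0.5% and resampling equidistance
against a 100,000-sample oracle to 0.1%). Point projection is a dense-table
search refined by 1D minimisation; exact ties on the table resolve to the
smallest parameter.

### Superimposition and sliding

Generalised Procrustes analysis centres every configuration, scales it to unit
centroid size, and iteratively rotates each to the current mean (Kabsch
solution constrained to determinant +1: reflections are never used, which is
why antimeres must be mirrored to the right-side convention *before*
analysis). Convergence is declared when the mean shape changes by less than
1e-10 (at most 100 iterations). After convergence the whole sample is rotated
into a canonical principal-axes orientation of the mean with a deterministic
sign rule, which makes the output unique — and therefore invariant to input
order — rather than merely unique up to rotation.

Semilandmarks (all ridge and CEJ landmarks) are slid to minimise the bending
energy of the thin-plate-spline interpolant between each specimen and the
current Procrustes mean. Numerical notes:

* 3D TPS kernel `U(r) = r`. The k×k bending block of the inverted TPS system
  is negative semidefinite in this orientation, so the package negates it:
  the resulting quadratic form is positive semidefinite with exactly the
  4-dimensional affine null space, and the sliding step is a genuine
  minimisation. Only the quadratic form enters any computation, so this is a
  sign convention, not a model change.
* Each semilandmark moves along a single tangent direction (curve sliding,
  no surface sliding), estimated by central differences over its ring
  ordering; the ridge ring interleaves the fixed cusps with their sections,
  the CEJ ring is closed on itself.
* The amplitudes solve one symmetric linear system per specimen (the bending
  block restricted to sliding landmarks, Hadamard-multiplied by the tangent
  Gram matrix); a ridge-regularised solve with a logged jitter is the
  fallback for singular systems.
* Displacements are capped at half the local inter-landmark spacing per
  round. The closed-form step is exact only in the linearised (small
  displacement) regime, and re-projection assumes the slid point is still
  nearest to its own neighbourhood of the curve; the cap enforces both.

The full protocol is GPA → slide → re-project onto each specimen's own spline
→ GPA → slide → re-project → final GPA: exactly two sliding rounds, after
which landmarks are treated as geometrically homologous shape coordinates.

### Statistics

* **PCA** of the flattened aligned coordinates, with a deterministic axis
  sign (largest-magnitude loading positive). Extreme shapes along an axis are
  `mean ± c·sqrt(eigenvalue)·axis`, conventionally at c = 1.5, for wireframes.
* **CVA** on the leading `n_pcs` PC scores (candidates 5–10, so the number of
  variables stays below the number of specimens). Canonical axes are scaled
  to unit pooled within-group variance, so Euclidean distance in canonical
  space is Mahalanobis distance. The leave-one-out variant refits the CVA
  without each specimen to expose spurious separation; the candidate count
  with the best cross-validated accuracy is selected, ties resolving to fewer
  PCs (a 5–10 sweep is exactly 6 CVA fits).
* **Typicality probabilities** use the chi-square upper tail of the squared
  Mahalanobis distance with df = the canonical-space dimension. The
  small-sample F variant exists in the literature; the chi-square form is the
  default here for determinism and because the conservative 0.1 threshold is
  conventionally applied to it. A specimen whose typicality is below 0.1 for
  every group is "unclassified".
* **Permutation tests** compare two groups from one joint superimposition:
  the shape statistic is the Euclidean distance between group-mean coordinate
  vectors (monotone in the Procrustes distance between means — the procedure
  names no statistic, so this choice is recorded here); the size statistic is
  the absolute difference of mean CEJ centroid sizes. The p-value convention
  is `(b + 1)/(m + 1)` with `>=`, so permutations that recreate the original
  split tie the observed value and the attainable floor is slightly above
  `1/(m + 1)`. Seeds are mandatory; the full-analysis default is 10,000
  permutations (tests use smaller, explicitly stated counts).
* **FDR control**: one Benjamini–Hochberg pass per test family (shape, size)
  across tooth positions. The family structure is not prescribed by the
  protocol; keeping the two families separate is this package's choice and is
  configurable through which p-values are passed to `benjamini_hochberg()`.
* **Conspecificity limits**: Procrustes distance between specimens is
  operationalised as the Euclidean distance between jointly superimposed
  coordinate vectors (not per-pair re-superimposition); on low-variance
  samples the two agree to well under 1% (tested against a per-pair oracle).
  The 95% limit is the type-7 interpolated percentile.

### Dentine body height

Relative dentine body height (DBH) is the distance between the centroid of a
marginal-ridge landmark subset (mesial + distal; on lower molars the distal
subset is split into two runs flanking the hypoconulid position) and the
centroid of matching cervix subsets, computed on unit-centroid-size
superimposed coordinates — a shape-relative, not absolute, measure. The exact
subset indices were chosen per tooth position in the original protocol but
never published; they are therefore *configuration*, not code.
`default_dbh_spec()` supplies defaults centred on the mid-points of the
mesial and distal ridge sections of the synthetic template (5 landmarks per
side; 6 on lower molars so the flanking halves are equal), and any analysis
that depends on other subsets should construct its own `dbh_spec()`.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be exercised against
known ground truth. A template models one tooth class as:

* a cervix ring with superellipse-like radius (`r0 = 4.5` mm, exponent 2.5,
  mesiodistal elongation 1.15) and a small vertical sinusoid (0.15 mm) —
  a closed, non-circular, realistic CEJ outline;
* a ridge ring at height `H` (dentine body height, default 2.8 mm, radius
  0.62 of the cervix) carrying Gaussian dentine-horn bumps (default heights
  2.0–1.4 mm, angular sd 15°) whose analytic maxima are the fixed cusp
  landmarks — the narrow width keeps the horn tails negligible at the
  mid-ridge DBH subsets, so the noiseless DBH is within 2% of `H/CS`;
* an optional radial reduction of the distal ("talonid") sector.

Specimens are realised by sampling the rings (36 raw points each, with the
ridge grid passing exactly through the cusp angles), applying a log-normal
isotropic scale (sd 0.05), iid Gaussian landmark noise (default sd = 2% of
the cervix radius, which keeps sliding in its small-displacement regime), and
a random rigid pose. Left-sided specimens are emitted in the left digitising
convention to exercise `mirror_to_right()`. Generation is a pure function of
(specification, seed); cohorts are written to disk in the package's TPS
dialect with a manifest and a ground-truth JSON record.

What the generator does **not** emulate: occlusal-basin and lateral-face
morphology (only the two rings and horn apices are modelled), wear,
digitisation error that is correlated along curves rather than iid, missing
data, and within-group covariance structure beyond isotropic noise plus size
variation. Passing tests therefore demonstrate the correctness of the
algorithms and their calibration under the stated generative conditions — not
that real dental samples satisfy those conditions.

`two_taxon_benchmark()` encodes the canonical contrast (relative body-height
increase plus talonid reduction in the derived group), and
`extant_analog_cohort()` provides three single-species reference groups
(chimp-, gorilla- and human-like in size and relative body height) for
conspecificity-limit analyses with planted outliers.

## Statistical calibration choices

The Monte-Carlo calibration of the permutation tests
(`null_permutation_calibration()`) runs 200 replicate null cohorts of 10 + 10
anterior teeth with 999 permutations each through the homologisation + GPA
path. Sliding is omitted there deliberately: it is blind to group labels, so
it cannot affect exchangeability under the null, and omitting it keeps the
simulation light; the anterior (CEJ-only) class is used for the same reason.
The problem sizes in the acceptance script (cohorts of 30, reference samples
of 12 per group, 999 permutations, 200–500 Monte-Carlo replicates) are the
package's chosen desk-scale study conditions; the full-analysis defaults
(10,000 permutations, PC candidates 5–10, typicality threshold 0.1) are used
wherever a single analysis rather than a calibration loop is run.

## Known limitations

* Curve sliding only; surface semilandmarks are out of scope.
* Sliding minimises bending energy, as specified; a Procrustes-distance
  sliding criterion is not implemented.
* The pipeline assumes one joint superimposition per tooth position; per-pair
  re-superimposition is available only as a test oracle. Whether pooled-group
  tests should deduplicate antimeres or multiple teeth per individual is a
  study-design question; the manifest keys make such filtering easy but the
  pipeline does not presume it.
* The DBH defaults are tied to the synthetic template's angular conventions;
  on real data the subsets must be chosen anatomically per tooth position.
* The digitising direction of rings relative to cusp order is taken from the
  manifest convention (start point, continuing mesially); files digitised
  under another convention must be re-ordered on import.
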