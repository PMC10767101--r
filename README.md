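# edjmorph

Geometric morphometrics of dental crown shape at the enamel–dentine junction.

## The problem

The enamel–dentine junction (EDJ) — the surface of the dentine crown beneath
the enamel cap — preserves taxonomically informative crown morphology even in
moderately worn teeth, because it forms early in development and is never
remodelled. Comparative dental studies therefore characterise crown shape with
3D landmarks on the EDJ marginal ridges and dentine horn apices, together with
the closed outline of the cervix (the cementum–enamel junction, CEJ), and ask
questions such as: which shape features separate two taxa; does a questioned
specimen classify with any of the candidate groups; and does the difference
between two specimens exceed the variation expected within a single species?

`edjmorph` implements that analysis pipeline end to end for users in
evolutionary morphometrics and palaeoanthropology:

1. **Curve homology.** Raw digitised curves (an EDJ marginal-ridge ring, a CEJ
   ring) are converted into fixed-count, geometrically homologous landmark
   sets: a periodic cubic spline is fitted through each ring, the ridge ring
   is split into sections at the arc-length projections of the dentine-horn
   landmarks (two sections in premolars, four in molars), and each section is
   resampled equidistantly (premolars 20 + 25, molars 20 per section; 40
   landmarks on every CEJ ring; totals 87 / 124 / 40 landmarks for premolars,
   molars and anterior teeth).
2. **Superimposition.** Generalised Procrustes analysis (GPA) removes
   location, scale and orientation; curve landmarks are treated as
   semilandmarks and slid along their local tangents to minimise the
   thin-plate-spline bending energy against the Procrustes mean shape, in two
   rounds with re-projection onto each specimen's spline after each round.
3. **Statistics.** PCA of shape coordinates (with wireframe shapes at ±1.5 SD
   along a component); canonical variate analysis on a 5–10 PC subset with
   leave-one-out cross-validation and chi-square typicality probabilities
   (threshold 0.1 → "unclassified"); seeded permutation tests for mean shape
   and centroid-size differences (p = (b+1)/(m+1)); Benjamini–Hochberg FDR
   control across tooth positions.
4. **Conspecificity limits.** Pairwise Procrustes-distance and relative
   dentine-body-height (DBH) difference distributions within and between
   groups, with 95% within-group limits; DBH is the distance between the
   centroid of mesial + distal marginal-ridge landmark subsets and the
   centroid of matching cervix subsets, on unit-centroid-size shapes.
5. **Synthetic cohorts.** A parametric tooth generator (superellipse cervix
   ring, Gaussian dentine-horn bumps, body height, talonid reduction) with
   full ground truth, so every stage is testable without any scan data.

## Worked example

Simulate a two-taxon premolar contrast (a 20% relative dentine-body-height
increase plus talonid reduction in the derived group) and run the full
pipeline:

```r
library(edjmorph)

bench  <- two_taxon_benchmark(delta_h = 0.2, n_per_group = 10, seed = 99,
                              dir = tempfile())
config <- run_config(bench$manifest, n_perm = 999, pc_candidates = 3:5,
                     seed = 100)
report <- run_analysis(config)
summ   <- report_summary(report)

summ$significance
#>                    position shape size
#> mandibular P3 mandibular P3   sig   ns

pos <- report$positions[["mandibular P3"]]
pos$shape_tests[["derived vs primitive"]]
#> <permutation_test> mean shape distance = 0.0700294, p = 0.001 (999 permutations, seed 1102)

pos$cva
#> <cva_result> 2 groups, 3 PCs, 1 canonical axes, resub acc 1.000, LOO acc 1.000

summ$limits
#>        position     group n_pairs    limit95
#> 1 mandibular P3   derived      45 0.04649808
#> 2 mandibular P3 primitive      45 0.04794096
```

The shape permutation test rejects at its attainable floor (p = 1/1000) and
leave-one-out CVA separates the groups perfectly, as expected for a strong
planted contrast; the size test is not significant because both groups share
the same size distribution. PC1 carries 61% of the shape variance and encodes
the body-height/talonid contrast. The mean relative dentine body height is
0.081 in the derived group versus 0.069 in the primitive group:

```r
spec <- default_dbh_spec(landmark_layout(tooth_class("P3", "mandibular")))
dbh  <- vapply(pos$aligned$aligned, dentine_body_height, numeric(1), spec = spec)
tapply(dbh, pos$aligned$groups, mean)
#>    derived  primitive
#> 0.08096971 0.06903922
```

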