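Package: edjmorph
Title: Geometric Morphometrics of Dental Crown Shape at the Enamel-Dentine Junction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics for dental crowns described at the
    enamel-dentine junction (EDJ) and the cervical outline (CEJ). Converts ordered ridge
    and cervix curve samples into fixed-count homologous landmark configurations by
    periodic cubic spline fitting, projection sectioning and equidistant arc-length
    resampling; superimposes configurations by generalised Procrustes analysis with
    two rounds of thin-plate-spline bending-energy sliding of semilandmarks; and
    provides the downstream statistical toolkit: principal component analysis of shape,
    canonical variate analysis with cross-validation and typicality-probability
    classification, permutation tests for mean shape and size differences with
    Benjamini-Hochberg false-discovery-rate control, pairwise Procrustes-distance
    distributions with 95% conspecificity limits, a relative dentine-body-height metric,
    and log centroid-size tooth-row profiles. A synthetic tooth-cohort generator with
    known ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
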