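Package: wmhconnect
Title: Functional-Connectivity Degree Centrality Analysis of White-Matter
    Hyperintensity Burden and Obesity
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline linking white-matter-hyperintensity
    (WMH) burden and abdominal obesity through resting-state functional
    connectivity. Subjects are stratified into a 2x2 factorial design (low/high
    WMH burden by median split of lesion volume; obese/non-obese by sex-specific
    waist-hip-ratio cutoffs). Per-subject region time series are turned into
    weighted graphs by Pearson correlation, soft-thresholding to scale-free
    topology ((r+1)/2)^beta, and Fisher r-to-z transformation; weighted degree
    centrality is computed per node and residualised on age and sex. Group
    differences are assessed per node with two-way factorial ANOVA
    (Benjamini-Hochberg FDR over nodes) and pooled-variance post-hoc t-tests
    (FDR over the six group pairs). Because the motivating cohort data are
    access-restricted, the package ships a first-class synthetic cohort
    generator (multivariate-normal time series with block correlation
    structure and implantable interaction effects) so the whole chain is
    testable without any download. Minimal NIfTI-1 input/output supports
    extracting mean region time series from a 4D image and an integer
    parcellation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
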