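Package: ictogen
Title: Thalamocortical Circuit Dynamics and White-Matter Statistics for
    Generalised Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a four-population thalamocortical neural mass model
    (cortical pyramidal and interneuron populations with sigmoid activation,
    linear thalamocortical relay and reticular populations, noise input to
    the relay population) and charts its dynamical regimes - fixed point,
    spike-wave discharge, fast oscillation, bistability - over planes of
    connectivity parameters.  Extracts the orientation of the seizure
    frontier in each plane and checks its concordance with a
    ridge-regularised logistic decision boundary fitted to white-matter
    integrity features of an epilepsy cohort.  Also implements the
    two-threshold (tract length by t-score) grid quantification of
    connectometry output - covariate residualisation, Wilcoxon rank-sum
    tests, Benjamini-Hochberg false discovery rate control and a streamline
    count mask - together with a synthetic-data module that emulates the
    cohort, region-level anisotropy features and threshold grids at stated
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
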