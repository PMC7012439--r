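Package: cineMotion
Title: Swallowing Motion Estimation from 2D MR Cine Contours
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of swallowing-structure motion from
    contours drawn on sagittal 2D MR cine frames. Consecutive-frame contours
    of each region of interest are registered with a modified thin-plate-spline
    robust point matching (TPS-RPM) algorithm that combines softassign fuzzy
    correspondence, deterministic annealing and symmetric outlier handling.
    The resulting analytic warps are composed into deformation vector fields
    on a uniform grid, decomposed into superior/inferior and
    anterior/posterior motion magnitudes, and screened by an automatic
    registration-error check that flags unsuccessful registrations. A
    synthetic contour generator with known ground-truth motion supports
    validation of the full pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mgcv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
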