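Package: lipidq
Title: Quantification, Drift Correction and QC Filtering for Targeted
    Serum Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for targeted lipidomics (MRM) peak
    area tables: isotopologue (M+2/M+1) co-integration correction,
    batch-QC anchored loess drift correction with a CV-improvement
    acceptance rule, class-specific internal standard quantification
    with a conditional BQC-average fallback, four-criterion quality
    control filtering (signal-to-blank, raw area, analytical CV, dilution
    linearity), lipid class totals and ceramide/cholesterol ratio
    metrics, and group statistics (Welch's t-tests, PCA on scaled
    centered log2 abundances). Includes a seeded synthetic MRM batch
    generator that emulates a pooled-QC run design with instrument
    drift, isotopic cross-talk and group effects, for validation and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
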