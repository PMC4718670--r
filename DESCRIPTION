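Package: lcmsquant
Title: Label-Free Quantitation of LC-MS Metabolomics Data with Dynamic
    Peak-Width Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromatographic peaks from LC-MS1 runs (mzML/mzXML,
    profile or centroid mode) using extracted-ion-chromatogram construction
    with peak boundaries determined dynamically from the full width at half
    maximum, assigns charge states (1-4) and second-isotope/monoisotope
    abundance ratios by peak-shape similarity, aligns peak lists across
    technical replicates and samples with landmark-based LOESS retention-time
    correction, and reports label-free abundances at replicate and sample
    level. Includes a synthetic-run simulator with ground-truth manifests for
    validation, and an isotope-ratio filter for metabolite candidate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mzR,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
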