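Package: methevolve
Title: Purity- and Copy-Number-Aware Tumor Methylome Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-region tumor methylome analysis from reduced
    representation bisulfite sequencing count data: copy-number- and
    purity-aware deconvolution of bulk methylation rates and epiallele
    discordance (PDR) into cancer-cell-specific estimates, tumor-normal
    differential methylation at position (DMP), region (DMR) and promoter
    level, intratumor methylation and expression heterogeneity distances,
    a dN/dS-analogous regulatory-selection ratio (MR/MN) for promoter
    hypermethylation, beta-regression ranking of candidate methylation
    driver genes from differentially hypermethylated cytosine ratios,
    copy-number-methylation interplay and event-timing classification,
    methylation-dependent dosage-compensation scanning, oncogene-passenger
    chromatin-transition detection at co-amplified loci, and
    expression-threshold dichotomization transferable to expression-only
    cohorts. Includes a synthetic cohort generator reproducing the mixture,
    event and noise structure these methods assume, so the full pipeline is
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
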