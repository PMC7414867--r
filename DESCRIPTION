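Package: hrdscar
Title: Genomic-Scar Scoring of Homologous Recombination Deficiency and
    Cross-Platform Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the three genomic-scar components of the homologous
    recombination deficiency (HRD) score - telomeric allelic imbalance (NtAI),
    loss-of-heterozygosity regions over 15 Mb (HRD-LOH) and large-scale state
    transitions (LST) - from allele-specific copy-number segmentations in
    ASCAT/ascatNgs-style tables, sums them into the HRD score and classifies
    homologous-recombination status at the standard threshold of 42. Also
    provides signal-quality metrics for Log2-ratio tracks (dLRS, MAPD, 10 kb
    binned deviation and correlation), a paired-cohort agreement battery
    (Pearson correlation with regression, Bland-Altman limits of agreement,
    intraclass correlation ICC(3,1), Fleiss kappa, classification concordance,
    component-contribution tests), and a synthetic paired-platform simulator
    with coverage-dependent segmentation noise so the whole analysis is
    testable without controlled-access tumour data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
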