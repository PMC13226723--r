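Package: wgscost
Title: Micro-Costing of Clinical Whole-Genome and Transcriptome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bottom-up (micro-)costing engine for clinical whole-genome plus
    whole-transcriptome sequencing (WGS/WTS) of tumour/normal pairs. Reads an
    itemised cost ledger (consumables, personnel, equipment, data processing),
    computes per-case cost breakdowns under idealised (hands-on time) or
    realistic (whole-position staffing with redundancy, backup equipment,
    re-sequencing error surcharge) allocation rules, links flow-cell throughput
    and mean coverage to flow-cell cost per case and platform capacity, and
    projects deterministic scenarios: case-volume sweeps with capacity steps,
    coverage sweeps, inflation/deflation, and library-protocol comparisons.
    Ships a calibrated synthetic ledger reproducing published aggregate
    figures for a university-hospital workflow, plus seeded random ledger
    generators for property testing.
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
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
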