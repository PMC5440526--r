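Package: micromiss
Title: Dual-Modality Gut Microbiota Comparison and Missing-Microbe Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the gut microbiota of two groups of children (cases with
    severe acute malnutrition versus healthy controls) characterised by two
    complementary modalities: high-throughput culture (culturomics) and 16S
    rRNA amplicon sequencing. Implements presence/absence beta-diversity via
    the unique/total (U/T) species ratio, Shannon diversity partitioned by
    oxygen tolerance, hitherto-unknown-diversity accounting (new taxa and
    unassigned OTUs), OTU post-processing rules (low-count filtering and
    species assignment by sequence identity), a small-sample test battery
    including the unconditional exact test of Barnard for 2x2 tables, and the
    identification of the missing bacterial repertoire with probiotic-candidate
    annotation. Ships a synthetic community generator so the whole pipeline is
    exercisable without external data.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
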