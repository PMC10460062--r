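Package: ampliregion
Title: In Silico Evaluation of 16S rRNA Sub-Region Primer Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing PCR primer pairs that target different
    variable sub-regions of the bacterial 16S rRNA gene. Extracts in silico
    amplicons from a taxonomy-labeled reference set by IUPAC-degenerate
    primer matching, scores taxon coverage per primer, re-classifies
    amplicons with a k-mer multinomial naive-Bayes classifier with bootstrap
    confidence, compares per-region neighbor-joining trees to the
    full-length tree by Robinson-Foulds distance, and contrasts community
    profiles (Chao1, Shannon, detection overlap, dominant-taxon-exclusion
    correlation). Includes a synthetic 16S-like reference-database and
    community simulator with controllable primer-site dropout and
    region-localized divergence, so the whole pipeline runs without any
    external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
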