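Package: chiscaf
Title: Likelihood-Based Genome Scaffolding with In Vitro Proximity-Ligation Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scaffolds draft genome assemblies using "Chicago"-style in vitro
    proximity-ligation read pairs. Models read-pair separations as a uniform
    noise floor plus a truncated mixture of exponentials, scores candidate
    contig joins by a spanning-pair log-likelihood ratio, builds and filters
    a contig-contig link graph, orders and orients contigs by dynamic
    programming, detects and breaks low-support (mis)joins with a
    repeat-robust per-position support score, and estimates gap sizes.
    Includes a synthetic Chicago-library simulator with truth tracking for
    exact assembly QC, a maximum-likelihood discriminator for heterozygous
    inversions, readers/writers for pairs/AGP/FASTA/BED, and ggplot2
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
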