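Package: meripscan
Title: Sliding-Window Peak Calling and Downstream Analysis for MeRIP-Seq (m6A-Seq)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcript-coordinate peak calling for methylated-RNA
    immunoprecipitation sequencing (MeRIP-seq / m6A-seq): reads are extended
    to fragment length, projected onto each gene's longest isoform, counted
    in 100-nt windows sliding by 10 nt, and tested for IP-over-input
    enrichment with a one-sided Fisher exact test; windows passing FDR and
    enrichment-score thresholds are merged into peaks. Downstream tools
    compare peak sets between conditions, compute 100-bin metagene profiles
    (5'UTR/CDS/3'UTR), check GGACU motif enrichment under peaks, quantify
    delta-delta-Cq expression, gene-specific m6A-IP qPCR enrichment and
    actinomycin-D mRNA decay half-lives, and simulate complete two-condition
    MeRIP-seq experiments with known ground truth for calibration and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Biostrings,
    yaml,
    withr
Config/testthat/edition: 3
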