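Package: polyssr
Title: Discovery of Putatively Polymorphic Microsatellites from
    Multi-Sample Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico enrichment of putatively polymorphic microsatellite
    (SSR) markers from assembled transcriptomes of two or more samples or
    ecotypes.  Perfect 1-6 bp tandem repeats are mined with MISA-style
    thresholds, transcripts are clustered across samples at >=90 percent
    identity on either strand, negative-strand members are re-oriented,
    homologous repeat loci are matched by their flanking sequence, and loci
    whose repeat counts differ between samples are reported as candidate
    polymorphic markers after filtering repeats too close to a sequence end,
    mononucleotide runs, and paralogy-driven false-positive clusters.
    Includes a synthetic transcript-family generator with planted
    polymorphic repeats and decoys plus a truth table, so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
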