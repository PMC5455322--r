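Package: famsynt
Title: Gene-Family Microsynteny, Selection and Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for small plant gene families
    across related genomes: domain-hit filtering and positional naming of
    family members, neighbor-joining phylogenies from Poisson-corrected
    protein distances with nonparametric bootstrap, detection of
    microsyntenic blocks around family anchor genes with a relative
    syntenic-quality statistic, Nei-Gojobori (1986) Ka/Ks estimation with
    sliding-window selection scans and Ks-epoch dating of duplication
    events, and qRT-PCR relative-expression summarization by the
    delta-delta-Ct method. Includes a genome-evolution simulator (whole
    genome duplication, tandem duplication, gene loss, segmental
    inversion, codon evolution under a specified dN/dS) that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
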