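Package: poolscan
Title: Pool-Seq Analysis of Two-Founder Genome Reselection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evolve-and-resequence experiments in which a mixed
    population derived from two founder strains is reared under contrasting
    environments and resequenced as pools. Includes a diploid Wright-Fisher
    forward simulator with per-locus selection, dominance and female-limited
    recombination; readers and writers for popoolation2-style sync allele
    count tables; founder-SNP filtering and pooled allele-frequency
    estimation; a Fisher exact test scan contrasting conditions with
    Bonferroni correction, top-rank selection and trajectory typing of
    selected SNPs; candidate-region clustering, a binned likelihood-ratio
    LOD scan with peak calling and 90 percent credible intervals, and
    overlap with gene and run-of-homozygosity annotations; competition-assay
    fitness statistics; and allele-specific qPCR frequency estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
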