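## A small planted reselection experiment shared by several test files,
## built once per run: 300 SNPs on two chromosomes, 20 strongly
## antagonistic (type2-like) loci, 3 replicates per condition over 12
## generations.
tiny_planted_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_reselection(
        n_snps = 300L,
        regimes = data.frame(type = "type2", count = 20L,
                             s_LD = -0.35, s_DD = 0.35,
                             stringsAsFactors = FALSE),
        n_individuals = 120L,
        generations = c(0L, 6L, 12L),
        n_replicates = 3L,
        mean_depth = 150,
        chrom_layout = c(chrA = 8e6, chrB = 8e6),
        seed = 42L)
    }
    cache
  }
})
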