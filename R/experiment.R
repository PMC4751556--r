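#' Simulate a full genome-reselection experiment
#'
#' End-to-end synthetic version of the two-founder reselection design: an
#' F1-hybrid base population is split into replicate populations reared
#' under light-dark cycling (LD) and constant dark (DD); each replicate
#' evolves under condition-specific per-locus selection with drift and
#' recombination, and recorded generations are pool-sequenced.  Defaults
#' mirror the study design this package models: populations of about 1000
#' flies, three replicates per condition, 49 generations with sequencing
#' at generations 0, 22 and 49, and mean pool depth 179x.  `n_snps`
#' defaults to a down-scaled map of 5000 founder SNPs (the full design
#' tracks about 1.4e5); see the package vignette.
#'
#' @param n_snps Number of founder SNPs.
#' @param regimes Planted selection regimes as for [make_founder_map()];
#'   defaults to [reselection_regimes()].
#' @param n_individuals Census size per replicate population.
#' @param generations Generations to record and sequence.
#' @param n_replicates Replicates per condition.
#' @param mean_depth Mean pool-seq depth.
#' @param error_rate Sequencing error rate.
#' @param recomb_cM_per_Mb Female recombination rate.
#' @param chrom_layout Chromosome lengths.
#' @param spread_regimes Passed to [make_founder_map()]; defaults to
#'   `TRUE` so planted loci are well separated for region calling.
#' @param seed Integer seed controlling the whole experiment.
#' @return List with elements `founder`, `states` (all recorded
#'   `population_state`s), `counts` (a multi-population [count_table()];
#'   generation 0 is sequenced once, as population `g0_base1`), and
#'   `truth` (data frame of true pool frequencies per recorded
#'   population).
#' @export
simulate_reselection <- function(n_snps = 5000L,
                                 regimes = reselection_regimes(),
                                 n_individuals = 1000L,
                                 generations = c(0L, 22L, 49L),
                                 n_replicates = 3L,
                                 mean_depth = 179,
                                 error_rate = 0.001,
                                 recomb_cM_per_Mb = 2,
                                 chrom_layout = dmel_chrom_layout(),
                                 spread_regimes = TRUE,
                                 seed = NULL) {
  local_seed(seed, {
    founder <- make_founder_map(n_snps, chrom_layout, regimes = regimes,
                                spread_regimes = spread_regimes)
    states <- list()
    for (cond in c("LD", "DD")) {
      states <- c(states,
                  simulate_generations(founder, cond,
                                       n_individuals = n_individuals,
                                       generations = generations,
                                       n_replicates = n_replicates,
                                       recomb_cM_per_Mb = recomb_cM_per_Mb))
    }
    ## generation 0 predates the environmental split: sequence it once
    is_gen0 <- vapply(states, function(s) s$generation == 0L, logical(1L))
    gen0 <- states[is_gen0][[1L]]
    gen0$condition <- "base"
    gen0$replicate_id <- 1L
    states <- c(list(gen0), states[!is_gen0])

    tables <- lapply(states, function(st) {
      sample_pooled_reads(st, mean_depth = mean_depth,
                          error_rate = error_rate)
    })
    counts <- bind_populations(tables)
    truth <- data.frame(snp_id = founder$snp_id,
                        planted_type = founder$planted_type,
                        stringsAsFactors = FALSE)
    for (st in states) {
      truth[[pop_label(st$generation, st$condition, st$replicate_id)]] <-
        dark_freq(st)
    }
    list(founder = founder, states = states, counts = counts, truth = truth)
  })
}

#' Run the condition-contrast scan on a simulated or real experiment
#'
#' Pipeline: estimate per-population frequencies, restrict to founder SNPs
#' (generation-0 frequency in \[0.4, 0.6\]), merge replicate counts per
#' condition at the focal generation, Fisher-exact scan LD vs DD, and
#' classify significant SNPs into trajectory types.
#'
#' @param counts Multi-population [count_table()] with populations
#'   labelled as by [pop_label()] (a `g0_base1` population supplies the
#'   founder filter).
#' @param focal_generation Generation at which conditions are contrasted
#'   (default 49).
#' @param min_coverage,founder_lo,founder_hi Frequency-estimation and
#'   founder-filter settings.
#' @param alpha_bonferroni,top_frac,bins,max_coverage Passed to
#'   [fisher_scan()] and [classify_significant()].
#' @param seed Seed for the coverage down-sampling draws.
#' @return List with `scan` (a `scan_result`), `freqs` (founder-filtered
#'   `freq_table` of all populations), `founder_keys`, and the merged
#'   tables `merged_LD`, `merged_DD`.
#' @export
reselection_scan <- function(counts, focal_generation = 49L,
                             min_coverage = 5L, founder_lo = 0.4,
                             founder_hi = 0.6, alpha_bonferroni = 0.01,
                             top_frac = 0.05, bins = c(0.35, 0.8),
                             max_coverage = 9000L, seed = NULL) {
  stopifnot(inherits(counts, "count_table"))
  pops <- populations(counts)
  meta <- parse_pop_label(pops)
  gen0_pop <- pops[meta$generation == 0L]
  if (length(gen0_pop) < 1L) {
    stop("no generation-0 population for the founder filter", call. = FALSE)
  }
  freqs_all <- estimate_frequencies(counts, min_coverage = min_coverage)
  gen0 <- freqs_all[, c("chrom", "pos", "ref", "dark", gen0_pop[1L])]
  attr(gen0, "pops") <- gen0_pop[1L]
  class(gen0) <- c("freq_table", "data.frame")
  keys <- select_founder_snps(gen0, lo = founder_lo, hi = founder_hi)

  fcounts <- filter_snps(counts, keys)
  freqs <- filter_snps(freqs_all, keys)

  take <- function(cond) {
    sel <- pops[meta$condition == cond & meta$generation == focal_generation]
    if (length(sel) == 0L) {
      stop("no ", cond, " populations at generation ", focal_generation,
           call. = FALSE)
    }
    sub <- fcounts[, c("chrom", "pos", "ref", "dark",
                       as.vector(rbind(paste0(sel, "_dark"),
                                       paste0(sel, "_other"))))]
    attr(sub, "pops") <- sel
    class(sub) <- c("count_table", "data.frame")
    sub
  }
  merged_LD <- merge_replicates(take("LD"), label = "LD_merged")
  merged_DD <- merge_replicates(take("DD"), label = "DD_merged")
  pv <- fisher_scan(merged_LD, merged_DD, max_coverage = max_coverage,
                    min_coverage = min_coverage, seed = seed)

  sub_freq <- function(cond) {
    sel <- pops[meta$condition == cond & meta$generation == focal_generation]
    sub <- freqs[, c("chrom", "pos", "ref", "dark", sel)]
    attr(sub, "pops") <- sel
    attr(sub, "depth") <- attr(freqs, "depth")[, sel, drop = FALSE]
    class(sub) <- c("freq_table", "data.frame")
    sub
  }
  scan <- classify_significant(pv, sub_freq("LD"), sub_freq("DD"),
                               alpha_bonferroni = alpha_bonferroni,
                               top_frac = top_frac, bins = bins)
  list(scan = scan, freqs = freqs, founder_keys = keys,
       merged_LD = merged_LD, merged_DD = merged_DD)
}
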