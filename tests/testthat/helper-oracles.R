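## Independent oracles used across test files.

## Deterministic single-locus selection recursion (infinite-population
## limit): genotype fitness 1 / 1+hs / 1+s, random mating.
wf_recursion <- function(p0, s, h, generations) {
  p <- p0
  for (g in seq_len(generations)) {
    w2 <- 1 + s
    w1 <- 1 + h * s
    wbar <- p^2 * w2 + 2 * p * (1 - p) * w1 + (1 - p)^2
    p <- (p^2 * w2 + p * (1 - p) * w1) / wbar
  }
  p
}

## Two-sided Fisher exact p by explicit hypergeometric enumeration with
## binomial coefficients (independent of the dhyper-based implementation).
fisher_enum_oracle <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  ks <- max(0, m - n2):min(n1, m)
  pr <- choose(n1, ks) * choose(n2, m - ks) / choose(n1 + n2, m)
  obs <- pr[ks == k1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

## Brute-force LOD oracle: maximise the exact binomial likelihoods over a
## fine grid of frequencies.
lod_grid_oracle <- function(k1, n1, k2, n2, grid = seq(1e-6, 1 - 1e-6, 1e-4)) {
  l1 <- max(dbinom(k1, n1, grid) * dbinom(k2, n2, grid))
  l2 <- max(dbinom(k1, n1, grid)) * max(dbinom(k2, n2, grid))
  log10(l2 / l1)
}

## Quick single-population count table for scan tests.
make_ct <- function(chrom, pos, dark, other, label = "pop1",
                    ref = "A", alt = "G") {
  count_table(
    data.frame(chrom = chrom, pos = pos, ref = ref, dark = alt,
               stringsAsFactors = FALSE),
    stats::setNames(list(list(dark = dark, other = other)), label))
}

## Minimal population_state for read-sampling tests.
fake_state <- function(founder, hap, generation = 0L, condition = "base",
                       replicate_id = 1L) {
  st <- list(generation = generation, condition = condition,
             replicate_id = replicate_id, haplotypes = hap)
  attr(st, "founder") <- founder
  class(st) <- "population_state"
  st
}
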