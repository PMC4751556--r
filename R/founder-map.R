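#' Default chromosome layout
#'
#' Lengths (bp) of the five major *Drosophila melanogaster* chromosome arms,
#' used as the default genome for synthetic founder maps.
#'
#' @return Named numeric vector of arm lengths in bp.
#' @export
dmel_chrom_layout <- function() {
  c(X = 22.4e6, `2L` = 23.0e6, `2R` = 21.1e6, `3L` = 24.5e6, `3R` = 27.9e6)
}

#' Canonical planted selection regimes
#'
#' Three selection regimes matching the three trajectory types the scan is
#' designed to recover, each with a between-condition contrast
#' |s_DD - s_LD| >= 0.15:
#' type 1 is positively selected in both conditions but more strongly in
#' constant dark (DD), type 2 is positively selected in DD and negatively in
#' light-dark cycling (LD), and type 3 is negatively selected in both but
#' more strongly in LD.  Coefficients were chosen, via the deterministic
#' single-locus recursion with additive dominance, so that after 49
#' generations the expected DD dark-allele frequency sits well inside the
#' corresponding classification bin (about 0.98, 0.57 and 0.28) while the
#' LD-DD contrast - and hence the exact-test signal - is as large as the
#' bin and the |s_DD - s_LD| >= 0.15 constraint allow.
#'
#' The default of one planted locus per regime reflects a capacity limit of
#' rank-based selection tiers: a strong sweep over 49 generations carries a
#' hitchhiking footprint of a few megabases, while the top-5% tier can hold
#' only about 5% of the genome (about 6 Mb here) regardless of SNP density,
#' so a genome of this size accommodates roughly three non-interfering
#' strong sweeps.  See the package vignette.
#'
#' @param n_per_type Number of planted loci per regime.
#' @return A data frame with columns `type`, `count`, `s_LD`, `s_DD`,
#'   suitable for the `regimes` argument of [make_founder_map()].
#' @export
reselection_regimes <- function(n_per_type = 1L) {
  data.frame(
    type  = c("type1", "type2", "type3"),
    count = rep(as.integer(n_per_type), 3L),
    s_LD  = c(0.010, -0.140, -0.260),
    s_DD  = c(0.160,  0.012, -0.038),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic founder SNP map
#'
#' Generates a map of biallelic SNPs that distinguish the two founder
#' strains ("dark" founder vs reference founder).  Positions are drawn
#' uniformly per chromosome (proportionally to chromosome length) and
#' sorted; a subset of loci can be planted with condition-specific selection
#' coefficients, all remaining loci are neutral.
#'
#' @param n_snps Total number of SNPs.
#' @param chrom_layout Named vector of chromosome lengths in bp.
#' @param regimes `NULL` for an all-neutral map, or a data frame with
#'   columns `type` (one of `"type1"`, `"type2"`, `"type3"`), `count`,
#'   `s_LD` and `s_DD` giving, per regime, the number of planted loci and
#'   the selection coefficient of the dark allele in each condition.
#' @param h Dominance coefficient of the dark allele, shared by all loci
#'   (genotype fitness 1, 1 + h s, 1 + s).
#' @param spread_regimes If `TRUE`, planted loci are placed at evenly spaced
#'   quantiles of the genome-wide SNP index (interleaving regimes) instead
#'   of at random SNPs; useful when downstream peak calling needs planted
#'   loci separated by more than its suppression distance.
#' @param seed Integer seed; identical seeds give identical maps.
#' @return A data frame of class `founder_map` with columns `snp_id`,
#'   `chrom`, `pos`, `ref_allele`, `dark_allele`, `s_LD`, `s_DD`, `h`,
#'   `planted_type`, and attribute `chrom_layout`.
#' @examples
#' fm <- make_founder_map(200, c(chr1 = 2e6), seed = 1)
#' table(fm$planted_type)
#' @export
make_founder_map <- function(n_snps, chrom_layout = dmel_chrom_layout(),
                             regimes = NULL, h = 0.5,
                             spread_regimes = FALSE, seed = NULL) {
  stopifnot(n_snps >= 1, length(chrom_layout) >= 1)
  if (any(chrom_layout <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (is.null(names(chrom_layout)) || anyDuplicated(names(chrom_layout))) {
    stop("chrom_layout must have unique names", call. = FALSE)
  }
  if (!is.null(regimes)) {
    need <- c("type", "count", "s_LD", "s_DD")
    if (!all(need %in% names(regimes))) {
      stop("regimes must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (sum(regimes$count) > n_snps) {
      stop("regime counts (", sum(regimes$count),
           ") exceed n_snps (", n_snps, ")", call. = FALSE)
    }
  }
  local_seed(seed, {
    ## allocate SNPs per chromosome proportionally (largest remainder)
    frac <- chrom_layout / sum(chrom_layout)
    n_per <- floor(frac * n_snps)
    rem <- n_snps - sum(n_per)
    if (rem > 0) {
      extra <- order(frac * n_snps - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1L
    }
    chrom <- rep(names(chrom_layout), n_per)
    pos <- unlist(lapply(seq_along(chrom_layout), function(i) {
      sort(sample.int(as.integer(chrom_layout[i]), n_per[i]))
    }), use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    shift <- sample.int(3L, n_snps, replace = TRUE)
    dark <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]

    s_LD <- numeric(n_snps)
    s_DD <- numeric(n_snps)
    planted <- rep("neutral", n_snps)
    if (!is.null(regimes) && sum(regimes$count) > 0) {
      total <- sum(regimes$count)
      idx <- if (spread_regimes) {
        unique(round(seq(1, n_snps, length.out = total + 2L)[-c(1L, total + 2L)]))
      } else {
        sample.int(n_snps, total)
      }
      if (length(idx) < total) {
        stop("cannot place ", total, " spread regime loci among ",
             n_snps, " SNPs", call. = FALSE)
      }
      ## interleave regimes so planted types alternate along the genome
      lab <- unlist(lapply(seq_len(max(regimes$count)), function(k) {
        regimes$type[regimes$count >= k]
      }))[seq_len(total)]
      for (j in seq_along(idx)) {
        r <- match(lab[j], regimes$type)
        s_LD[idx[j]] <- regimes$s_LD[r]
        s_DD[idx[j]] <- regimes$s_DD[r]
        planted[idx[j]] <- regimes$type[r]
      }
    }
    fm <- data.frame(
      snp_id = snp_key(chrom, pos),
      chrom = chrom, pos = as.integer(pos),
      ref_allele = ref, dark_allele = dark,
      s_LD = s_LD, s_DD = s_DD, h = h,
      planted_type = planted,
      stringsAsFactors = FALSE
    )
    attr(fm, "chrom_layout") <- chrom_layout
    class(fm) <- c("founder_map", "data.frame")
    fm
  })
}

validate_founder_map <- function(fm) {
  stopifnot(inherits(fm, "data.frame"))
  need <- c("chrom", "pos", "ref_allele", "dark_allele", "s_LD", "s_DD", "h")
  if (!all(need %in% names(fm))) {
    stop("founder map lacks columns: ",
         paste(setdiff(need, names(fm)), collapse = ", "), call. = FALSE)
  }
  if (any(fm$ref_allele == fm$dark_allele)) {
    stop("founder map has sites with dark allele equal to reference allele",
         call. = FALSE)
  }
  for (ch in unique(fm$chrom)) {
    p <- fm$pos[fm$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on ", ch, call. = FALSE)
    }
  }
  invisible(fm)
}
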