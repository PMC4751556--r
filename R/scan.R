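#' Merge replicate count tables
#'
#' Element-wise sum of read counts over all populations of all supplied
#' tables, the pooled-data analogue of merging replicate alignments before
#' testing.  Depth is conserved: merged depth equals the sum of the
#' replicate depths at every SNP.
#'
#' @param tables A list of `count_table`s (each may hold several
#'   populations), or a single multi-population `count_table`.
#' @param label Label of the merged population.
#' @return A single-population [count_table()].
#' @export
merge_replicates <- function(tables, label = "merged") {
  if (inherits(tables, "count_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  check_same_keys(tables)
  keys <- tables[[1L]][, c("chrom", "pos", "ref", "dark")]
  dark <- 0L
  other <- 0L
  for (tb in tables) {
    for (lab in populations(tb)) {
      cc <- pop_counts(tb, lab)
      dark <- dark + cc[, "dark"]
      other <- other + cc[, "other"]
    }
  }
  count_table(keys, stats::setNames(list(list(dark = dark, other = other)),
                                    label))
}

## Two-sided Fisher exact p for one 2x2 table [k1, n1-k1; k2, n2-k2],
## probability-mass method: sum of hypergeometric outcomes no more likely
## than the observed one (the convention of stats::fisher.test).
fisher_p_one <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  lo <- max(0L, m - n2)
  hi <- min(n1, m)
  d <- stats::dhyper(lo:hi, n1, n2, m)
  sum(d[d <= d[k1 - lo + 1L] * (1 + 1e-7)])
}

#' Vectorised two-sided Fisher exact test on allele counts
#'
#' @param k1,n1 Dark-allele count and depth in the first condition.
#' @param k2,n2 Dark-allele count and depth in the second condition.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_p <- function(k1, n1, k2, n2) {
  stopifnot(length(k1) == length(n1), length(k2) == length(n2),
            length(k1) == length(k2))
  if (any(k1 > n1 | k2 > n2 | k1 < 0 | k2 < 0)) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  vapply(seq_along(k1), function(i) {
    fisher_p_one(k1[i], n1[i], k2[i], n2[i])
  }, numeric(1L))
}

#' Fisher exact scan contrasting two merged conditions
#'
#' Per SNP, tests the 2x2 table of dark vs other read counts in the two
#' merged conditions with a two-sided Fisher exact test.  SNPs whose depth
#' exceeds `max_coverage` in a condition are first down-sampled to
#' `max_coverage` reads without replacement (hypergeometric, seeded); SNPs
#' with zero depth in either condition are skipped with a message.
#'
#' @param merged_LD,merged_DD Single-population `count_table`s covering the
#'   same SNPs (see [merge_replicates()]).
#' @param max_coverage Depth cap per condition (default 9000).
#' @param min_coverage SNPs below this depth in either condition are
#'   skipped (default 5).
#' @param seed Integer seed for the down-sampling draws.
#' @return Data frame with columns `chrom`, `pos`, `k_LD`, `n_LD`, `k_DD`,
#'   `n_DD` (counts actually tested) and `p_value`; skipped SNPs carry
#'   `NA` p-values.
#' @export
fisher_scan <- function(merged_LD, merged_DD, max_coverage = 9000L,
                        min_coverage = 5L, seed = NULL) {
  stopifnot(inherits(merged_LD, "count_table"),
            inherits(merged_DD, "count_table"))
  if (length(populations(merged_LD)) != 1L ||
      length(populations(merged_DD)) != 1L) {
    stop("fisher_scan expects single-population (merged) tables",
         call. = FALSE)
  }
  check_same_keys(list(merged_LD, merged_DD))
  a <- pop_counts(merged_LD, populations(merged_LD))
  b <- pop_counts(merged_DD, populations(merged_DD))
  k1 <- a[, "dark"]; n1 <- rowSums(a)
  k2 <- b[, "dark"]; n2 <- rowSums(b)

  local_seed(seed, {
    over1 <- which(n1 > max_coverage)
    if (length(over1) > 0L) {
      k1[over1] <- stats::rhyper(length(over1), k1[over1],
                                 n1[over1] - k1[over1], max_coverage)
      n1[over1] <- max_coverage
    }
    over2 <- which(n2 > max_coverage)
    if (length(over2) > 0L) {
      k2[over2] <- stats::rhyper(length(over2), k2[over2],
                                 n2[over2] - k2[over2], max_coverage)
      n2[over2] <- max_coverage
    }
    ok <- n1 >= min_coverage & n2 >= min_coverage
    if (any(!ok)) {
      message("fisher_scan: skipped ", sum(!ok),
              " SNP(s) below minimum coverage")
    }
    p <- rep(NA_real_, length(k1))
    p[ok] <- fisher_p(k1[ok], n1[ok], k2[ok], n2[ok])
    data.frame(chrom = merged_LD$chrom, pos = merged_LD$pos,
               k_LD = k1, n_LD = n1, k_DD = k2, n_DD = n2,
               p_value = p, stringsAsFactors = FALSE)
  })
}

#' Classify scanned SNPs into selection trajectory types
#'
#' Applies Bonferroni correction (m = number of tested SNPs), flags the
#' top `top_frac` fraction of SNPs by p-value rank (ties broken by genomic
#' order), computes per-condition mean frequencies as unweighted means over
#' replicate populations and the allele frequency change
#' AFC = mean(DD) - mean(LD), and assigns trajectory types among top-ranked
#' SNPs with higher DD frequency: type 1 if the mean DD frequency is in
#' \[0.8, 1\], type 2 in \[0.35, 0.8), type 3 in \[0, 0.35).
#'
#' @param scan Output of [fisher_scan()].
#' @param freq_LD,freq_DD `freq_table`s of the per-replicate populations in
#'   each condition, covering the scanned SNPs.
#' @param alpha_bonferroni Family-wise significance level (default 0.01).
#' @param top_frac Fraction of tested SNPs flagged top-ranked (default 0.05).
#' @param bins Two inner bin boundaries on the mean DD frequency
#'   (default `c(0.35, 0.8)`).
#' @return A `scan_result` data frame with columns `chrom`, `pos`,
#'   `p_value`, `p_bonferroni`, `significant`, `mean_freq_LD`,
#'   `mean_freq_DD`, `afc`, `top_flag`, `direction`, `type_label`.
#' @export
classify_significant <- function(scan, freq_LD, freq_DD,
                                 alpha_bonferroni = 0.01, top_frac = 0.05,
                                 bins = c(0.35, 0.8)) {
  stopifnot(all(c("chrom", "pos", "p_value") %in% names(scan)),
            length(bins) == 2L, bins[1L] < bins[2L])
  key <- snp_key(scan$chrom, scan$pos)
  mLD <- mean_pop_freq(freq_LD, key)
  mDD <- mean_pop_freq(freq_DD, key)

  p <- scan$p_value
  m <- sum(!is.na(p))
  p_bonf <- pmin(1, p * m)
  significant <- !is.na(p_bonf) & p_bonf < alpha_bonferroni

  ## top-rank flag over all tested SNPs, ties broken by genomic order
  n_top <- ceiling(top_frac * m)
  ord <- order(is.na(p), p, scan$chrom, scan$pos)
  top_flag <- rep(FALSE, length(p))
  if (n_top > 0L && m > 0L) top_flag[ord[seq_len(min(n_top, m))]] <- TRUE

  afc <- mDD - mLD
  direction <- rep(NA_character_, length(p))
  known <- !is.na(afc)
  direction[known] <- ifelse(afc[known] > 0, "higher_DD",
                             ifelse(afc[known] < 0, "higher_LD", "tie"))

  type <- rep("none", length(p))
  cand <- top_flag & !is.na(direction) & direction == "higher_DD" &
    !is.na(mDD)
  type[cand & mDD >= bins[2L]] <- "type1"
  type[cand & mDD >= bins[1L] & mDD < bins[2L]] <- "type2"
  type[cand & mDD < bins[1L]] <- "type3"

  out <- data.frame(chrom = scan$chrom, pos = scan$pos,
                    p_value = p, p_bonferroni = p_bonf,
                    significant = significant,
                    mean_freq_LD = mLD, mean_freq_DD = mDD, afc = afc,
                    top_flag = top_flag, direction = direction,
                    type_label = type, stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

## unweighted mean of per-replicate frequencies; NA if the SNP is missing
## in any replicate used
mean_pop_freq <- function(freqs, key) {
  stopifnot(inherits(freqs, "freq_table"))
  fk <- snp_key(freqs$chrom, freqs$pos)
  idx <- match(key, fk)
  fm <- as.matrix(freqs[idx, populations(freqs), drop = FALSE])
  rowMeans(fm)
}

#' Chi-square test for directional bias of selected SNPs
#'
#' Goodness-of-fit of the counts of SNPs with higher frequency in DD versus
#' higher in LD against a 50:50 expectation (1 df, no continuity
#' correction).
#'
#' @param n_higher_DD,n_higher_LD Non-negative counts.
#' @return List with `statistic`, `p_value`, `expected`.
#' @export
direction_bias_test <- function(n_higher_DD, n_higher_LD) {
  stopifnot(n_higher_DD >= 0, n_higher_LD >= 0)
  total <- n_higher_DD + n_higher_LD
  if (total == 0) {
    stop("direction bias test undefined for zero counts", call. = FALSE)
  }
  ct <- stats::chisq.test(c(n_higher_DD, n_higher_LD), p = c(0.5, 0.5))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       expected = unname(ct$expected))
}
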