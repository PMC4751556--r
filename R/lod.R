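## Binomial log-likelihood up to the constant binomial coefficient, which
## cancels in every ratio used here.  Accepts non-integer (rescaled) counts.
binom_ll <- function(k, n, p) {
  t1 <- ifelse(k > 0, k * log(p), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log1p(-p), 0)
  t1 + t2
}

## Per-bin generalized likelihood-ratio LOD contrasting the two conditions:
## LOD = log10 [ max_{p1,p2} L1(p1) L2(p2) / max_p L1(p) L2(p) ],
## with closed-form MLEs p_i = k_i / n_i and p0 = (k1+k2)/(n1+n2).
lod_one <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) return(0)
  p1 <- k1 / n1
  p2 <- k2 / n2
  p0 <- (k1 + k2) / (n1 + n2)
  (binom_ll(k1, n1, p1) + binom_ll(k2, n2, p2) -
     binom_ll(k1, n1, p0) - binom_ll(k2, n2, p0)) / log(10)
}

## Discrete Gaussian kernel smoothing of a per-bin track.
## mode "sum":  unnormalised kernel (K(0) = 1) -- aggregates the evidence of
##              linked bins into a composite LOD used for peak detection.
## mode "mean": kernel normalised over all bins in range (a standard
##              Gaussian filter, empty bins included) -- a local average
##              that tempers the composite likelihood for localisation.
smooth_track <- function(lod, bw_bins, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (bw_bins <= 0 || length(lod) < 2L) return(lod)
  half <- ceiling(4 * bw_bins)
  kern <- exp(-0.5 * ((-half):half / bw_bins)^2)
  n <- length(lod)
  padded <- c(numeric(half), lod, numeric(half))
  sm <- vapply(seq_len(n), function(i) {
    sum(kern * padded[i:(i + 2L * half)])
  }, numeric(1L))
  if (mode == "mean") {
    ## renormalise near the edges over in-range bins only
    w <- vapply(seq_len(n), function(i) {
      j <- (i - half):(i + half)
      sum(kern[j >= 1L & j <= n])
    }, numeric(1L))
    sm <- sm / w
  }
  sm
}

#' Binned likelihood-ratio LOD scan contrasting two conditions
#'
#' Dark/other read counts of the two merged conditions are summed within
#' consecutive `bin_bp` windows per chromosome.  SNPs effectively fixed in
#' either condition (frequency below `fixed_lo` or above `fixed_hi`) are
#' excluded first, and each condition's counts in a bin are capped at
#' 2 x `pool_n` chromosomes by proportional rescaling, since reads in
#' excess of the pooled chromosome count carry no extra information about
#' the pool.  Each bin is scored with a generalized likelihood-ratio LOD
#' (log10) comparing condition-specific binomial frequencies against a
#' shared one; empty bins score 0.  With `smooth_bw_bins > 0` the track is
#' Gaussian-kernel smoothed; the default `"sum"` mode accumulates the
#' evidence of linked neighbouring bins (a composite likelihood), which is
#' what makes a fixed detection threshold meaningful when single bins
#' contain few SNPs.
#'
#' @param merged_LD,merged_DD Single-population `count_table`s on the same
#'   SNPs.
#' @param bin_bp Bin width in bp (default 1000).
#' @param pool_n Number of pooled individuals per condition (default 3000);
#'   caps effective counts at `2 * pool_n`.
#' @param smooth_bw_bins Gaussian kernel bandwidth (sd) in bins; 0 disables
#'   smoothing.
#' @param smooth_mode `"sum"` or `"mean"`; see Details.
#' @param drop_fixed,fixed_lo,fixed_hi Fixed-SNP filter switches.
#' @return A `lod_track` data frame with columns `chrom`, `start`, `mid`,
#'   `lod` (smoothed) and `lod_raw`; attribute `bin_bp`.
#' @export
lod_scan <- function(merged_LD, merged_DD, bin_bp = 1000L, pool_n = 3000L,
                     smooth_bw_bins = 30, smooth_mode = c("sum", "mean"),
                     drop_fixed = TRUE, fixed_lo = 0.01, fixed_hi = 0.99) {
  smooth_mode <- match.arg(smooth_mode)
  if (bin_bp <= 0) stop("bin_bp must be positive", call. = FALSE)
  stopifnot(inherits(merged_LD, "count_table"),
            inherits(merged_DD, "count_table"))
  check_same_keys(list(merged_LD, merged_DD))
  a <- pop_counts(merged_LD, populations(merged_LD))
  b <- pop_counts(merged_DD, populations(merged_DD))
  k1 <- a[, "dark"]; n1 <- rowSums(a)
  k2 <- b[, "dark"]; n2 <- rowSums(b)
  keep <- n1 > 0 & n2 > 0
  if (drop_fixed) {
    f1 <- ifelse(n1 > 0, k1 / n1, NA_real_)
    f2 <- ifelse(n2 > 0, k2 / n2, NA_real_)
    keep <- keep & f1 >= fixed_lo & f1 <= fixed_hi &
      f2 >= fixed_lo & f2 <= fixed_hi
  }
  keep[is.na(keep)] <- FALSE
  chrom <- merged_LD$chrom[keep]
  pos <- merged_LD$pos[keep]
  k1 <- k1[keep]; n1 <- n1[keep]; k2 <- k2[keep]; n2 <- n2[keep]

  cap <- 2 * pool_n
  tracks <- lapply(unique(merged_LD$chrom), function(ch) {
    sel <- chrom == ch
    rng <- range(merged_LD$pos[merged_LD$chrom == ch])
    first <- floor((rng[1L] - 1L) / bin_bp) * bin_bp + 1L
    starts <- seq(first, rng[2L], by = bin_bp)
    if (!any(sel)) {
      return(data.frame(chrom = ch, start = as.integer(starts),
                        mid = as.integer(starts + bin_bp %/% 2L),
                        lod = 0, lod_raw = 0, stringsAsFactors = FALSE))
    }
    bin <- findInterval(pos[sel], starts)
    agg <- function(v) {
      out <- numeric(length(starts))
      t <- tapply(v, bin, sum)
      out[as.integer(names(t))] <- t
      out
    }
    K1 <- agg(k1[sel]); N1 <- agg(n1[sel])
    K2 <- agg(k2[sel]); N2 <- agg(n2[sel])
    over <- N1 > cap
    K1[over] <- K1[over] * cap / N1[over]; N1[over] <- cap
    over <- N2 > cap
    K2[over] <- K2[over] * cap / N2[over]; N2[over] <- cap
    raw <- vapply(seq_along(starts), function(i) {
      lod_one(K1[i], N1[i], K2[i], N2[i])
    }, numeric(1L))
    data.frame(chrom = ch, start = as.integer(starts),
               mid = as.integer(starts + bin_bp %/% 2L),
               lod = smooth_track(raw, smooth_bw_bins, smooth_mode),
               lod_raw = raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  attr(out, "bin_bp") <- bin_bp
  class(out) <- c("lod_track", "data.frame")
  out
}

#' Call LOD peaks
#'
#' Local maxima of the track above `threshold`, selected greedily in
#' decreasing LOD order while suppressing further candidates within
#' `min_sep_bp` on the same chromosome.
#'
#' @param track A `lod_track` from [lod_scan()].
#' @param threshold Minimum LOD (default 75).
#' @param min_sep_bp Minimum separation between peaks in bp (default 1 Mb).
#' @return Data frame with `chrom`, `peak_pos` (bin midpoint), `peak_lod`.
#' @export
call_peaks <- function(track, threshold = 75, min_sep_bp = 1000000L) {
  stopifnot(inherits(track, "lod_track"))
  cand <- do.call(rbind, lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    n <- nrow(tr)
    if (n == 0L) return(NULL)
    left <- c(-Inf, tr$lod[-n])
    right <- c(tr$lod[-1L], -Inf)
    tr[tr$lod > threshold & tr$lod >= left & tr$lod >= right, , drop = FALSE]
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(chrom = character(), peak_pos = integer(),
                      peak_lod = numeric(), stringsAsFactors = FALSE))
  }
  cand <- cand[order(-cand$lod, cand$chrom, cand$mid), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sel <- keep & cand$chrom == cand$chrom[i] &
      abs(cand$mid - cand$mid[i]) < min_sep_bp
    if (!any(sel)) keep[i] <- TRUE
  }
  out <- data.frame(chrom = cand$chrom[keep], peak_pos = cand$mid[keep],
                    peak_lod = cand$lod[keep], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$peak_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 90% credible interval around a LOD peak
#'
#' Recomputes the LOD track from the counts of a window centred at the
#' peak, converts it to a bin posterior proportional to 10^LOD normalised
#' over the window, and returns the smallest contiguous run of bins
#' containing the peak bin whose cumulative mass reaches `mass`, grown
#' greedily toward the neighbour with higher mass.  The default `"mean"`
#' smoothing tempers the composite likelihood: linked bins measure the same
#' underlying frequency contrast, so for localisation their scores are
#' averaged rather than summed (the summed track would overstate positional
#' precision).
#'
#' @param merged_LD,merged_DD Single-population `count_table`s.
#' @param chrom,peak_pos Peak location (e.g. from [call_peaks()]).
#' @param window_bp Window width centred at the peak (default 1 Mb; widen
#'   for peaks whose elevated scores extend further).
#' @param mass Posterior mass of the interval (default 0.90).
#' @param bin_bp,pool_n,smooth_bw_bins,smooth_mode,... Passed to
#'   [lod_scan()] for the recomputation.
#' @return List with `ci_start`, `ci_end` (bp; `ci_end - ci_start` equals
#'   the span), `span_kb`, and `posterior` (data frame of bins and masses).
#' @export
credible_interval <- function(merged_LD, merged_DD, chrom, peak_pos,
                              window_bp = 1000000L, mass = 0.90,
                              bin_bp = 1000L, pool_n = 3000L,
                              smooth_bw_bins = 100,
                              smooth_mode = "mean", ...) {
  stopifnot(mass > 0, mass <= 1)
  half <- window_bp / 2
  sel <- merged_LD$chrom == chrom & merged_LD$pos >= peak_pos - half &
    merged_LD$pos <= peak_pos + half
  if (!any(sel)) stop("no SNPs in the credible-interval window", call. = FALSE)
  if (peak_pos - half < 1) {
    message("credible_interval: window truncated at chromosome start")
  }
  keep <- snp_key(merged_LD$chrom, merged_LD$pos)[sel]
  track <- lod_scan(filter_snps(merged_LD, keep), filter_snps(merged_DD, keep),
                    bin_bp = bin_bp, pool_n = pool_n,
                    smooth_bw_bins = smooth_bw_bins,
                    smooth_mode = smooth_mode, ...)
  w <- 10^(track$lod - max(track$lod))
  w <- w / sum(w)
  nb <- length(w)
  peak_bin <- which.min(abs(track$mid - peak_pos))
  a <- b <- peak_bin
  cum <- w[peak_bin]
  while (cum < mass && (a > 1L || b < nb)) {
    left <- if (a > 1L) w[a - 1L] else -Inf
    right <- if (b < nb) w[b + 1L] else -Inf
    if (left >= right) {
      a <- a - 1L; cum <- cum + w[a]
    } else {
      b <- b + 1L; cum <- cum + w[b]
    }
  }
  ci_start <- track$start[a]
  ci_end <- track$start[b] + bin_bp
  list(ci_start = ci_start, ci_end = ci_end,
       span_kb = (ci_end - ci_start) / 1000,
       posterior = data.frame(start = track$start, mid = track$mid,
                              mass = w, stringsAsFactors = FALSE))
  }

#' LOD peaks with credible intervals
#'
#' Convenience wrapper: runs [lod_scan()], [call_peaks()] and
#' [credible_interval()] and returns one row per peak.
#'
#' @inheritParams lod_scan
#' @inheritParams call_peaks
#' @param ci_window_bp,ci_mass,ci_smooth_bw_bins Credible-interval
#'   settings.  With `ci_window_bp = NULL` (default) the window of each
#'   peak is widened to the contiguous stretch of elevated composite LOD
#'   (above half the detection threshold) around it, clamped between 1 and
#'   3 Mb: peaks whose high scores extend further than the basic 1 Mb
#'   window get a proportionally wider localisation window.
#' @return Data frame with `chrom`, `peak_pos`, `peak_lod`, `ci_start`,
#'   `ci_end`, `span_kb`.
#' @export
lod_peaks_with_ci <- function(merged_LD, merged_DD, bin_bp = 1000L,
                              pool_n = 3000L, smooth_bw_bins = 30,
                              threshold = 75, min_sep_bp = 1000000L,
                              ci_window_bp = NULL, ci_mass = 0.90,
                              ci_smooth_bw_bins = 100) {
  track <- lod_scan(merged_LD, merged_DD, bin_bp = bin_bp, pool_n = pool_n,
                    smooth_bw_bins = smooth_bw_bins, smooth_mode = "sum")
  peaks <- call_peaks(track, threshold = threshold, min_sep_bp = min_sep_bp)
  if (nrow(peaks) == 0L) {
    peaks$ci_start <- integer()
    peaks$ci_end <- integer()
    peaks$span_kb <- numeric()
    return(peaks)
  }
  window_for <- function(i) {
    if (!is.null(ci_window_bp)) return(ci_window_bp)
    tr <- track[track$chrom == peaks$chrom[i], , drop = FALSE]
    d <- tr$mid - peaks$peak_pos[i]
    high <- abs(d) <= 1500000 & tr$lod >= threshold / 2
    extent <- if (any(high)) 2 * max(abs(d[high])) else 0
    min(max(1000000, extent), 3000000)
  }
  ci <- lapply(seq_len(nrow(peaks)), function(i) {
    credible_interval(merged_LD, merged_DD, peaks$chrom[i],
                      peaks$peak_pos[i], window_bp = window_for(i),
                      mass = ci_mass, bin_bp = bin_bp, pool_n = pool_n,
                      smooth_bw_bins = ci_smooth_bw_bins)
  })
  peaks$ci_start <- vapply(ci, `[[`, numeric(1L), "ci_start")
  peaks$ci_end <- vapply(ci, `[[`, numeric(1L), "ci_end")
  peaks$span_kb <- vapply(ci, `[[`, numeric(1L), "span_kb")
  peaks
}

#' Dominant trajectory type of each peak interval
#'
#' Assigns each peak the majority trajectory type among the typed SNPs
#' falling inside its credible interval (ties broken in favour of the
#' lower type number; `"none"` when the interval holds no typed SNP).
#'
#' @param peaks Output of [lod_peaks_with_ci()].
#' @param scan A `scan_result` from [classify_significant()].
#' @return `peaks` with an added `selection_type` column.
#' @export
peak_selection_type <- function(peaks, scan) {
  stopifnot(all(c("chrom", "ci_start", "ci_end") %in% names(peaks)),
            all(c("chrom", "pos", "type_label") %in% names(scan)))
  typed <- scan[scan$type_label != "none", , drop = FALSE]
  peaks$selection_type <- vapply(seq_len(nrow(peaks)), function(i) {
    hit <- typed$chrom == peaks$chrom[i] &
      typed$pos >= peaks$ci_start[i] & typed$pos <= peaks$ci_end[i]
    if (!any(hit)) return("none")
    tab <- table(typed$type_label[hit])
    names(tab)[which.max(tab)]
  }, "")
  peaks
}
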