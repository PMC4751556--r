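#' Qualify an allele-specific primer pair
#'
#' An allele-specific primer pair discriminates the two alleles through the
#' 3' terminal mismatch: on a pure template the matched primer must reach
#' threshold more than `min_delta` cycles before the mismatched one, on
#' both pure templates (dark-founder and reference genomic DNA).
#'
#' @param ct_pure_dark Length-2 numeric: Ct of the (dark-allele primer,
#'   reference primer) reactions on pure dark-founder template.
#' @param ct_pure_ref The same on pure reference template.
#' @param min_delta Minimum discrimination in cycles (default 4.25,
#'   strictly exceeded).
#' @return `TRUE` if the pair qualifies.
#' @examples
#' qualify_primers(c(20, 25), c(26, 21))       # passes
#' qualify_primers(c(20, 24.25), c(26, 21))    # exactly 4.25 fails
#' @export
qualify_primers <- function(ct_pure_dark, ct_pure_ref, min_delta = 4.25) {
  stopifnot(length(ct_pure_dark) == 2L, length(ct_pure_ref) == 2L,
            all(is.finite(c(ct_pure_dark, ct_pure_ref))))
  (ct_pure_dark[[2L]] - ct_pure_dark[[1L]] > min_delta) &&
    (ct_pure_ref[[1L]] - ct_pure_ref[[2L]] > min_delta)
}

#' Estimate dark-allele frequency from qPCR cycle differences
#'
#' With per-cycle amplification efficiency E, a template containing the
#' dark allele at frequency f yields dCt = Ct(dark primer) - Ct(ref primer)
#' = log_E((1 - f) / f) plus a primer-specific offset.  Normalising against
#' a 50:50 calibrator (ddCt = dCt_sample - dCt_calibrator) removes the
#' offset and inverts to f = 1 / (1 + E^ddCt).
#'
#' @param delta_ct_sample dCt of the sample (dark-primer Ct minus
#'   ref-primer Ct).
#' @param delta_ct_calibrator dCt of the f = 0.5 calibrator.
#' @param efficiency Per-cycle amplification factor (default 2, perfect
#'   doubling).
#' @return Estimated frequency in (0, 1).
#' @examples
#' estimate_freq_from_ct(0, 0)                  # 0.5
#' estimate_freq_from_ct(log2(1 / 9), 0)        # 0.9
#' @export
estimate_freq_from_ct <- function(delta_ct_sample, delta_ct_calibrator = 0,
                                  efficiency = 2) {
  stopifnot(all(is.finite(delta_ct_sample)),
            all(is.finite(delta_ct_calibrator)), efficiency > 1)
  ddct <- delta_ct_sample - delta_ct_calibrator
  1 / (1 + efficiency^ddct)
}

#' Estimate frequencies for a batch of qPCR records
#'
#' @param records Data frame with columns `snp_id`, `sample_id`, `ct_dark`,
#'   `ct_ref`, `is_calibrator`; exactly one calibrator row per `snp_id`.
#' @param efficiency Per-cycle amplification factor.
#' @return `records` with added columns `delta_ct`, `delta_delta_ct` and
#'   `estimated_freq`.
#' @export
estimate_freqs_qpcr <- function(records, efficiency = 2) {
  need <- c("snp_id", "sample_id", "ct_dark", "ct_ref", "is_calibrator")
  if (!all(need %in% names(records))) {
    stop("qPCR records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$ct_dark <= 0 | records$ct_ref <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  records$delta_ct <- records$ct_dark - records$ct_ref
  out <- lapply(split(records, records$snp_id), function(g) {
    cal <- which(g$is_calibrator)
    if (length(cal) != 1L) {
      stop("need exactly one calibrator for SNP ", g$snp_id[1L],
           " (found ", length(cal), ")", call. = FALSE)
    }
    g$delta_delta_ct <- g$delta_ct - g$delta_ct[cal]
    g$estimated_freq <- estimate_freq_from_ct(g$delta_ct, g$delta_ct[cal],
                                              efficiency = efficiency)
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Concordance between qPCR and sequencing frequencies
#'
#' Coefficient of determination (R^2) of the ordinary least-squares fit of
#' qPCR-estimated frequencies on sequencing-based frequencies.
#'
#' @param freq_qpcr,freq_ngs Numeric vectors of equal length (>= 3).
#' @return R^2 in \[0, 1\].
#' @export
concordance <- function(freq_qpcr, freq_ngs) {
  stopifnot(length(freq_qpcr) == length(freq_ngs), length(freq_qpcr) >= 3)
  if (stats::sd(freq_qpcr) == 0 || stats::sd(freq_ngs) == 0) {
    stop("concordance undefined for zero-variance input", call. = FALSE)
  }
  ## R^2 of the simple OLS fit with intercept equals the squared
  ## correlation
  stats::cor(freq_qpcr, freq_ngs)^2
}

#' Read a qPCR Ct CSV
#'
#' Expected columns: `snp_id`, `sample_id`, `ct_dark`, `ct_ref`,
#' `is_calibrator`.
#'
#' @param path CSV path.
#' @return Data frame of qPCR records.
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_calibrator <- as.logical(df$is_calibrator)
  df
}
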