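#' Competition assay parameters
#'
#' @param prob Named probabilities of the four progeny classes
#'   (`W`, `G`, `R`, `Y`); must be non-negative and sum to 1.
#' @param n_offspring Progeny per replicate vial.
#' @return An `assay_params` list.
#' @export
assay_params <- function(prob = c(W = 0.25, G = 0.25, R = 0.25, Y = 0.25),
                         n_offspring = 200L) {
  stopifnot(all(c("W", "G", "R", "Y") %in% names(prob)),
            n_offspring >= 1)
  prob <- prob[c("W", "G", "R", "Y")]
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-8) {
    stop("class probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(prob = prob, n_offspring = as.integer(n_offspring)),
            class = "assay_params")
}

#' Simulate a four-class competition assay
#'
#' Progeny counts per replicate vial are Multinomial(`n_offspring`,
#' class probabilities).
#'
#' @param params An [assay_params()] object.
#' @param n_replicates Number of replicate vials.
#' @param condition Condition label attached to the output.
#' @param seed Integer seed.
#' @return Data frame with columns `condition`, `replicate`, `W`, `G`,
#'   `R`, `Y`.
#' @export
simulate_competition_assay <- function(params, n_replicates = 10L,
                                       condition = "DD", seed = NULL) {
  stopifnot(inherits(params, "assay_params"), n_replicates >= 1)
  local_seed(seed, {
    m <- stats::rmultinom(n_replicates, params$n_offspring, params$prob)
    data.frame(condition = condition, replicate = seq_len(n_replicates),
               W = m[1L, ], G = m[2L, ], R = m[3L, ], Y = m[4L, ],
               stringsAsFactors = FALSE)
  })
}

#' Simulate allele-specific qPCR measurements
#'
#' For a template with dark-allele frequency f, the cycle difference
#' between the allele-specific reactions is
#' dCt = log2((1 - f) / f) + offset + Normal(0, `ct_noise_sd`), where the
#' offset is a primer-specific constant removed by calibration.  A
#' calibrator sample at f = 0.5 is appended per SNP.
#'
#' @param true_freqs Frequencies of the test samples, strictly inside
#'   (0, 1); a pure template (f of 0 or 1) has no finite dCt.
#' @param ct_noise_sd Cycle noise standard deviation (default 0.3).
#' @param snp_id SNP identifier for the batch.
#' @param primer_offset Primer-specific dCt offset in cycles.
#' @param base_ct Reference-primer Ct assigned to every reaction.
#' @param seed Integer seed.
#' @return Data frame in the layout of [estimate_freqs_qpcr()] input, with
#'   the true frequency kept in `true_freq`.
#' @export
simulate_qpcr <- function(true_freqs, ct_noise_sd = 0.3, snp_id = "snp1",
                          primer_offset = 0.8, base_ct = 22, seed = NULL) {
  if (any(true_freqs <= 0 | true_freqs >= 1)) {
    stop("true_freqs must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(ct_noise_sd >= 0, base_ct > 0)
  local_seed(seed, {
    f <- c(true_freqs, 0.5)
    n <- length(f)
    dct <- log2((1 - f) / f) + primer_offset +
      stats::rnorm(n, 0, ct_noise_sd)
    data.frame(
      snp_id = snp_id,
      sample_id = c(paste0("sample", seq_along(true_freqs)), "calibrator"),
      ct_dark = base_ct + dct,
      ct_ref = base_ct,
      is_calibrator = c(rep(FALSE, length(true_freqs)), TRUE),
      true_freq = f,
      stringsAsFactors = FALSE)
  })
}

#' Convert population weights to fly counts
#'
#' Census sizes of the mixed populations are estimated by weighing frozen
#' flies against a calibration weighing (by default 320 flies = 0.42 g).
#'
#' @param weights_g Numeric vector of population weights in grams.
#' @param calibration_flies,calibration_g The calibration pair.
#' @return Integer vector of estimated fly counts.
#' @examples
#' weights_to_counts(c(0.42, 0.84))
#' @export
weights_to_counts <- function(weights_g, calibration_flies = 320L,
                              calibration_g = 0.42) {
  if (calibration_g <= 0) stop("calibration_g must be positive", call. = FALSE)
  if (any(weights_g < 0)) stop("negative weight", call. = FALSE)
  as.integer(round(weights_g * calibration_flies / calibration_g))
}
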