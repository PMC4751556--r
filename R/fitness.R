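#' Classify competition-assay progeny by fluorescent markers
#'
#' In the four-way competition assay the tester strain carries no marker,
#' competitor females carry GFP and competitor males carry DsRed, so the
#' marker combination of an offspring identifies its parental pairing:
#' neither marker = White (tester x tester), GFP only = Green (competitor
#' female x tester male), DsRed only = Red (tester female x competitor
#' male), both = Yellow (competitor x competitor).
#'
#' @param gfp,dsred Logical vectors of marker expression.
#' @return Character vector in `c("White", "Green", "Red", "Yellow")`.
#' @examples
#' classify_progeny(c(FALSE, TRUE), c(FALSE, TRUE))
#' @export
classify_progeny <- function(gfp, dsred) {
  stopifnot(is.logical(gfp), is.logical(dsred), length(gfp) == length(dsred))
  ifelse(gfp,
         ifelse(dsred, "Yellow", "Green"),
         ifelse(dsred, "Red", "White"))
}

#' Comparative fitness (CF) of the tester strain
#'
#' CF measures the tester's genomic contribution to the offspring pool:
#' CF = (2 W + 1 (G + R) + 0 Y) / (2 (W + G + R + Y)) x 100, where W, G,
#' R, Y are White/Green/Red/Yellow progeny counts.  CF = 50 means tester
#' and competitor contributed equally; CF of the competitor is obtained by
#' swapping W and Y, and the two always sum to 100.
#'
#' @param counts A named numeric vector with elements `W`, `G`, `R`, `Y`,
#'   or a data frame with those columns (one row per replicate vial).
#' @return CF in percent (vector if `counts` has several rows).
#' @examples
#' comparative_fitness(c(W = 25, G = 25, R = 25, Y = 25))
#' @export
comparative_fitness <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("W", "G", "R", "Y") %in% names(counts)))
    W <- counts$W; G <- counts$G; R <- counts$R; Y <- counts$Y
  } else {
    stopifnot(all(c("W", "G", "R", "Y") %in% names(counts)))
    W <- counts[["W"]]; G <- counts[["G"]]; R <- counts[["R"]]
    Y <- counts[["Y"]]
  }
  if (any(c(W, G, R, Y) < 0)) stop("negative progeny count", call. = FALSE)
  total <- W + G + R + Y
  if (any(total == 0)) {
    stop("comparative fitness undefined for empty progeny table",
         call. = FALSE)
  }
  (2 * W + G + R) / (2 * total) * 100
}

#' Angular (variance-stabilising) transformation of proportions
#'
#' @param p Proportions in \[0, 1\].
#' @return `asin(sqrt(p))` in radians.
#' @export
angular <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  asin(sqrt(p))
}

#' Exact two-sided Mann-Whitney test
#'
#' Exact conditional Mann-Whitney (Wilcoxon rank-sum) test by full
#' enumeration of group assignments, with ties handled by mid-ranks.  The
#' two-sided p-value is the probability, over all assignments of the pooled
#' values to the two groups, of a rank sum at least as far from its null
#' expectation as the observed one (for the symmetric tie-free null this
#' equals doubling the smaller tail).
#'
#' @param x,y Numeric samples.
#' @param max_enum Largest number of assignments enumerated (guard).
#' @return List with `statistic` (rank sum of `x`) and `p_value`.
#' @export
mann_whitney_exact <- function(x, y, max_enum = 5e6) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n <- n1 + length(y)
  if (choose(n, n1) > max_enum) {
    stop("too many assignments to enumerate (", choose(n, n1), ")",
         call. = FALSE)
  }
  r <- rank(c(x, y))  # mid-ranks
  w_obs <- sum(r[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
  list(statistic = w_obs, p_value = p)
}

#' Condition contrast of progeny proportions
#'
#' Tests per-vial progeny proportions between the two light conditions
#' with an exact two-sided Mann-Whitney test and with a Welch t-test on
#' angular-transformed proportions (Welch-Satterthwaite df).
#'
#' @param props_LD,props_DD Numeric vectors of per-vial proportions in
#'   \[0, 1\], length >= 2 each.
#' @return List with `mw_p`, `mw_statistic`, `welch_p`, `welch_statistic`,
#'   `welch_df`.
#' @export
proportion_tests <- function(props_LD, props_DD) {
  stopifnot(length(props_LD) >= 2, length(props_DD) >= 2,
            all(props_LD >= 0 & props_LD <= 1),
            all(props_DD >= 0 & props_DD <= 1))
  mw <- mann_whitney_exact(props_LD, props_DD)
  a1 <- angular(props_LD)
  a2 <- angular(props_DD)
  if (stats::sd(a1) == 0 && stats::sd(a2) == 0) {
    message("proportion_tests: constant samples; Welch p degenerate")
    welch <- list(statistic = 0, parameter = NA_real_,
                  p.value = if (mean(a1) == mean(a2)) 1 else 0)
  } else {
    welch <- stats::t.test(a1, a2, var.equal = FALSE)
  }
  list(mw_p = mw$p_value, mw_statistic = mw$statistic,
       welch_p = welch$p.value,
       welch_statistic = unname(welch$statistic),
       welch_df = unname(welch$parameter))
}

#' Read a progeny count CSV
#'
#' Expected columns: `condition`, `replicate`, `W`, `G`, `R`, `Y`.
#'
#' @param path CSV path.
#' @return Data frame of progeny counts.
#' @export
read_progeny_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "W", "G", "R", "Y")
  if (!all(need %in% names(df))) {
    stop("progeny CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
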