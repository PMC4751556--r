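#' Mean frequency trajectories per SNP type
#'
#' For each trajectory type and condition, averages the per-replicate
#' SNP frequencies at every recorded generation.  Population columns of
#' `freqs` must be labelled as by [pop_label()]; replicates of a condition
#' are averaged per SNP first (unweighted), then across the SNPs of a type.
#'
#' @param freqs A `freq_table` holding all recorded populations
#'   (generations x conditions x replicates).
#' @param types Data frame with columns `chrom`, `pos`, `type_label`
#'   (for example a [classify_significant()] result); SNPs labelled
#'   `"none"` are ignored.
#' @return List with `summary` (data frame `type_label`, `condition`,
#'   `generation`, `mean_freq`, `n_snps`) and `trajectories` (long data
#'   frame of per-SNP mean-replicate frequencies).
#' @export
trajectory_summary <- function(freqs, types) {
  stopifnot(inherits(freqs, "freq_table"),
            all(c("chrom", "pos", "type_label") %in% names(types)))
  pops <- populations(freqs)
  meta <- parse_pop_label(pops)
  types <- types[types$type_label != "none", , drop = FALSE]
  empty <- list(
    summary = data.frame(type_label = character(), condition = character(),
                         generation = integer(), mean_freq = numeric(),
                         n_snps = integer(), stringsAsFactors = FALSE),
    trajectories = data.frame(chrom = character(), pos = integer(),
                              type_label = character(),
                              condition = character(),
                              generation = integer(), freq = numeric(),
                              stringsAsFactors = FALSE))
  if (nrow(types) == 0L) return(empty)

  idx <- match(snp_key(types$chrom, types$pos), snp_key(freqs$chrom, freqs$pos))
  if (anyNA(idx)) {
    stop("typed SNPs absent from the frequency table", call. = FALSE)
  }
  traj <- list()
  ## the generation-0 base population predates the LD/DD split and is
  ## shared by both conditions
  conds <- setdiff(unique(meta$condition), "base")
  for (cond in conds) {
    for (gen in sort(unique(meta$generation))) {
      sel <- pops[(meta$condition == cond | meta$condition == "base") &
                    meta$generation == gen]
      if (length(sel) == 0L) next
      fm <- as.matrix(freqs[idx, sel, drop = FALSE])
      traj[[length(traj) + 1L]] <- data.frame(
        chrom = types$chrom, pos = types$pos,
        type_label = types$type_label, condition = cond,
        generation = gen, freq = rowMeans(fm),
        stringsAsFactors = FALSE)
    }
  }
  trajectories <- do.call(rbind, traj)
  agg <- stats::aggregate(freq ~ type_label + condition + generation,
                          data = trajectories, FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(freq ~ type_label + condition + generation,
                          data = trajectories,
                          FUN = function(z) sum(!is.na(z)))
  names(agg)[names(agg) == "freq"] <- "mean_freq"
  agg$n_snps <- cnt$freq
  list(summary = agg[order(agg$type_label, agg$condition, agg$generation), ],
       trajectories = trajectories)
}

#' Non-metric MDS embedding of population frequency profiles
#'
#' Embeds populations in two dimensions by Kruskal non-metric MDS
#' ([MASS::isoMDS()]) of the Euclidean distances between their SNP
#' frequency vectors (complete-case SNPs only).  Populations with exactly
#' identical profiles (zero distance) are collapsed onto one point, since
#' zero dissimilarities are inadmissible in the stress minimisation.
#'
#' @param freqs A multi-population `freq_table` (at least 3 populations).
#' @return List with `points` (data frame `population`, `dim1`, `dim2`) and
#'   `stress` (Kruskal stress-1, percent).
#' @export
mds_embed <- function(freqs) {
  stopifnot(inherits(freqs, "freq_table"))
  pops <- populations(freqs)
  if (length(pops) < 3L) {
    stop("MDS needs at least 3 populations", call. = FALSE)
  }
  fm <- as.matrix(freqs[, pops, drop = FALSE])
  fm <- fm[stats::complete.cases(fm), , drop = FALSE]
  if (nrow(fm) < 2L) stop("too few complete-case SNPs for MDS", call. = FALSE)
  profiles <- t(fm)

  dup <- duplicated(profiles)
  uniq <- which(!dup)
  rep_of <- uniq[match(
    apply(profiles, 1L, paste, collapse = "\r"),
    apply(profiles[uniq, , drop = FALSE], 1L, paste, collapse = "\r"))]

  nu <- length(uniq)
  if (nu == 1L) {
    pts <- matrix(0, nrow = 1L, ncol = 2L)
    stress <- 0
  } else if (nu == 2L) {
    d <- sqrt(sum((profiles[uniq[1L], ] - profiles[uniq[2L], ])^2))
    pts <- rbind(c(-d / 2, 0), c(d / 2, 0))
    stress <- 0
  } else {
    dd <- stats::dist(profiles[uniq, , drop = FALSE])
    fit <- MASS::isoMDS(dd, k = 2L, trace = FALSE)
    pts <- fit$points
    stress <- fit$stress
  }
  coords <- pts[match(rep_of, uniq), , drop = FALSE]
  list(points = data.frame(population = pops,
                           dim1 = coords[, 1L], dim2 = coords[, 2L],
                           stringsAsFactors = FALSE),
       stress = stress)
}

#' Expected/observed quantile pairs for QQ plotting of p-values
#'
#' @param p Numeric vector of p-values in (0, 1\]; exact zeros are clamped
#'   to the smallest positive double with a message.
#' @return Data frame with `expected` and `observed` -log10 p columns, both
#'   in decreasing order (most extreme point first).
#' @export
qq_data <- function(p) {
  stopifnot(length(p) >= 1, all(!is.na(p)), all(p <= 1), all(p >= 0))
  if (any(p == 0)) {
    message("qq_data: clamped ", sum(p == 0), " zero p-value(s)")
    p[p == 0] <- .Machine$double.xmin
  }
  m <- length(p)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = sort(-log10(p), decreasing = TRUE))
}
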