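#' Allele count tables
#'
#' A `count_table` is a data frame keyed by (`chrom`, `pos`, `ref`, `dark`)
#' with, per population, two integer columns `<label>_dark` and
#' `<label>_other` holding the read counts supporting the dark-founder
#' allele and the reference allele.  Population labels follow
#' [pop_label()].  Positions are 1-based and sorted within chromosome.
#'
#' @param keys Data frame with columns `chrom`, `pos`, `ref`, `dark`.
#' @param counts Named list; each element a list/data frame with integer
#'   vectors `dark` and `other`, named by population label.
#' @return A `count_table`.
#' @export
count_table <- function(keys, counts) {
  stopifnot(all(c("chrom", "pos", "ref", "dark") %in% names(keys)))
  if (anyDuplicated(snp_key(keys$chrom, keys$pos))) {
    stop("duplicate (chrom, pos) keys in count table", call. = FALSE)
  }
  ord <- order(keys$chrom, keys$pos)
  x <- data.frame(chrom = keys$chrom, pos = as.integer(keys$pos),
                  ref = keys$ref, dark = keys$dark,
                  stringsAsFactors = FALSE)[ord, , drop = FALSE]
  for (lab in names(counts)) {
    d <- as.integer(counts[[lab]]$dark)[ord]
    o <- as.integer(counts[[lab]]$other)[ord]
    if (any(d < 0 | o < 0, na.rm = TRUE)) {
      stop("negative counts for population ", lab, call. = FALSE)
    }
    x[[paste0(lab, "_dark")]] <- d
    x[[paste0(lab, "_other")]] <- o
  }
  rownames(x) <- NULL
  attr(x, "pops") <- names(counts)
  class(x) <- c("count_table", "data.frame")
  x
}

#' @rdname count_table
#' @param x A `count_table` or `freq_table`.
#' @export
populations <- function(x) attr(x, "pops")

## counts of one population as a two-column matrix (dark, other)
pop_counts <- function(x, label) {
  cbind(dark = x[[paste0(label, "_dark")]],
        other = x[[paste0(label, "_other")]])
}

#' Combine the populations of several count tables
#'
#' All tables must cover exactly the same SNPs; population labels must not
#' collide.
#'
#' @param tables List of `count_table`s.
#' @return A single `count_table` holding all populations.
#' @export
bind_populations <- function(tables) {
  stopifnot(length(tables) >= 1)
  check_same_keys(tables)
  keys <- tables[[1L]][, c("chrom", "pos", "ref", "dark")]
  counts <- list()
  for (tb in tables) {
    for (lab in populations(tb)) {
      if (lab %in% names(counts)) {
        stop("duplicated population label: ", lab, call. = FALSE)
      }
      cc <- pop_counts(tb, lab)
      counts[[lab]] <- list(dark = cc[, "dark"], other = cc[, "other"])
    }
  }
  count_table(keys, counts)
}

check_same_keys <- function(tables) {
  k0 <- snp_key(tables[[1L]]$chrom, tables[[1L]]$pos)
  for (i in seq_along(tables)[-1L]) {
    ki <- snp_key(tables[[i]]$chrom, tables[[i]]$pos)
    if (length(ki) != length(k0) || any(ki != k0)) {
      off <- union(setdiff(ki, k0), setdiff(k0, ki))
      stop("count tables do not cover the same SNPs; first offenders: ",
           paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Sample pooled sequencing reads from a simulated population
#'
#' Emulates pool-seq of the whole population: per SNP the true pool
#' frequency is f = (dark-allele copies) / 2N, sequencing depth is drawn
#' per `depth_model`, and dark-supporting reads are Binomial(depth,
#' f (1 - e) + (1 - f) e) with symmetric per-read error rate e.
#'
#' @param state A `population_state`.
#' @param mean_depth Mean sequencing depth per SNP.
#' @param depth_model `"poisson"` (depth ~ Poisson(mean_depth)) or
#'   `"fixed"` (every SNP at exactly `mean_depth`).
#' @param error_rate Per-read allele flip probability, in \[0, 0.1\].
#' @param label Population label; defaults to
#'   `g{generation}_{condition}{replicate}` from the state.
#' @param seed Integer seed.
#' @return A single-population [count_table()].
#' @export
sample_pooled_reads <- function(state, mean_depth = 179,
                                depth_model = c("poisson", "fixed"),
                                error_rate = 0.001, label = NULL,
                                seed = NULL) {
  stopifnot(inherits(state, "population_state"), mean_depth > 0)
  depth_model <- match.arg(depth_model)
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must be in [0, 0.1]", call. = FALSE)
  }
  founder <- attr(state, "founder")
  label <- label %||% pop_label(state$generation, state$condition,
                                state$replicate_id)
  f <- dark_freq(state)
  n <- length(f)
  local_seed(seed, {
    depth <- switch(depth_model,
      poisson = stats::rpois(n, mean_depth),
      fixed = rep(as.integer(round(mean_depth)), n)
    )
    p_read <- f * (1 - error_rate) + (1 - f) * error_rate
    k <- stats::rbinom(n, depth, p_read)
    keys <- data.frame(chrom = founder$chrom, pos = founder$pos,
                       ref = founder$ref_allele, dark = founder$dark_allele,
                       stringsAsFactors = FALSE)
    counts <- stats::setNames(list(list(dark = k, other = depth - k)), label)
    count_table(keys, counts)
  })
}

#' Estimate per-population dark-allele frequencies
#'
#' Frequencies are count_dark / depth; SNPs whose depth is below
#' `min_coverage` in a population are flagged missing (`NA`) there and are
#' excluded from downstream tests that use that population.
#'
#' @param counts A `count_table`.
#' @param min_coverage Minimum depth for a frequency call (default 5).
#' @return A `freq_table`: data frame with the key columns plus one numeric
#'   frequency column per population; the per-population depth matrix is
#'   kept in attribute `depth`.
#' @export
estimate_frequencies <- function(counts, min_coverage = 5L) {
  stopifnot(inherits(counts, "count_table"), min_coverage >= 1)
  pops <- populations(counts)
  out <- counts[, c("chrom", "pos", "ref", "dark")]
  depth <- matrix(0L, nrow = nrow(counts), ncol = length(pops),
                  dimnames = list(NULL, pops))
  for (lab in pops) {
    cc <- pop_counts(counts, lab)
    d <- cc[, "dark"] + cc[, "other"]
    f <- ifelse(d >= min_coverage, cc[, "dark"] / d, NA_real_)
    out[[lab]] <- f
    depth[, lab] <- d
  }
  attr(out, "pops") <- pops
  attr(out, "depth") <- depth
  attr(out, "min_coverage") <- min_coverage
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Select founder SNPs from the generation-0 frequency table
#'
#' Keeps SNPs whose generation-0 frequency lies in \[`lo`, `hi`\]
#' (inclusive bounds) with adequate coverage; all downstream analyses are
#' restricted to this set.  In an F1-hybrid base population genuine
#' founder-diagnostic SNPs sit near frequency 0.5.
#'
#' @param gen0 A single-population `freq_table` for generation 0.
#' @param lo,hi Inclusive frequency bounds (defaults 0.4 and 0.6).
#' @return Character vector of SNP keys (`"chrom:pos"`).
#' @export
select_founder_snps <- function(gen0, lo = 0.4, hi = 0.6) {
  stopifnot(inherits(gen0, "freq_table"))
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  pops <- populations(gen0)
  if (length(pops) != 1L) {
    stop("select_founder_snps expects a single-population table", call. = FALSE)
  }
  f <- gen0[[pops]]
  keep <- !is.na(f) & f >= lo & f <= hi
  snp_key(gen0$chrom, gen0$pos)[keep]
}

#' Restrict a table to a set of SNP keys
#'
#' @param x A `count_table` or `freq_table`.
#' @param keys Character vector of `"chrom:pos"` keys.
#' @return The table restricted to `keys`, attributes preserved.
#' @export
filter_snps <- function(x, keys) {
  keep <- snp_key(x$chrom, x$pos) %in% keys
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pops") <- attr(x, "pops")
  if (!is.null(attr(x, "depth"))) {
    attr(out, "depth") <- attr(x, "depth")[keep, , drop = FALSE]
  }
  class(out) <- class(x)
  out
}
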