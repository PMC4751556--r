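#' Read and write popoolation2-style sync files
#'
#' The sync format is tab-delimited with columns `chrom`, `pos`, `ref` and
#' one `A:T:C:G:N:del` count field per population.  `write_sync()` places
#' dark-allele counts on the dark base and reference-supporting counts on
#' the reference base.  Because sync itself carries no notion of which
#' allele is founder-diagnostic, `read_sync()` takes the designation from a
#' founder map (`chrom`, `pos`, `ref_allele`, `dark_allele`); without one it
#' infers the dark allele as the non-reference base with the highest total
#' count across populations and refuses ambiguous sites (ties) rather than
#' guessing.
#'
#' @param path File path.
#' @param labels Population labels, in column order.  Required by
#'   `read_sync()` when more than one population column is present
#'   (defaults to `pop1`, `pop2`, ...).
#' @param founder Optional founder map data frame designating the dark
#'   allele per site.
#' @param multiallelic_frac Sites where a base other than the reference and
#'   dark alleles exceeds this fraction of a population's depth are dropped
#'   (with a message); such sites violate the biallelic model.
#' @return `read_sync()` returns a [count_table()]; `write_sync()` returns
#'   `path` invisibly.
#' @export
read_sync <- function(path, labels = NULL, founder = NULL,
                      multiallelic_frac = 0.05) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty sync file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L]) || nf[1L] < 4L) {
    bad <- which(nf != nf[1L])[1L] %||% 1L
    stop("ragged sync line ", bad, " in ", path, call. = FALSE)
  }
  npop <- nf[1L] - 3L
  labels <- labels %||% paste0("pop", seq_len(npop))
  if (length(labels) != npop) {
    stop("expected ", npop, " population labels, got ", length(labels),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- vapply(fields, `[[`, "", 3L)
  bases <- c("A", "T", "C", "G")
  ## counts[[p]] is a 6-column matrix A:T:C:G:N:del
  counts <- vector("list", npop)
  for (p in seq_len(npop)) {
    col <- vapply(fields, `[[`, "", 3L + p)
    parts <- strsplit(col, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 6L)
    if (length(bad) > 0L) {
      stop("malformed sync count field (expected 6 ':' fields) at line ",
           bad[1L], " in ", path, call. = FALSE)
    }
    m <- matrix(suppressWarnings(as.integer(unlist(parts))),
                ncol = 6L, byrow = TRUE)
    if (anyNA(m)) {
      stop("non-numeric count at line ", which(rowSums(is.na(m)) > 0)[1L],
           " in ", path, call. = FALSE)
    }
    counts[[p]] <- m
  }
  if (!all(ref %in% bases)) {
    stop("unknown reference base code at line ",
         which(!ref %in% bases)[1L], " in ", path, call. = FALSE)
  }

  ## designate the dark allele
  if (!is.null(founder)) {
    fkey <- snp_key(founder$chrom, founder$pos)
    idx <- match(snp_key(chrom, pos), fkey)
    if (anyNA(idx)) {
      stop(sum(is.na(idx)), " sync sites absent from the founder map",
           call. = FALSE)
    }
    dark <- founder$dark_allele[idx]
  } else {
    tot <- Reduce(`+`, lapply(counts, function(m) m[, 1:4, drop = FALSE]))
    tot[cbind(seq_along(ref), match(ref, bases))] <- -1L  # mask reference
    best <- max.col(tot, ties.method = "first")
    runner <- max.col(replace(tot, cbind(seq_along(ref), best), -1L),
                      ties.method = "first")
    amb <- tot[cbind(seq_along(ref), best)] ==
      tot[cbind(seq_along(ref), runner)] &
      tot[cbind(seq_along(ref), best)] > 0L
    if (any(amb)) {
      stop("ambiguous dark-allele designation (tied counts) at line ",
           which(amb)[1L], "; supply a founder map", call. = FALSE)
    }
    dark <- bases[best]
  }
  if (any(dark == ref)) {
    stop("dark allele equals reference at line ", which(dark == ref)[1L],
         call. = FALSE)
  }

  ## biallelic check: any third allele above multiallelic_frac drops the site
  iref <- match(ref, bases)
  idark <- match(dark, bases)
  drop <- rep(FALSE, length(ref))
  for (p in seq_len(npop)) {
    m <- counts[[p]]
    third <- rowSums(m) - m[cbind(seq_along(ref), iref)] -
      m[cbind(seq_along(ref), idark)]
    depth <- pmax(rowSums(m), 1L)
    drop <- drop | (third / depth > multiallelic_frac)
  }
  if (any(drop)) {
    message("read_sync: dropped ", sum(drop),
            " site(s) with >2 segregating alleles")
  }
  keep <- !drop
  keys <- data.frame(chrom = chrom[keep], pos = pos[keep],
                     ref = ref[keep], dark = dark[keep],
                     stringsAsFactors = FALSE)
  lst <- stats::setNames(lapply(seq_len(npop), function(p) {
    m <- counts[[p]][keep, , drop = FALSE]
    list(dark = m[cbind(seq_len(nrow(m)), idark[keep])],
         other = m[cbind(seq_len(nrow(m)), iref[keep])])
  }), labels)
  count_table(keys, lst)
}

#' @rdname read_sync
#' @param x A `count_table`.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  bases <- c("A", "T", "C", "G")
  n <- nrow(x)
  iref <- match(x$ref, bases)
  idark <- match(x$dark, bases)
  cols <- vapply(populations(x), function(lab) {
    m <- matrix(0L, nrow = n, ncol = 6L)
    cc <- pop_counts(x, lab)
    m[cbind(seq_len(n), idark)] <- cc[, "dark"]
    m[cbind(seq_len(n), iref)] <- cc[, "other"]
    paste(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L], m[, 6L], sep = ":")
  }, character(n))
  cols <- matrix(cols, nrow = n)
  lines <- do.call(paste, c(list(x$chrom, x$pos, x$ref),
                            lapply(seq_len(ncol(cols)), function(j) cols[, j]),
                            list(sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the simplified biallelic TSV count format
#'
#' A headered TSV with columns `chrom`, `pos`, `ref`, `dark` and, per
#' population, `<label>_dark` and `<label>_other`.  Unlike sync this format
#' preserves population labels and the dark-allele designation.
#'
#' @param path File path.
#' @param x A `count_table`.
#' @return `read_counts_tsv()` returns a [count_table()];
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  dark_cols <- grep("_dark$", names(df), value = TRUE)
  labels <- sub("_dark$", "", dark_cols)
  miss <- setdiff(paste0(labels, "_other"), names(df))
  if (length(miss) > 0L) {
    stop("missing columns in count TSV: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keys <- df[, c("chrom", "pos", "ref", "dark")]
  counts <- stats::setNames(lapply(labels, function(lab) {
    list(dark = df[[paste0(lab, "_dark")]],
         other = df[[paste0(lab, "_other")]])
  }), labels)
  count_table(keys, counts)
}

#' Write per-SNP truth tables for simulated experiments
#'
#' @param founder A founder map.
#' @param states Optional list of `population_state`s whose true pool
#'   frequencies are added as columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(founder, states = NULL, path) {
  out <- as.data.frame(founder)
  for (st in states %||% list()) {
    lab <- pop_label(st$generation, st$condition, st$replicate_id)
    out[[paste0("true_", lab)]] <- dark_freq(st)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
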