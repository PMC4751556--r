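#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## With seed = NULL the current stream is used and left advanced, so callers
## can compose several stochastic steps under one outer seed.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Population label helpers
#'
#' Populations are labelled `g{generation}_{condition}{replicate}`
#' (for example `g49_DD2`); the generation-0 base population, which exists
#' before the split into conditions, is labelled `g0_base1`.
#'
#' @param generation Integer generation number.
#' @param condition Character condition code (`"LD"`, `"DD"`, or `"base"`).
#' @param replicate Integer replicate id.
#' @return `pop_label()` returns a character vector of labels;
#'   `parse_pop_label()` returns a data frame with columns `generation`,
#'   `condition` and `replicate`.
#' @examples
#' pop_label(49, "DD", 2)
#' parse_pop_label("g22_LD3")
#' @export
pop_label <- function(generation, condition, replicate) {
  sprintf("g%d_%s%d", as.integer(generation), as.character(condition),
          as.integer(replicate))
}

#' @rdname pop_label
#' @param label Character vector of population labels.
#' @export
parse_pop_label <- function(label) {
  m <- regmatches(label, regexec("^g([0-9]+)_([A-Za-z]+)([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed population label(s): ",
         paste(label[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    generation = vapply(m, function(x) as.integer(x[2L]), 1L),
    condition  = vapply(m, function(x) x[3L], ""),
    replicate  = vapply(m, function(x) as.integer(x[4L]), 1L),
    stringsAsFactors = FALSE
  )
}

## shared key for a SNP row
snp_key <- function(chrom, pos) paste0(chrom, ":", pos)
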