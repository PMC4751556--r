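#' Forward-simulate a two-founder mixed population
#'
#' Diploid Wright-Fisher simulation with per-locus viability selection,
#' random mating, and crossover recombination.  Generation 0 consists
#' entirely of F1 hybrids: every individual carries one complete dark-founder
#' haplotype and one complete reference-founder haplotype, so every SNP
#' starts at frequency 0.5.  Each generation, parents are sampled with
#' probability proportional to fitness (multiplicative across loci; genotype
#' fitness 1, 1 + h s, 1 + s for 0/1/2 copies of the dark allele, with
#' s = `s_LD` or `s_DD` from the founder map according to `condition`), and
#' each offspring receives one recombined gamete from its "maternal" parent
#' and, by default, one non-recombined gamete from its "paternal" parent
#' (male meiosis in *Drosophila* is achiasmatic).  Crossover counts per
#' chromosome are Poisson with mean `recomb_cM_per_Mb` x length(Mb) / 100;
#' chromosomes assort independently.  The census size is held constant.
#'
#' @param founder A [make_founder_map()] result.
#' @param condition `"LD"` or `"DD"`; selects which selection coefficient
#'   column of the founder map applies.
#' @param n_individuals Constant census size N (>= 2).
#' @param generations Integer vector of generations to record (0 = the F1
#'   base population).
#' @param n_replicates Number of independent replicate populations.
#' @param recomb_cM_per_Mb Female recombination rate in cM/Mb.
#' @param female_recomb_only If `TRUE` (default) only the maternal gamete
#'   recombines.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output.
#' @return A list of `population_state` objects, one per recorded
#'   generation and replicate, each with elements `generation`, `condition`,
#'   `replicate_id` and `haplotypes` (integer matrix, SNPs x 2N, 1 = dark
#'   founder origin) plus the founder map as attribute `founder`.
#' @examples
#' fm <- make_founder_map(50, c(chr1 = 1e6), seed = 1)
#' st <- simulate_generations(fm, "DD", n_individuals = 40,
#'                            generations = c(0, 5), seed = 1)
#' sapply(st, function(s) mean(dark_freq(s)))
#' @export
simulate_generations <- function(founder, condition = c("LD", "DD"),
                                 n_individuals = 1000L,
                                 generations = c(0L, 22L, 49L),
                                 n_replicates = 1L,
                                 recomb_cM_per_Mb = 2,
                                 female_recomb_only = TRUE,
                                 seed = NULL) {
  condition <- match.arg(condition)
  validate_founder_map(founder)
  stopifnot(n_individuals >= 2, n_replicates >= 1, recomb_cM_per_Mb >= 0)
  generations <- sort(unique(as.integer(generations)))
  stopifnot(all(generations >= 0))

  s <- if (condition == "LD") founder$s_LD else founder$s_DD
  h <- founder$h
  layout <- attr(founder, "chrom_layout")
  chroms <- unique(founder$chrom)
  blocks <- lapply(chroms, function(ch) {
    rows <- which(founder$chrom == ch)
    len <- if (!is.null(layout) && ch %in% names(layout)) {
      as.numeric(layout[[ch]])
    } else {
      max(founder$pos[rows]) * 1.05
    }
    list(rows = rows, pos = founder$pos[rows], len = len,
         lambda = recomb_cM_per_Mb * (len / 1e6) / 100)
  })

  local_seed(seed, {
    out <- list()
    for (rep_id in seq_len(n_replicates)) {
      states <- wf_run(founder, s, h, blocks, n_individuals, generations,
                       female_recomb_only, condition, rep_id)
      out <- c(out, states)
    }
    out
  })
}

## one replicate; returns list of recorded population_state
wf_run <- function(founder, s, h, blocks, N, generations,
                   female_recomb_only, condition, rep_id) {
  n <- nrow(founder)
  odd <- seq(1L, 2L * N, by = 2L)
  even <- odd + 1L
  H <- matrix(0L, nrow = n, ncol = 2L * N)
  H[, odd] <- 1L   # F1 hybrids: one full dark haplotype per individual

  sel <- which(s != 0)
  wtab <- cbind(1, pmax(0, 1 + h[sel] * s[sel]), pmax(0, 1 + s[sel]))

  states <- list()
  record <- function(gen, Hm) {
    st <- list(generation = gen, condition = condition,
               replicate_id = rep_id, haplotypes = Hm)
    attr(st, "founder") <- founder
    class(st) <- "population_state"
    st
  }
  if (0L %in% generations) states[[length(states) + 1L]] <- record(0L, H)
  if (length(generations) == 0L || max(generations) == 0L) return(states)

  for (t in seq_len(max(generations))) {
    w <- if (length(sel) == 0L) {
      rep(1, N)
    } else {
      G <- H[sel, odd, drop = FALSE] + H[sel, even, drop = FALSE]
      fit <- matrix(wtab[cbind(rep(seq_along(sel), N), as.vector(G) + 1L)],
                    nrow = length(sel))
      exp(colSums(log(fit)))
    }
    if (!any(w > 0)) {
      stop("population extinct (all fitness zero) at generation ", t,
           " in replicate ", rep_id, call. = FALSE)
    }
    mothers <- sample.int(N, N, replace = TRUE, prob = w)
    fathers <- sample.int(N, N, replace = TRUE, prob = w)
    clash <- which(fathers == mothers)
    while (length(clash) > 0L) {
      fathers[clash] <- sample.int(N, length(clash), replace = TRUE, prob = w)
      clash <- clash[fathers[clash] == mothers[clash]]
    }
    M <- make_gametes(H, mothers, blocks, recomb = TRUE)
    P <- make_gametes(H, fathers, blocks, recomb = !female_recomb_only)
    H <- matrix(0L, nrow = n, ncol = 2L * N)
    H[, odd] <- M
    H[, even] <- P
    if (t %in% generations) states[[length(states) + 1L]] <- record(t, H)
  }
  states
}

## one gamete per parent; vectorised except for gametes with >=1 crossover
make_gametes <- function(H, parents, blocks, recomb) {
  np <- length(parents)
  G <- matrix(0L, nrow = nrow(H), ncol = np)
  c1 <- 2L * parents - 1L
  for (b in blocks) {
    choice <- sample(c(0L, 1L), np, replace = TRUE)
    G[b$rows, ] <- H[b$rows, c1 + choice, drop = FALSE]
    if (recomb && b$lambda > 0) {
      nx <- stats::rpois(np, b$lambda)
      for (g in which(nx > 0L)) {
        br <- sort(stats::runif(nx[g], 0, b$len))
        sw <- (findInterval(b$pos, br) %% 2L) == 1L
        if (any(sw)) {
          G[b$rows[sw], g] <- H[b$rows[sw], c1[g] + (1L - choice[g])]
        }
      }
    }
  }
  G
}

#' Dark-allele counts and frequencies of a simulated population
#'
#' @param state A `population_state` from [simulate_generations()].
#' @return `dark_allele_counts()`: integer vector of dark-allele copies per
#'   SNP; `dark_freq()`: the same divided by 2N.
#' @export
dark_allele_counts <- function(state) {
  stopifnot(inherits(state, "population_state"))
  as.integer(rowSums(state$haplotypes))
}

#' @rdname dark_allele_counts
#' @export
dark_freq <- function(state) {
  dark_allele_counts(state) / ncol(state$haplotypes)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> gen %d, %s, replicate %d: %d SNPs x %d haplotypes\n",
              x$generation, x$condition, x$replicate_id,
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}
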