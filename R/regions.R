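#' Cluster significant SNPs into candidate regions
#'
#' Single-linkage clustering along the genome: SNPs on the same chromosome
#' whose neighbours lie within `gap_bp` share a region; region bounds are
#' the min/max member positions (1-based inclusive).  The result is
#' independent of the input order.
#'
#' @param snps Data frame with columns `chrom` and `pos` (e.g. the
#'   significant rows of a [classify_significant()] result).
#' @param gap_bp Maximum linking distance in bp (default 100 kb).
#' @return Data frame with columns `chrom`, `start`, `end`, `n_snps`,
#'   `total_bases` and `snp_ids` (semicolon-joined `chrom:pos` keys).
#' @export
cluster_regions <- function(snps, gap_bp = 100000L) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)), gap_bp >= 0)
  if (nrow(snps) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      total_bases = integer(), snp_ids = character(),
                      stringsAsFactors = FALSE))
  }
  snps <- unique(snps[, c("chrom", "pos")])
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  new_chrom <- c(TRUE, snps$chrom[-1L] != snps$chrom[-nrow(snps)])
  gap <- c(0L, diff(snps$pos))
  region_id <- cumsum(new_chrom | gap > gap_bp)
  out <- do.call(rbind, lapply(split(snps, region_id), function(g) {
    data.frame(chrom = g$chrom[1L], start = min(g$pos), end = max(g$pos),
               n_snps = nrow(g),
               total_bases = max(g$pos) - min(g$pos) + 1L,
               snp_ids = paste(snp_key(g$chrom, g$pos), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Overlap of candidate regions with runs of homozygosity
#'
#' Intervals are 1-based inclusive; any shared base (including a single
#' boundary base) counts as overlap.  When `genome_bp` is supplied, the
#' ROH fraction of the genome is reported as the expected per-region
#' overlap probability under a random placement null.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param roh Data frame with `chrom`, `start`, `end` of ROH intervals.
#' @param genome_bp Optional total genome length in bp.
#' @return List with `n_overlapping`, `overlaps` (logical per region),
#'   `observed_fraction`, and `expected_fraction` (NA without `genome_bp`).
#' @export
roh_overlap <- function(regions, roh, genome_bp = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end") %in% names(roh)))
  hit <- vapply(seq_len(nrow(regions)), function(i) {
    same <- roh$chrom == regions$chrom[i]
    any(same & roh$start <= regions$end[i] & roh$end >= regions$start[i])
  }, logical(1L))
  expected <- if (is.null(genome_bp)) {
    NA_real_
  } else {
    sum(roh$end - roh$start + 1) / genome_bp
  }
  list(n_overlapping = sum(hit), overlaps = hit,
       observed_fraction = if (nrow(regions) > 0) mean(hit) else NA_real_,
       expected_fraction = expected)
}

## coerce a chrom/start/end data frame (or GRanges) to GRanges
as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end))
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- x[[nm]]
  gr
}

#' Genes overlapping candidate regions and carrying variants
#'
#' A gene is reported for a region when its span intersects the region and
#' at least one founder variant (SNP or InDel) falls within the gene span.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [cluster_regions()] or peak credible intervals.
#' @param genes Gene annotation: data frame with `chrom`, `start`, `end`,
#'   `gene_id`, or a `GRanges` with a `gene_id` metadata column.
#' @param variants Data frame with `chrom`, `pos` of founder variants.
#' @return `regions` with added columns `genes` (comma-joined gene ids) and
#'   `n_genes`.
#' @export
overlap_annotations <- function(regions, genes, variants) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  ggr <- as_granges(genes)
  if (!"gene_id" %in% names(S4Vectors::mcols(ggr))) {
    stop("gene annotation needs a gene_id column", call. = FALSE)
  }
  vgr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  with_var <- GenomicRanges::countOverlaps(ggr, vgr) >= 1L
  rgr <- as_granges(regions)
  hits <- GenomicRanges::findOverlaps(rgr, ggr[with_var])
  ids <- S4Vectors::mcols(ggr[with_var])$gene_id
  lists <- split(ids[S4Vectors::subjectHits(hits)],
                 factor(S4Vectors::queryHits(hits),
                        levels = seq_len(nrow(regions))))
  regions$genes <- vapply(lists, function(g) {
    paste(sort(unique(g)), collapse = ",")
  }, "")
  regions$n_genes <- vapply(lists, function(g) length(unique(g)), 1L)
  regions
}

#' Read interval annotations
#'
#' Thin wrappers over [rtracklayer::import()]: BED input (0-based
#' half-open) is converted to 1-based inclusive coordinates; GFF3 input is
#' filtered to `type == "gene"` rows.
#'
#' @param path File path.
#' @return Data frame with `chrom`, `start`, `end` (plus `gene_id` for
#'   GFF3 genes and named BED features).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$gene_id <- nm
  out
}

#' @rdname read_bed
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  id <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$Name
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = as.character(id),
             stringsAsFactors = FALSE)
}

#' Write regions as a BED file (0-based half-open)
#'
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  rtracklayer::export(as_granges(regions), path, format = "BED")
  invisible(path)
}
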