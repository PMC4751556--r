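test_that("sync lines parse with the designated dark allele", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines("2L\t5000\tA\t10:0:0:5:0:0", path)
  founder <- data.frame(chrom = "2L", pos = 5000, ref_allele = "A",
                        dark_allele = "G", stringsAsFactors = FALSE)
  ct <- read_sync(path, labels = "p1", founder = founder)
  cc <- poolscan:::pop_counts(ct, "p1")
  expect_equal(unname(cc[1, "dark"]), 5)
  expect_equal(unname(cc[1, "other"]), 10)
})

test_that("sync write/read round-trips a random table exactly", {
  fm <- make_founder_map(100, c(chr1 = 1e6, chr2 = 5e5), seed = 10)
  set.seed(10)
  keys <- data.frame(chrom = fm$chrom, pos = fm$pos, ref = fm$ref_allele,
                     dark = fm$dark_allele, stringsAsFactors = FALSE)
  ct <- count_table(keys, list(
    a = list(dark = rpois(100, 40), other = rpois(100, 50)),
    b = list(dark = rpois(100, 30), other = rpois(100, 60))))
  f1 <- withr::local_tempfile(fileext = ".sync")
  f2 <- withr::local_tempfile(fileext = ".sync")
  write_sync(ct, f1)
  back <- read_sync(f1, labels = c("a", "b"),
                    founder = data.frame(chrom = fm$chrom, pos = fm$pos,
                                         ref_allele = fm$ref_allele,
                                         dark_allele = fm$dark_allele))
  expect_equal(as.data.frame(back), as.data.frame(ct))
  write_sync(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed sync input fails with the offending line", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("2L\t100\tA\t1:0:0:0:0:0",
               "2L\t200\tA\t1:0:0:0:0"), path)
  expect_error(read_sync(path), "line 2")
  writeLines(c("2L\t100\tA\t1:0:0:0:0:0",
               "2L\t200\tA"), path)
  expect_error(read_sync(path), "ragged")
})

test_that("ambiguous dark-allele inference is refused, unambiguous succeeds", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines("2L\t100\tA\t10:3:3:0:0:0", path)   # T and C tie
  expect_error(read_sync(path), "ambiguous")
  writeLines("2L\t100\tA\t10:6:0:0:0:0", path)
  ct <- read_sync(path)
  expect_equal(ct$dark, "T")
})

test_that("sites with a third segregating allele are dropped with a message", {
  path <- withr::local_tempfile(fileext = ".sync")
  writeLines(c("2L\t100\tA\t10:0:0:10:0:0",
               "2L\t200\tA\t10:5:0:10:0:0"), path)
  founder <- data.frame(chrom = "2L", pos = c(100, 200),
                        ref_allele = "A", dark_allele = "G")
  expect_message(ct <- read_sync(path, founder = founder), "dropped 1")
  expect_equal(nrow(ct), 1)
})

test_that("biallelic TSV round-trips with labels preserved", {
  fm <- make_founder_map(20, c(chr1 = 1e5), seed = 11)
  keys <- data.frame(chrom = fm$chrom, pos = fm$pos, ref = fm$ref_allele,
                     dark = fm$dark_allele)
  ct <- count_table(keys, list(g0_base1 = list(dark = 1:20, other = 20:1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(ct, path)
  back <- read_counts_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(ct))
  expect_equal(populations(back), "g0_base1")
})

test_that("frequencies are counts over depth with low-coverage SNPs missing", {
  ct <- make_ct("2L", c(100, 200, 300), dark = c(90, 2, 179),
                other = c(90, 2, 0))
  f <- estimate_frequencies(ct, min_coverage = 5)
  expect_equal(f[["pop1"]], c(0.5, NA, 1))
})

test_that("the founder filter keeps the closed interval [0.4, 0.6]", {
  ct <- make_ct("2L", c(100, 200, 300, 400),
                dark = c(39, 40, 50, 61), other = c(61, 60, 50, 39))
  f <- estimate_frequencies(ct)
  keys <- select_founder_snps(f)
  expect_setequal(keys, c("2L:200", "2L:300"))
  ## idempotence
  keep1 <- filter_snps(f, keys)
  keys2 <- select_founder_snps(keep1)
  expect_setequal(keys2, keys)
  ## empty input, boundary config
  empty <- filter_snps(f, character(0))
  expect_length(select_founder_snps(empty), 0)
  expect_error(select_founder_snps(f, lo = 0.7, hi = 0.3), "lo")
})

test_that("founder-SNP retention at depth 179 matches the binomial prediction", {
  fm <- make_founder_map(2000, c(chr1 = 1e7), seed = 12)
  st <- fake_state(fm, cbind(matrix(1L, 2000, 50), matrix(0L, 2000, 50)))
  ct <- sample_pooled_reads(st, mean_depth = 179, depth_model = "fixed",
                            error_rate = 0, label = "g0", seed = 12)
  f <- estimate_frequencies(ct)
  kept <- sum(!is.na(f[["g0"]]) & f[["g0"]] >= 0.4 & f[["g0"]] <= 0.6)
  predicted <- pbinom(107, 179, 0.5) - pbinom(71, 179, 0.5)
  mc_se <- sqrt(predicted * (1 - predicted) / 2000)
  expect_lt(abs(kept / 2000 - predicted), 4 * mc_se)
})
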