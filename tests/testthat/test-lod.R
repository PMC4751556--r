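test_that("equal condition frequencies give LOD 0 and no peaks", {
  x <- make_ct("2L", 1:20 * 1000, dark = rep(30L, 20), other = rep(70L, 20),
               label = "LD")
  y <- make_ct("2L", 1:20 * 1000, dark = rep(30L, 20), other = rep(70L, 20),
               label = "DD")
  tr <- lod_scan(x, y)
  expect_true(all(abs(tr$lod) < 1e-10))
  expect_equal(nrow(call_peaks(tr)), 0)
})

test_that("the LOD closed form and brute-force likelihood oracle agree", {
  ## fully opposed conditions: LOD = 200 log10(2)
  x <- make_ct("2L", 5000, dark = 0L, other = 100L, label = "LD")
  y <- make_ct("2L", 5000, dark = 100L, other = 0L, label = "DD")
  tr <- lod_scan(x, y, smooth_bw_bins = 0, drop_fixed = FALSE)
  expect_equal(max(tr$lod), 200 * log10(2), tolerance = 1e-9)

  ## grid-search oracle on small tables
  set.seed(6)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(poolscan:::lod_one(k1, n1, k2, n2),
                 lod_grid_oracle(k1, n1, k2, n2), tolerance = 1e-3)
  }
})

test_that("LOD grows with evidence and caps at the pooled chromosome count", {
  lods <- vapply(1:5, function(mult) {
    poolscan:::lod_one(10 * mult, 50 * mult, 30 * mult, 50 * mult)
  }, numeric(1))
  expect_true(all(diff(lods) > 0))

  ## above 2 * pool_n the counts are rescaled, not trusted
  x <- make_ct("2L", 5000, dark = 4000L, other = 6000L, label = "LD")
  y <- make_ct("2L", 5000, dark = 6000L, other = 4000L, label = "DD")
  tr_cap <- lod_scan(x, y, pool_n = 50, smooth_bw_bins = 0)
  expect_equal(max(tr_cap$lod), poolscan:::lod_one(40, 100, 60, 100),
               tolerance = 1e-9)
})

test_that("peak calling suppresses lesser maxima within the separation distance", {
  mk_track <- function(pos, lod) {
    tr <- data.frame(chrom = "2L", start = pos - 500, mid = pos,
                     lod = lod, lod_raw = lod)
    attr(tr, "bin_bp") <- 1000L
    class(tr) <- c("lod_track", "data.frame")
    tr
  }
  pos <- seq(1000, 2e6, by = 1000)
  lod <- rep(0, length(pos))
  lod[pos == 500000] <- 100
  lod[pos == 1000000] <- 90
  pk <- call_peaks(mk_track(pos, lod), threshold = 75, min_sep_bp = 1e6)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_pos, 500000)
  expect_equal(pk$peak_lod, 100)

  ## beyond the separation both survive; below threshold none do
  lod2 <- rep(0, length(pos))
  lod2[pos == 400000] <- 100
  lod2[pos == 1600000] <- 90
  expect_equal(nrow(call_peaks(mk_track(pos, lod2))), 2)
  expect_equal(nrow(call_peaks(mk_track(pos, lod2 / 2))), 0)

  ## reproducibility
  expect_identical(call_peaks(mk_track(pos, lod2)),
                   call_peaks(mk_track(pos, lod2)))
})

test_that("credible intervals behave at the degenerate limits", {
  ## all posterior mass in one bin: span equals the bin width
  x <- make_ct("2L", c(500200, 500800), dark = c(5L, 5L), other = c(95L, 95L),
               label = "LD")
  y <- make_ct("2L", c(500200, 500800), dark = c(95L, 95L), other = c(5L, 5L),
               label = "DD")
  ci <- credible_interval(x, y, "2L", 500500, window_bp = 1e6,
                          smooth_bw_bins = 0)
  expect_equal(ci$span_kb, 1)
  expect_equal(ci$ci_end - ci$ci_start, 1000)

  ## uniform posterior over 1000 bins at mass 0.9 covers 900 bins
  pos <- seq(500, 999500, by = 1000)
  u1 <- make_ct("2L", pos, dark = rep(20L, 1000), other = rep(20L, 1000),
                label = "LD")
  u2 <- make_ct("2L", pos, dark = rep(30L, 1000), other = rep(10L, 1000),
                label = "DD")
  ci_u <- credible_interval(u1, u2, "2L", 500000, window_bp = 1e6,
                            mass = 0.9, smooth_bw_bins = 0)
  expect_equal(ci_u$span_kb, 900)

  ## symmetric profile: interval symmetric about the peak (within a bin)
  contrast <- round(seq(10, 50, length.out = 6))
  pos_s <- seq(495000, 505000, by = 1000) + 500
  tri <- c(contrast, rev(contrast)[-1])
  s1 <- make_ct("2L", pos_s, dark = rep(50L, 11), other = rep(50L, 11),
                label = "LD")
  s2 <- make_ct("2L", pos_s, dark = 50L + tri, other = 50L - tri,
                label = "DD")
  ci_s <- credible_interval(s1, s2, "2L", 500500, window_bp = 2e4,
                            smooth_bw_bins = 0)
  left <- 500500 - ci_s$ci_start
  right <- ci_s$ci_end - 500500
  expect_lt(abs(left - right), 2000)
})

test_that("peak intervals inherit the majority type of their SNPs", {
  peaks <- data.frame(chrom = c("2L", "3R"), peak_pos = c(5000, 5000),
                      ci_start = c(1000, 1000), ci_end = c(9000, 9000))
  scan <- data.frame(chrom = c("2L", "2L", "2L", "3R"),
                     pos = c(2000, 3000, 4000, 20000),
                     type_label = c("type2", "type2", "type1", "type3"))
  out <- peak_selection_type(peaks, scan)
  expect_equal(out$selection_type, c("type2", "none"))
})
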