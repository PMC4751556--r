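test_that("merging replicates sums counts and conserves depth", {
  a <- make_ct("2L", c(100, 200), dark = c(10, 1), other = c(5, 2), label = "r1")
  b <- make_ct("2L", c(100, 200), dark = c(20, 3), other = c(15, 4), label = "r2")
  m <- merge_replicates(list(a, b))
  cc <- poolscan:::pop_counts(m, "merged")
  expect_equal(unname(cc[1, ]), c(30, 20))
  expect_equal(unname(cc[2, ]), c(4, 6))

  ## single replicate is the identity
  one <- merge_replicates(list(a))
  expect_equal(unname(poolscan:::pop_counts(one, "merged")),
               unname(poolscan:::pop_counts(a, "r1")))

  ## depth conservation over random replicates
  set.seed(1)
  reps <- lapply(1:3, function(i) {
    make_ct("3R", 1:50 * 1000, dark = rbinom(50, 150, 0.5),
            other = 0L, label = paste0("r", i))
  })
  reps <- lapply(reps, function(x) {
    x[[paste0(populations(x), "_other")]] <-
      150L - x[[paste0(populations(x), "_dark")]]
    x
  })
  m3 <- merge_replicates(reps)
  cc <- poolscan:::pop_counts(m3, "merged")
  expect_true(all(rowSums(cc) == 450))

  ## mismatched keys are refused with offenders named
  c2 <- make_ct("2L", c(100, 999), dark = c(1, 1), other = c(1, 1))
  expect_error(merge_replicates(list(a, c2)), "2L:999")
})

test_that("fisher scan reproduces exact hypergeometric p-values", {
  ## identical tables: p = 1 everywhere
  x <- make_ct("2L", 1:5 * 100, dark = c(5, 10, 0, 20, 7),
               other = c(5, 0, 10, 5, 7), label = "LD")
  y <- make_ct("2L", 1:5 * 100, dark = c(5, 10, 0, 20, 7),
               other = c(5, 0, 10, 5, 7), label = "DD")
  sc <- fisher_scan(x, y)
  expect_equal(sc$p_value, rep(1, 5), tolerance = 1e-12)

  ## worked example: (2,8) vs (8,2) has p = 4252/184756
  expect_equal(fisher_p(2, 10, 8, 10), 4252 / 184756, tolerance = 1e-12)
  expect_equal(fisher_p(2, 10, 8, 10), fisher_enum_oracle(2, 10, 8, 10),
               tolerance = 1e-12)

  ## agreement with stats::fisher.test on random tables
  set.seed(2)
  for (i in 1:25) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    k1 <- rbinom(1, n1, runif(1)); k2 <- rbinom(1, n2, runif(1))
    ft <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))$p.value
    expect_equal(fisher_p(k1, n1, k2, n2), ft, tolerance = 1e-9)
  }

  ## condition symmetry
  sc2 <- fisher_scan(y, x)
  expect_equal(sc2$p_value, sc$p_value)
})

test_that("excess coverage is down-sampled reproducibly and empty SNPs skipped", {
  x <- make_ct("2L", c(100, 200), dark = c(6000, 0), other = c(6000, 0),
               label = "LD")
  y <- make_ct("2L", c(100, 200), dark = c(5000, 0), other = c(7000, 0),
               label = "DD")
  expect_message(s1 <- fisher_scan(x, y, max_coverage = 9000, seed = 5),
                 "skipped 1")
  expect_true(all(s1$n_LD[1] == 9000, s1$n_DD[1] == 9000))
  expect_true(is.na(s1$p_value[2]))
  s2 <- suppressMessages(fisher_scan(x, y, max_coverage = 9000, seed = 5))
  expect_identical(s1, s2)
})

test_that("classification applies Bonferroni, top-rank and DD-frequency bins", {
  n <- 60   # top-5% tier holds ceiling(0.05 * 60) = 3 SNPs
  pos <- 1:n * 1000
  scan <- data.frame(chrom = "2L", pos = pos,
                     p_value = c(1e-30, 1e-20, 1e-10, rep(0.5, n - 3)))
  mk_freq <- function(vals, labs) {
    keys <- data.frame(chrom = "2L", pos = pos, ref = "A", dark = "G",
                       stringsAsFactors = FALSE)
    ct <- count_table(keys, stats::setNames(lapply(seq_along(labs), function(i)
      list(dark = round(vals[, i] * 100), other = 100 - round(vals[, i] * 100))),
      labs))
    estimate_frequencies(ct)
  }
  fDD <- matrix(0.5, n, 2)
  fDD[1, ] <- 0.90   # -> type1
  fDD[2, ] <- 0.35   # -> type2 (left-closed bin)
  fDD[3, ] <- 0.80   # -> type1 (left-closed bin)
  fLD <- matrix(0.5, n, 2)
  fLD[1:3, ] <- 0.10
  freq_DD <- mk_freq(fDD, c("g49_DD1", "g49_DD2"))
  freq_LD <- mk_freq(fLD, c("g49_LD1", "g49_LD2"))
  res <- classify_significant(scan, freq_LD, freq_DD)
  expect_equal(res$type_label[1:3], c("type1", "type2", "type1"))
  expect_equal(sum(res$top_flag), ceiling(0.05 * n))
  expect_equal(res$p_bonferroni, pmin(1, res$p_value * n))

  ## a SNP with higher LD frequency is never typed, whatever its p
  fLD2 <- fLD; fLD2[1, ] <- 0.99
  res2 <- classify_significant(scan, mk_freq(fLD2, c("g49_LD1", "g49_LD2")),
                               freq_DD)
  expect_equal(res2$type_label[1], "none")
  expect_equal(res2$direction[1], "higher_LD")

  ## the three types partition the top & higher-DD set
  expect_equal(sum(res$type_label != "none"),
               sum(res$top_flag & res$direction == "higher_DD" &
                     !is.na(res$mean_freq_DD)))
})

test_that("direction bias test is a 1-df chi-square against 50:50", {
  even <- direction_bias_test(100, 100)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  big <- direction_bias_test(6015, 1129)
  expect_equal(big$statistic, 2 * 2443^2 / 3572, tolerance = 1e-10)
  expect_lt(big$p_value, 1e-300)

  expect_equal(direction_bias_test(0, 10)$statistic, 10)
  expect_error(direction_bias_test(0, 0), "zero")
})
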