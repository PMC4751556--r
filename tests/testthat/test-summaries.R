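test_that("flat frequency profiles give flat mean trajectories", {
  pos <- 1:10 * 100
  keys <- data.frame(chrom = "2L", pos = pos, ref = "A", dark = "G")
  labs <- c("g0_base1", "g22_LD1", "g22_DD1", "g49_LD1", "g49_DD1")
  ct <- count_table(keys, stats::setNames(lapply(labs, function(l)
    list(dark = rep(50L, 10), other = rep(50L, 10))), labs))
  freqs <- estimate_frequencies(ct)
  types <- data.frame(chrom = "2L", pos = pos,
                      type_label = rep(c("type1", "none"), 5))
  out <- trajectory_summary(freqs, types)
  expect_true(all(out$summary$mean_freq == 0.5))
  expect_setequal(out$summary$condition, c("LD", "DD"))
  expect_setequal(out$summary$generation, c(0, 22, 49))

  ## no typed SNPs: empty summary, no error
  none <- trajectory_summary(freqs,
                             data.frame(chrom = "2L", pos = pos,
                                        type_label = "none"))
  expect_equal(nrow(none$summary), 0)
})

test_that("antagonistically selected loci rise in DD and fall in LD", {
  sim <- tiny_planted_sim()
  freqs <- estimate_frequencies(sim$counts)
  planted <- sim$founder[sim$founder$planted_type == "type2",
                         c("chrom", "pos")]
  planted$type_label <- "type2"
  out <- trajectory_summary(freqs, planted)
  s <- out$summary
  dd <- s[s$condition == "DD", ]
  ld <- s[s$condition == "LD", ]
  expect_true(all(diff(dd$mean_freq[order(dd$generation)]) > 0))
  expect_true(all(diff(ld$mean_freq[order(ld$generation)]) < 0))
  ## per-locus sign test at the final generation
  tr <- out$trajectories
  last <- tr[tr$generation == 12, ]
  up_dd <- sum(last$freq[last$condition == "DD"] > 0.5)
  dn_ld <- sum(last$freq[last$condition == "LD"] < 0.5)
  expect_gte(up_dd, 15)
  expect_gte(dn_ld, 15)
})

test_that("MDS collapses identical profiles and separates the conditions", {
  sim <- tiny_planted_sim()
  freqs <- estimate_frequencies(sim$counts)
  emb <- mds_embed(freqs)
  expect_equal(nrow(emb$points), length(populations(freqs)))
  expect_gte(emb$stress, 0)

  ## two identical populations land on the same point
  pos <- 1:50 * 100
  keys <- data.frame(chrom = "2L", pos = pos, ref = "A", dark = "G")
  set.seed(3)
  k <- rbinom(50, 100, 0.5)
  k2 <- rbinom(50, 100, 0.3)
  k3 <- rbinom(50, 100, 0.7)
  ct <- count_table(keys, list(
    a = list(dark = k, other = 100 - k),
    b = list(dark = k, other = 100 - k),
    c = list(dark = k2, other = 100 - k2),
    d = list(dark = k3, other = 100 - k3)))
  emb2 <- mds_embed(estimate_frequencies(ct))
  pa <- unlist(emb2$points[emb2$points$population == "a", c("dim1", "dim2")])
  pb <- unlist(emb2$points[emb2$points$population == "b", c("dim1", "dim2")])
  expect_equal(unname(pa), unname(pb))

  ## conditions separate at the final generation (positive silhouette)
  labs <- populations(freqs)
  meta <- parse_pop_label(labs)
  final <- labs[meta$generation == 12]
  pts <- emb$points[match(final, emb$points$population), c("dim1", "dim2")]
  cond <- parse_pop_label(final)$condition
  d <- as.matrix(dist(pts))
  sil <- vapply(seq_along(final), function(i) {
    a <- mean(d[i, cond == cond[i] & seq_along(final) != i])
    b <- mean(d[i, cond != cond[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_error(mds_embed(estimate_frequencies(
    count_table(keys, list(a = list(dark = k, other = 100 - k))))),
    "at least 3")
})

test_that("a perfectly two-dimensional configuration embeds with ~zero stress", {
  set.seed(4)
  coords <- matrix(runif(10), 5, 2)
  keys <- data.frame(chrom = "2L", pos = c(100, 200), ref = "A", dark = "G")
  ct <- count_table(keys, stats::setNames(lapply(1:5, function(i)
    list(dark = round(coords[i, ] * 1000), other = 1000 - round(coords[i, ] * 1000))),
    paste0("p", 1:5)))
  emb <- mds_embed(estimate_frequencies(ct))
  expect_lt(emb$stress, 1)
})

test_that("qq_data pairs sorted observed quantiles with -log10(i/(m+1))", {
  q <- qq_data(c(0.5, 0.25, 0.125))
  expect_equal(q$expected, -log10(c(1, 2, 3) / 4))
  expect_equal(q$observed, -log10(c(0.125, 0.25, 0.5)))

  ## evenly spaced p-values sit exactly on the identity line
  m <- 200
  q2 <- qq_data(seq_len(m) / (m + 1))
  expect_equal(q2$observed, q2$expected)

  expect_message(q3 <- qq_data(c(0, 0.5)), "clamped")
  expect_true(is.finite(q3$observed[1]))
  expect_equal(nrow(qq_data(0.3)), 1)
})
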