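test_that("Shannon entropy of pattern distributions", {
  expect_equal(shannon_entropy(uniform_distribution(3)), log2(13),
               tolerance = 1e-12)
  expect_equal(round(shannon_entropy(uniform_distribution(3)), 3), 3.700)
  expect_equal(round(shannon_entropy(uniform_distribution(4)), 3), 7.637)
  point <- uniform_distribution(3)
  point$probs[] <- 0
  point$probs["38"] <- 1
  expect_equal(shannon_entropy(point), 0)
  # invariance under relabeling of the probability vector
  set.seed(3)
  p <- runif(13); p <- p / sum(p)
  expect_equal(shannon_entropy(p), shannon_entropy(sample(p)),
               tolerance = 1e-12)
})

test_that("normalized entropy maps into [0, 1]", {
  expect_equal(normalized_entropy(uniform_distribution(3)), 1)
  point <- uniform_distribution(4)
  point$probs[] <- 0
  point$probs[1] <- 1
  expect_equal(normalized_entropy(point), 0)
  two <- uniform_distribution(3)
  two$probs[] <- 0
  two$probs[c("6", "12")] <- 0.5
  expect_equal(normalized_entropy(two), 1 / log2(13), tolerance = 1e-12)
  # random censuses stay in [0, 1]
  for (seed in 1:5) {
    net <- random_digraph(15, 0.2, seed = seed)
    h <- normalized_entropy(frequency_distribution(census(net, 3)))
    expect_gte(h, 0); expect_lte(h, 1)
  }
  expect_error(normalized_entropy(structure(list(k = 5, probs = 1),
                                            class = "frequency_distribution")),
               "3- and 4-node")
})

test_that("minimum ranks replicate the printed complexity rankings", {
  ref <- kc_reference()
  expect_identical(min_rank(ref$cc), as.integer(ref$cc_rank))
  expect_identical(min_rank(ref$kc), as.integer(ref$kc_rank))
  expect_identical(min_rank(c(3, 1, 2)), c(3L, 1L, 2L))
  expect_identical(min_rank(c(3, 1, 2), ascending = FALSE), c(1L, 3L, 2L))
  expect_identical(min_rank(rep(7, 4)), rep(1L, 4))
})

test_that("Spearman correlation of the printed complexity ranks is 0.083", {
  ref <- kc_reference()
  srcc <- spearman_rank_correlation(ref$cc_rank, ref$kc_rank)
  expect_equal(round(srcc, 3), 0.083)
  expect_equal(spearman_rank_correlation(1:5, 1:5), 1)
  expect_equal(spearman_rank_correlation(1:5, 5:1), -1)
  expect_equal(spearman_rank_correlation(ref$cc_rank, ref$kc_rank),
               spearman_rank_correlation(ref$kc_rank, ref$cc_rank))
  expect_error(spearman_rank_correlation(rep(1, 4), 1:4), "zero variance")
})

test_that("contingency table splits nodes by module and gene-set status", {
  net <- directed_network(rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  tab <- contingency_table(net, census(net, 3), census(net, 4), c("a", "d"))
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(1L, 1L, 2L, 1L))

  # drivers disjoint from the network: a = b = 0
  tab2 <- contingency_table(net, census(net, 3), census(net, 4),
                            c("TP53", "KRAS"))
  expect_identical(c(tab2$a, tab2$b), c(0L, 0L))

  # every node in the module: b = d = 0
  tri <- directed_network(rbind(c("p", "q"), c("q", "r")))
  tab3 <- contingency_table(tri, census(tri, 3), census(tri, 4), c("p", "q"))
  expect_identical(c(tab3$b, tab3$d), c(0L, 0L))
  expect_identical(tab3$a + tab3$b + tab3$c + tab3$d, 3L)
})

test_that("odds ratio with conditional pseudo-count correction", {
  expect_equal(odds_ratio(list(a = 2, b = 3, c = 4, d = 6)), 1)
  expect_equal(odds_ratio(list(a = 10, b = 5, c = 2, d = 8)), 8)
  expect_equal(odds_ratio(list(a = 0, b = 5, c = 2, d = 8), pseudo = 1),
               (1 * 9) / (6 * 3))
  # enrichment direction: OR > 1 iff the in-module driver fraction is higher
  expect_gt(odds_ratio(list(a = 8, b = 2, c = 10, d = 20)), 1)
  expect_lt(odds_ratio(list(a = 2, b = 8, c = 20, d = 10)), 1)
  expect_error(odds_ratio(list(a = 1, b = 0, c = 0, d = 1), pseudo = 0),
               "undefined")
})
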