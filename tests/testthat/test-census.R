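test_that("connected subsets are enumerated exactly once", {
  path <- directed_network(rbind(c("a", "b"), c("b", "c")))
  expect_identical(connected_subsets(path, 3), list(c("a", "b", "c")))

  star <- directed_network(rbind(c("x", "a"), c("x", "b"), c("x", "c")))
  subs <- connected_subsets(star, 3)
  expect_setequal(vapply(subs, paste, "", collapse = "+"),
                  c("a+b+x", "a+c+x", "b+c+x"))

  two <- directed_network(rbind(c("a", "b"), c("c", "d")))
  expect_length(connected_subsets(two, 3), 0)
  expect_length(connected_subsets(path, 5), 0)  # k > n: empty, no error
})

test_that("census classifies canonical examples", {
  cascade <- directed_network(rbind(c("a", "b"), c("b", "c")))
  expect_identical(census(cascade, 3)$counts, c("12" = 1L))

  ffl <- directed_network(rbind(c("x", "y"), c("x", "z"), c("y", "z")))
  expect_identical(census(ffl, 3)$counts, c("38" = 1L))

  star <- directed_network(rbind(c("x", "a"), c("x", "b"), c("x", "c")))
  expect_identical(census(star, 3)$counts, c("6" = 3L))
})

test_that("occurrence node order realizes the canonical representative", {
  net <- directed_network(rbind(c("x", "y"), c("x", "z"), c("y", "z")))
  cen <- census(net, 3)
  occ <- cen$occurrences[["38"]][[1]]
  m <- adjacency_matrix(net)
  expect_identical(unname(m[occ, occ]), unname(decode_id(38, 3)))
})

test_that("ESU census agrees with brute-force subset classification", {
  set.seed(101)
  for (rep in 1:12) {
    net <- random_digraph(sample(6:12, 1), runif(1, 0.1, 0.35),
                          seed = 1000 + rep)
    for (k in 3:4) {
      cen <- census(net, k, with_nodes = FALSE)
      expect_identical(sorted_counts(cen$counts),
                       oracle_census_counts(net, k))
      expect_identical(cen$n_subsets, sum(cen$counts) + 0L)
    }
  }
})

test_that("census is invariant under node relabeling of the network", {
  net <- random_digraph(10, 0.25, seed = 77)
  perm <- sample(length(net$nodes))
  relabeled <- directed_network(cbind(
    match(net$edges[, 1], net$nodes[perm]),
    match(net$edges[, 2], net$nodes[perm])))
  expect_identical(unname(sorted_counts(census(net, 3)$counts)),
                   unname(sorted_counts(census(relabeled, 3)$counts)))
})

test_that("census agrees with igraph motif counts per isomorphism class", {
  # independent cross-check: igraph's RAND-ESU full census, with its
  # isomorphism classes mapped onto canonical decimal ids
  net <- random_digraph(14, 0.2, seed = 99)
  g <- igraph::graph_from_edgelist(net$edges)
  for (k in 3:4) {
    mot <- igraph::motifs(g, k)
    byid <- integer(0)
    for (cls in which(!is.na(mot) & mot > 0)) {
      rep_g <- igraph::graph_from_isomorphism_class(k, cls - 1L,
                                                    directed = TRUE)
      rep_m <- as.matrix(igraph::as_adjacency_matrix(rep_g))
      storage.mode(rep_m) <- "integer"
      id <- as.character(canonical_id(rep_m))
      byid[id] <- as.integer(sum(byid[id], mot[cls], na.rm = TRUE))
    }
    expect_identical(sorted_counts(byid),
                     sorted_counts(census(net, k, with_nodes = FALSE)$counts))
  }
})

test_that("node coverage fractions", {
  casc <- directed_network(rbind(c("a", "b"), c("b", "c")))
  cov <- node_coverage(census(casc, 3), census(casc, 4), casc)
  expect_equal(cov$k3, 1)
  expect_equal(cov$k4, 0)

  mixed <- directed_network(rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  cov2 <- node_coverage(census(mixed, 3), census(mixed, 4), mixed)
  expect_equal(cov2$k3, 3 / 5)
  expect_equal(cov2$both, 0)
})

test_that("frequency distributions cover the catalog and sum to one", {
  star <- directed_network(rbind(c("x", "a"), c("x", "b"), c("x", "c")))
  d <- frequency_distribution(census(star, 3))
  expect_length(d$probs, 13)
  expect_equal(unname(d$probs["6"]), 1)
  expect_equal(sum(d$probs), 1)

  two <- directed_network(rbind(c("a", "b"), c("b", "c"), c("p", "q"),
                                c("q", "r"), c("p", "r")))
  d2 <- frequency_distribution(census(two, 3))
  expect_equal(unname(d2$probs[c("12", "38")]), c(0.5, 0.5))

  empty <- directed_network(rbind(c("a", "b")))
  expect_error(frequency_distribution(census(empty, 3)), "empty")
})
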