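edge_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("edge lists parse, drop self-loops and collapse duplicates", {
  net <- read_edge_list(edge_file(c("a\tb", "b\tc")))
  expect_identical(net$nodes, c("a", "b", "c"))
  expect_identical(nrow(net$edges), 2L)

  expect_warning(net2 <- read_edge_list(edge_file(c("a\ta", "a\tb"))),
                 "self-loop")
  expect_identical(net2$nodes, c("a", "b"))
  expect_identical(nrow(net2$edges), 1L)
  expect_identical(net2$n_selfloops_dropped, 1L)

  net3 <- read_edge_list(edge_file(c("a\tb", "a\tb")))
  expect_identical(nrow(net3$edges), 1L)
  expect_identical(net3$n_duplicates_collapsed, 1L)

  expect_error(read_edge_list(edge_file(c("# only a comment"))), "empty")
  expect_error(read_edge_list(edge_file(c("a\tb", "lonely"))), "line 2")
})

test_that("edge-list round trip preserves nodes and edges", {
  set.seed(11)
  net <- random_digraph(20, 0.15, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  # isolated nodes are not serialized by an edge list
  expect_identical(back$nodes, sort(unique(c(net$edges))))
  expect_setequal(paste(back$edges[, 1], back$edges[, 2]),
                  paste(net$edges[, 1], net$edges[, 2]))
})

test_that("edge order does not affect census statistics", {
  lines <- c("a\tb", "a\tc", "b\tc", "c\td")
  n1 <- read_edge_list(edge_file(lines))
  n2 <- read_edge_list(edge_file(rev(lines)))
  expect_identical(census(n1, 3)$counts, census(n2, 3)$counts)
})

test_that("gene lists are trimmed, deduplicated and comment-aware", {
  expect_length(read_gene_set(edge_file(c("TP53", "KRAS", "TP53"))), 2)
  expect_identical(read_gene_set(edge_file(" BRCA1 ")), "BRCA1")
  expect_identical(read_gene_set(edge_file(c("# header", "EGFR"))), "EGFR")
  expect_error(read_gene_set(edge_file("# nothing")), "empty")
})

kgml_doc <- function(entries, relations) {
  paste0('<?xml version="1.0"?>\n<pathway name="path:test" org="hsa">\n',
         paste(entries, collapse = "\n"), "\n",
         paste(relations, collapse = "\n"), "\n</pathway>")
}

test_that("minimal KGML: entries become nodes, relations become edges", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(kgml_doc(
    c('<entry id="1" name="hsa:A1 hsa:A2" type="gene"/>',
      '<entry id="2" name="hsa:B" type="gene"/>'),
    c('<relation entry1="1" entry2="2" type="PPrel"/>')), f)
  net <- read_kgml(f)
  expect_identical(net$nodes, c("hsa:A1", "hsa:B"))
  expect_identical(unname(net$edges[1, ]), c("hsa:A1", "hsa:B"))
  # expanding multi-gene entries duplicates the relation per name
  netx <- read_kgml(f, expand_entries = TRUE)
  expect_identical(netx$nodes, c("hsa:A1", "hsa:A2", "hsa:B"))
  expect_identical(nrow(netx$edges), 2L)
})

test_that("KGML self-relations are dropped and cascades come out as paths", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(kgml_doc(
    c('<entry id="1" name="hsa:A" type="gene"/>',
      '<entry id="2" name="hsa:B" type="gene"/>',
      '<entry id="3" name="hsa:C" type="gene"/>',
      '<entry id="4" name="hsa:D" type="gene"/>'),
    c('<relation entry1="1" entry2="2" type="PPrel"/>',
      '<relation entry1="2" entry2="3" type="PPrel"/>',
      '<relation entry1="3" entry2="4" type="PPrel"/>',
      '<relation entry1="2" entry2="2" type="PPrel"/>')), f)
  expect_warning(net <- read_kgml(f), "self-loop")
  expect_identical(nrow(net$edges), 3L)
  expect_identical(census(net, 4)$counts, c("328" = 1L))  # 4-node cascade
})

test_that("KGML group entries expand to their components", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(kgml_doc(
    c('<entry id="1" name="hsa:A" type="gene"/>',
      '<entry id="2" name="hsa:B" type="gene"/>',
      '<entry id="3" name="hsa:C" type="gene"/>',
      paste0('<entry id="9" name="undefined" type="group">',
             '<component id="1"/><component id="2"/></entry>')),
    c('<relation entry1="9" entry2="3" type="PPrel"/>')), f)
  net <- read_kgml(f)
  expect_setequal(paste(net$edges[, 1], net$edges[, 2]),
                  c("hsa:A hsa:C", "hsa:B hsa:C"))
})
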