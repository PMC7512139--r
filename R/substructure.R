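#' Functional subgraphs and irreducibility
#'
#' A functional subgraph of a pattern is obtained by choosing a node subset
#' and a subset of the induced edges that spans the subset and is weakly
#' connected (the structural/functional motif distinction of brain-network
#' analysis).  A pattern with no same-size functional subgraph is
#' *irreducible*; irreducible patterns are exactly the minimal-edge (k-1
#' edge) tree patterns.
#'
#' @name substructure-module
NULL

#' Functional subgraph patterns embedded in a pattern
#'
#' All canonical ids q of size `k_sub` such that some node subset S of the
#' pattern (|S| = k_sub) and some edge subset among S spans S and is weakly
#' connected with canonical id q.  When `k_sub` equals the pattern size the
#' pattern itself is excluded (proper containment only).
#'
#' @param id canonical pattern id.
#' @param k pattern node count.
#' @param k_sub size of the embedded subgraphs, `k_sub <= k`.
#' @return Sorted integer vector of canonical ids.
#' @examples
#' functional_subgraphs(38, 3, 3)  # FFL embeds the SIM, cascade and MIM
#' @export
functional_subgraphs <- function(id, k, k_sub = k) {
  stopifnot(k_sub >= 2, k_sub <= k)
  cpp_functional_subgraphs(as.integer(id), as.integer(k), as.integer(k_sub))
}

#' Irreducible patterns of a catalog
#'
#' Patterns with no same-size functional subgraph: removing any single edge
#' disconnects them.
#'
#' @param catalog a `pattern_catalog` from [enumerate_patterns()].
#' @return Sorted integer vector of canonical ids.
#' @examples
#' irreducible_patterns(enumerate_patterns(3))  # 6, 12, 36
#' @export
irreducible_patterns <- function(catalog) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  k <- catalog$k
  catalog$ids[vapply(catalog$ids, function(id) {
    length(functional_subgraphs(id, k, k)) == 0
  }, logical(1))]
}

#' Binary containment matrix between two catalogs
#'
#' Entry (p, q) is 1 iff pattern q (size `catalog_sub$k`) occurs as a
#' functional subgraph of pattern p (size `catalog_k$k`).
#'
#' @param catalog_k container catalog (rows).
#' @param catalog_sub contained catalog (columns), `catalog_sub$k <=
#'   catalog_k$k`.
#' @return Binary integer matrix with id dimnames.
#' @export
containment_table <- function(catalog_k, catalog_sub) {
  stopifnot(inherits(catalog_k, "pattern_catalog"),
            inherits(catalog_sub, "pattern_catalog"),
            catalog_sub$k <= catalog_k$k)
  out <- matrix(0L, length(catalog_k$ids), length(catalog_sub$ids),
                dimnames = list(catalog_k$ids, catalog_sub$ids))
  for (i in seq_along(catalog_k$ids)) {
    fs <- functional_subgraphs(catalog_k$ids[i], catalog_k$k, catalog_sub$k)
    out[i, as.character(fs)] <- 1L
  }
  out
}
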