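#' Subgraph census of a directed network
#'
#' Enumerates every weakly connected k-node *induced* subgraph occurrence of
#' a network with the ESU (exact subgraph enumeration) recursion, classifies
#' each occurrence by canonical pattern id, and reports node identities.
#' Two occurrences sharing nodes are counted separately; each connected
#' k-subset of nodes is counted exactly once.
#'
#' @name census-module
NULL

# undirected adjacency index list of a network
undirected_adjlist <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  if (nrow(net$edges) > 0) {
    a <- match(net$edges[, 1], net$nodes)
    b <- match(net$edges[, 2], net$nodes)
    for (e in seq_along(a)) {
      adj[[a[e]]] <- c(adj[[a[e]]], b[e])
      adj[[b[e]]] <- c(adj[[b[e]]], a[e])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

#' Enumerate connected k-node subsets (ESU)
#'
#' Yields each node subset of size k whose induced undirected support is
#' connected, exactly once.
#'
#' @param net a [directed_network()].
#' @param k subset size (2 to 5).
#' @return List of character vectors of node labels (sorted within subset).
#' @export
connected_subsets <- function(net, k) {
  idx <- connected_subsets_idx(net, k)
  lapply(idx, function(s) net$nodes[s])
}

connected_subsets_idx <- function(net, k) {
  stopifnot(k >= 2, k <= 5)
  n <- length(net$nodes)
  if (k > n) return(list())
  adj <- undirected_adjlist(net)
  res <- list()
  cnt <- 0L
  push <- function(sub) {
    cnt <<- cnt + 1L
    res[[cnt]] <<- sub
  }
  extend <- function(v, sub, ext) {
    if (length(sub) == k) {
      push(sort(sub))
      return()
    }
    excl <- unique(c(sub, unlist(adj[sub])))
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      nb <- adj[[w]]
      newext <- unique(c(ext, setdiff(nb[nb > v], c(excl, w))))
      extend(v, c(sub, w), newext)
    }
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    extend(v, v, nb[nb > v])
  }
  res[seq_len(cnt)]
}

#' Census of k-node induced subgraph occurrences
#'
#' @param net a [directed_network()].
#' @param k subgraph size (3 or 4 typically; 2 and 5 supported).
#' @param with_nodes if TRUE (default), store per-pattern occurrence node
#'   tuples, ordered so that relabeling the induced submatrix by the stored
#'   order realizes the canonical representative (ties between realizing
#'   permutations broken by lexicographic node label).
#' @return A `subgraph_census`: list with `k`, `counts` (named integer
#'   vector over observed pattern ids), `occurrences` (named list of
#'   occurrence label tuples, or NULL), `covered` (labels of nodes in at
#'   least one occurrence), and `n_subsets`, the total number of connected
#'   k-subsets.
#' @examples
#' net <- directed_network(rbind(c("x", "a"), c("x", "b"), c("x", "c")))
#' census(net, 3)$counts  # id 6 (SIM) occurs 3 times
#' @export
census <- function(net, k, with_nodes = TRUE) {
  subsets <- connected_subsets_idx(net, k)
  m <- adjacency_matrix(net)
  ids <- integer(length(subsets))
  for (s in seq_along(subsets)) {
    sub <- m[subsets[[s]], subsets[[s]], drop = FALSE]
    ids[s] <- cpp_canonical_id(encode_bits(sub), k)
  }
  counts <- table(factor(ids))
  counts <- stats::setNames(as.integer(counts), names(counts))
  occ <- NULL
  if (with_nodes && length(subsets) > 0) {
    occ <- split(seq_along(subsets), as.character(ids))
    occ <- lapply(occ, function(which_s) {
      lapply(which_s, function(s) {
        realizing_order(m[subsets[[s]], subsets[[s]], drop = FALSE],
                        net$nodes[subsets[[s]]])
      })
    })
  } else if (with_nodes) {
    occ <- list()
  }
  covered <- if (length(subsets) > 0) {
    sort(unique(net$nodes[unlist(subsets)]))
  } else {
    character(0)
  }
  structure(list(k = k, counts = counts, occurrences = occ,
                 covered = covered, n_subsets = length(subsets)),
            class = "subgraph_census")
}

# node label tuple, ordered so the induced matrix relabeled by it equals the
# canonical representative; lexicographically smallest among realizers
realizing_order <- function(sub, labels) {
  k <- nrow(sub)
  canon <- cpp_canonical_id(encode_bits(sub), k)
  perms <- permutations_of(k)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    ord <- perms[p, ]
    # relabeled matrix entry (a,b) = sub[node placed at a, node placed at b]
    if (encode_bits(sub[ord, ord, drop = FALSE]) == canon) {
      cand <- labels[ord]
      if (is.null(best) ||
          paste(cand, collapse = "\r") < paste(best, collapse = "\r"))
        best <- cand
    }
  }
  best
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1)))
  }))
}

#' @export
print.subgraph_census <- function(x, ...) {
  cat("<subgraph_census> k =", x$k, "|", x$n_subsets, "occurrences,",
      length(x$counts), "patterns,", length(x$covered), "covered nodes\n")
  invisible(x)
}

#' Node coverage of subgraph occurrences
#'
#' Fraction of network nodes appearing in at least one occurrence, at the
#' 3-node level, the 4-node level, and in both.
#'
#' @param census3,census4 `subgraph_census` objects computed on `net`.
#' @param net the [directed_network()] the censuses were computed on.
#' @return List with fractions `k3`, `k4`, `both`.
#' @export
node_coverage <- function(census3, census4, net) {
  n <- length(net$nodes)
  if (n == 0) stop("undefined coverage: empty network", call. = FALSE)
  list(k3 = length(census3$covered) / n,
       k4 = length(census4$covered) / n,
       both = length(intersect(census3$covered, census4$covered)) / n)
}

#' Normalized pattern frequency distribution of a census
#'
#' Occurrence frequencies normalized to one over the *full* catalog for the
#' census size: patterns absent from the network get probability zero.
#'
#' @param cen a `subgraph_census`.
#' @return A `frequency_distribution`: list with `k` and `probs`, a named
#'   numeric vector over all catalog ids summing to 1.
#' @export
frequency_distribution <- function(cen) {
  if (cen$n_subsets == 0)
    stop("undefined distribution: census is empty", call. = FALSE)
  cat <- enumerate_patterns(cen$k)
  probs <- stats::setNames(numeric(length(cat$ids)), cat$ids)
  probs[names(cen$counts)] <- cen$counts / sum(cen$counts)
  structure(list(k = cen$k, probs = probs), class = "frequency_distribution")
}

#' Uniform frequency distribution over a pattern catalog
#'
#' @param k pattern size (2 to 5).
#' @return A `frequency_distribution` with equal probability on every
#'   catalog pattern.
#' @export
uniform_distribution <- function(k) {
  cat <- enumerate_patterns(k)
  p <- rep(1 / length(cat$ids), length(cat$ids))
  structure(list(k = k, probs = stats::setNames(p, cat$ids)),
            class = "frequency_distribution")
}
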