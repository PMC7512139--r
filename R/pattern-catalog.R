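#' Canonical pattern catalog for small directed graphs
#'
#' A "pattern" is an isomorphism class of weakly connected, self-loop-free
#' binary directed graphs on k nodes (mutual arcs allowed, multi-arcs not).
#' Each class is named by its canonical decimal id: the minimum, over all k!
#' node relabelings, of the row-major bit encoding of the adjacency matrix
#' (most-significant bit = entry (1,1), entry (i,j) = 1 means an edge i -> j).
#' Under this convention id 6 is the single-input module (SIM), 12 the
#' cascade, 36 the multiple-input module (MIM), 38 the feed-forward loop,
#' 98 the 3-cycle and 238 the complete 3-node digraph.
#'
#' @name pattern-catalog
NULL

validate_adjacency <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("adjacency matrix must be square", call. = FALSE)
  if (!all(m %in% c(0, 1)))
    stop("invalid matrix: entries must be binary 0/1", call. = FALSE)
  if (any(diag(m) != 0))
    stop("invalid matrix: nonzero diagonal (self-loops are not allowed)",
         call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Encode an adjacency matrix as its row-major decimal id
#'
#' @param m binary adjacency matrix with zero diagonal.
#' @return Integer id: `sum over (i,j) of m[i,j] * 2^(k^2 - (k*(i-1)+j))`.
#' @examples
#' m <- matrix(0L, 3, 3); m[3, 1] <- m[3, 2] <- 1L
#' encode_bits(m)  # 6, the single-input module
#' @export
encode_bits <- function(m) {
  m <- validate_adjacency(m)
  k <- nrow(m)
  idx <- k * (row(m) - 1) + col(m)        # row-major position, 1-based
  as.integer(sum(m * 2^(k^2 - idx)))
}

#' Decode a decimal pattern id into its adjacency matrix
#'
#' Inverse of [encode_bits()].
#'
#' @param id non-negative integer below `2^(k^2)` with all diagonal bits zero.
#' @param k node count.
#' @return k x k binary adjacency matrix.
#' @examples
#' decode_id(38, 3)  # the feed-forward loop
#' @export
decode_id <- function(id, k) {
  if (id < 0 || id >= 2^(k^2))
    stop("invalid id: out of range for a ", k, "-node pattern", call. = FALSE)
  bits <- as.integer(bitwAnd(id %/% 2^((k^2 - 1):0), 1))
  m <- matrix(bits, k, k, byrow = TRUE)
  if (any(diag(m) != 0))
    stop("invalid id: diagonal bit set (self-loop)", call. = FALSE)
  m
}

#' Test weak connectivity of a pattern adjacency matrix
#'
#' @param m binary adjacency matrix with zero diagonal.
#' @return TRUE iff the undirected support of `m` is connected.
#' @export
is_weakly_connected <- function(m) {
  m <- validate_adjacency(m)
  cpp_is_weakly_connected(encode_bits(m), nrow(m))
}

#' Canonical id of a pattern
#'
#' Minimum of [encode_bits()] over all node relabelings; invariant under
#' permutation of the input's node order.
#'
#' @param m weakly connected binary adjacency matrix with zero diagonal.
#' @return The canonical decimal [encode_bits()] id (a `pattern_id`).
#' @examples
#' # any labeling of the feed-forward loop maps to id 38
#' m <- matrix(0L, 3, 3); m[1, 2] <- m[1, 3] <- m[2, 3] <- 1L
#' canonical_id(m)
#' @export
canonical_id <- function(m) {
  m <- validate_adjacency(m)
  if (!cpp_is_weakly_connected(encode_bits(m), nrow(m)))
    stop("not connected: pattern must be weakly connected", call. = FALSE)
  cpp_canonical_id(encode_bits(m), nrow(m))
}

#' Enumerate all weakly connected k-node patterns
#'
#' Exhaustively scans all `2^(k(k-1))` off-diagonal bit assignments, keeps
#' the weakly connected digraphs and groups them by canonical id.  The
#' catalog sizes are 2, 13, 199 and 9364 for k = 2, 3, 4, 5.
#'
#' @param k node count, 2 to 5.
#' @return A `pattern_catalog`: list with `k`, sorted integer vector `ids`,
#'   and `matrices`, the list of canonical adjacency representatives.
#' @examples
#' cat3 <- enumerate_patterns(3)
#' length(cat3$ids)  # 13
#' @export
enumerate_patterns <- function(k) {
  if (!(k %in% 2:5))
    stop("unsupported size: k must be between 2 and 5", call. = FALSE)
  key <- paste0("k", k)
  if (!is.null(.catalog_cache[[key]])) return(.catalog_cache[[key]])
  ids <- cpp_enumerate_patterns(k)
  cat <- structure(
    list(k = k, ids = ids, matrices = lapply(ids, decode_id, k = k)),
    class = "pattern_catalog")
  .catalog_cache[[key]] <- cat
  cat
}

#' @export
print.pattern_catalog <- function(x, ...) {
  cat("<pattern_catalog> k =", x$k, "with", length(x$ids), "patterns\n")
  cat("ids:", paste(head(x$ids, 13), collapse = " "),
      if (length(x$ids) > 13) "..." else "", "\n")
  invisible(x)
}
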