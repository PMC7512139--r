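#' Non-spectral pattern descriptors
#'
#' Traditional reciprocity R, correlation reciprocity r, cyclomatic
#' complexity CC, and a pluggable Kolmogorov-complexity estimate KC.
#'
#' @name descriptors-module
NULL

#' Traditional reciprocity R
#'
#' Fraction of arcs belonging to mutual dyads: the number of ordered edges
#' (i,j) whose mirror (j,i) is also present, divided by the edge count.
#'
#' @param m binary adjacency matrix with zero diagonal, at least one edge.
#' @return Real in \[0, 1\].
#' @export
reciprocity_traditional <- function(m) {
  m <- validate_adjacency(m)
  e <- sum(m)
  if (e == 0) stop("undefined reciprocity: no edges", call. = FALSE)
  sum(m * t(m)) / e
}

#' Correlation reciprocity r
#'
#' Pearson-style correlation between mirror off-diagonal adjacency entries:
#' `r = sum (a_ij - abar)(a_ji - abar) / sum (a_ij - abar)^2` over i != j,
#' with `abar` the mean off-diagonal entry.  Positive r indicates a
#' bidirectional tendency; negative r, pure in/out structure.  For the
#' complete digraph the expression is 0/0 and r is defined as 1.
#'
#' @inheritParams reciprocity_traditional
#' @return Real in \[-1, 1\].
#' @examples
#' reciprocity_r(decode_id(110, 3))  # -0.2
#' @export
reciprocity_r <- function(m) {
  m <- validate_adjacency(m)
  if (sum(m) == 0) stop("undefined reciprocity: no edges", call. = FALSE)
  off <- row(m) != col(m)
  abar <- sum(m[off]) / sum(off)
  den <- sum((m[off] - abar)^2)
  if (den == 0) return(1)  # complete digraph: all off-diagonal entries equal
  sum((m[off] - abar) * (t(m)[off] - abar)) / den
}

#' Cyclomatic complexity CC
#'
#' `CC = e - N + 2P` with P the number of exit nodes (out-degree zero),
#' measuring independent paths of the decision structure.
#'
#' @inheritParams reciprocity_traditional
#' @return Non-negative integer.
#' @examples
#' cyclomatic_complexity(decode_id(6, 3))  # 3: two sinks
#' @export
cyclomatic_complexity <- function(m) {
  m <- validate_adjacency(m)
  as.integer(sum(m) - nrow(m) + 2 * sum(rowSums(m) == 0))
}

#' Context-tree-weighting complexity backend
#'
#' The default algorithmic-complexity backend: the code length (in bits) a
#' depth-`depth` context-tree-weighting universal code with Krichevsky-
#' Trofimov leaf estimators assigns to a bit string.  Regular strings
#' compress to short code lengths, random-looking strings do not, so the
#' value estimates Kolmogorov complexity up to an additive constant in the
#' same spirit as CTM-table lookups.  Deterministic for a fixed depth.
#'
#' @param depth context depth in bits (default 3).
#' @return A `kc_backend`: list with `fun(bits) -> bits`, `name`, `version`.
#' @export
ctw_backend <- function(depth = 3L) {
  depth <- as.integer(depth)
  stopifnot(depth >= 0)
  structure(list(fun = function(bits) ctw_code_length(bits, depth),
                 name = "ctw-kt", version = paste0("depth", depth)),
            class = "kc_backend")
}

# -log2 of the CTW weighted probability of a 0/1 vector (zero-padded context)
ctw_code_length <- function(bits, depth = 3L) {
  stopifnot(all(bits %in% c(0L, 1L)), length(bits) >= 1)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(ctx) paste0("c", paste(ctx, collapse = ""))
  n <- length(bits)
  padded <- c(rep(0L, depth), bits)
  for (t in seq_len(n)) {
    ctx <- padded[seq_len(depth) + t - 1L]  # the `depth` symbols before bit t
    b <- bits[t]
    for (d in 0:depth) {
      kk <- key(tail(ctx, d))
      cur <- counts[[kk]]
      if (is.null(cur)) cur <- c(0, 0)
      cur[b + 1] <- cur[b + 1] + 1
      counts[[kk]] <- cur
    }
  }
  kt_log2 <- function(ab) {  # log2 KT probability of (zeros, ones)
    if (sum(ab) == 0) return(0)
    (lgamma(ab[1] + 0.5) + lgamma(ab[2] + 0.5) - 2 * lgamma(0.5) -
       lgamma(sum(ab) + 1) + lgamma(1)) / log(2)
  }
  pw <- function(ctx, d) {  # log2 weighted probability at a context node
    cur <- counts[[key(ctx)]]
    if (is.null(cur)) return(0)
    lkt <- kt_log2(cur)
    if (d == depth) return(lkt)
    lch <- pw(c(0L, ctx), d + 1) + pw(c(1L, ctx), d + 1)
    mx <- max(lkt, lch)
    mx + log2(2^(lkt - mx) + 2^(lch - mx)) - 1
  }
  -pw(integer(0), 0)
}

#' Kolmogorov complexity estimate of a pattern (block decomposition)
#'
#' Serializes the adjacency matrix as its row-major bit string and applies
#' the block decomposition method: the string is cut into blocks of at most
#' `block_size` bits, and the estimate is the sum over unique blocks of the
#' backend's code length plus log2 of the block's multiplicity.  Strings no
#' longer than `block_size` (every pattern up to 3 nodes with the default)
#' reduce to a single backend lookup.
#'
#' @inheritParams reciprocity_traditional
#' @param backend a `kc_backend`, e.g. [ctw_backend()].
#' @param block_size maximal block length in bits (default 12).
#' @return Positive real (bits), deterministic for a fixed backend.
#' @export
kolmogorov_complexity <- function(m, backend = ctw_backend(),
                                  block_size = 12L) {
  m <- validate_adjacency(m)
  if (!inherits(backend, "kc_backend") || !is.function(backend$fun))
    stop("complexity backend missing or invalid: supply a 'kc_backend'",
         call. = FALSE)
  bits <- as.integer(t(m))  # row-major serialization
  if (length(bits) > 4 * block_size)
    stop("unsupported size: bit string longer than backend block support",
         call. = FALSE)
  starts <- seq(1, length(bits), by = block_size)
  blocks <- vapply(starts, function(s) {
    paste(bits[s:min(s + block_size - 1, length(bits))], collapse = "")
  }, character(1))
  tab <- table(blocks)
  sum(vapply(names(tab), function(b) {
    backend$fun(as.integer(strsplit(b, "")[[1]]))
  }, numeric(1)) + log2(as.integer(tab)))
}
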