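#' Synthetic directed networks
#'
#' Generators for seeded random digraphs with controllable size, density
#' and reciprocity, plus planted-pattern fixtures with exact ground truth,
#' so the whole census/descriptor pipeline is testable without external
#' pathway downloads.
#'
#' @name synth-module
NULL

#' Seeded random digraph with target reciprocity
#'
#' Samples each unordered node pair from a four-outcome categorical
#' distribution (no edge, i->j, j->i, mutual).  With edge probability p per
#' ordered pair and target correlation reciprocity rho, the mutual-dyad
#' probability is `m = p^2 + rho * p * (1 - p)` so the expected correlation
#' between mirror entries equals rho; dyad-level generation is required
#' because reciprocity is a dyad property that independent per-arc sampling
#' cannot reach.
#'
#' @param n node count (>= 2).
#' @param p_edge probability of each ordered edge, in \[0, 1\].
#' @param target_r desired correlation reciprocity in \[-1, 1\], or NULL
#'   (default) for independent arcs (rho = 0).
#' @param seed integer seed fixing the full output, or NULL.
#' @return A [directed_network()] with nodes `v001`, `v002`, ...
#' @export
random_digraph <- function(n, p_edge, target_r = NULL, seed = NULL) {
  stopifnot(n >= 2, p_edge >= 0, p_edge <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- p_edge
  rho <- if (is.null(target_r)) 0 else target_r
  stopifnot(rho >= -1, rho <= 1)
  m <- p^2 + rho * p * (1 - p)
  lo <- max(0, 2 * p - 1)
  if (m < lo - 1e-12 || m > p + 1e-12)
    stop("infeasible config: target_r = ", rho, " unreachable at p_edge = ",
         p, call. = FALSE)
  m <- min(max(m, lo), p)
  probs <- c(none = 1 - 2 * p + m, fwd = p - m, rev = p - m, mutual = m)
  labels <- sprintf("v%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  draw <- sample(4, nrow(pairs), replace = TRUE, prob = probs)
  from <- character(0); to <- character(0)
  fwd <- draw == 2 | draw == 4
  rev <- draw == 3 | draw == 4
  from <- c(labels[pairs[fwd, "row"]], labels[pairs[rev, "col"]])
  to <- c(labels[pairs[fwd, "col"]], labels[pairs[rev, "row"]])
  directed_network(cbind(from, to), nodes = labels)
}

#' Planted-pattern network with exact ground truth
#'
#' Builds the disjoint union of the requested pattern instances, plus
#' optional background nodes arranged as disjoint single edges (a matching)
#' that never touch a planted instance and contain no connected subset of
#' three or more nodes — so the census at k >= 3 is known exactly by
#' construction even with background present.
#'
#' @param plant data.frame with columns `k`, `id`, `count`: how many
#'   node-disjoint instances of each canonical pattern to plant.
#' @param seed integer seed (only the background is stochastic), or NULL.
#' @param background_nodes number of extra background nodes (default 0).
#' @param background_p probability that each background node pair is joined
#'   by its matching edge.
#' @return List with `net` (a [directed_network()]) and `truth`, a list
#'   mapping each planted size k to the named occurrence-count vector the
#'   census must recover.
#' @export
planted_pattern_network <- function(plant, seed = NULL, background_nodes = 0,
                                    background_p = 0.1) {
  stopifnot(is.data.frame(plant), nrow(plant) >= 1,
            all(c("k", "id", "count") %in% names(plant)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  from <- character(0); to <- character(0); nodes <- character(0)
  inst <- 0L
  for (r in seq_len(nrow(plant))) {
    m <- decode_id(plant$id[r], plant$k[r])
    for (cc in seq_len(plant$count[r])) {
      inst <- inst + 1L
      lab <- sprintf("g%03d_n%d", inst, seq_len(plant$k[r]))
      nodes <- c(nodes, lab)
      ed <- which(m == 1L, arr.ind = TRUE)
      from <- c(from, lab[ed[, 1]])
      to <- c(to, lab[ed[, 2]])
    }
  }
  if (background_nodes > 0) {
    bg <- sprintf("bg_n%d", seq_len(background_nodes))
    nodes <- c(nodes, bg)
    npair <- background_nodes %/% 2
    if (npair > 0 && background_p > 0) {
      on <- rbinom(npair, 1, background_p) == 1  # disjoint matching edges
      from <- c(from, bg[2 * which(on) - 1])
      to <- c(to, bg[2 * which(on)])
    }
  }
  net <- directed_network(cbind(from, to), nodes = nodes)
  truth <- lapply(split(plant, plant$k), function(pp) {
    stats::setNames(as.integer(pp$count), pp$id)
  })
  list(net = net, truth = truth)
}
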