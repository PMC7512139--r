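#' Entropy, rank statistics and driver-gene enrichment
#'
#' Shannon entropy of subgraph frequency distributions, minimum-rank /
#' Spearman statistics for descriptor comparisons, and 2x2 odds-ratio
#' enrichment of a gene set in the subgraph module of a network.
#'
#' @name stats-module
NULL

as_probs <- function(dist) {
  p <- if (inherits(dist, "frequency_distribution")) dist$probs else dist
  stopifnot(is.numeric(p), all(p >= 0), abs(sum(p) - 1) < 1e-9)
  p
}

#' Shannon entropy of a frequency distribution (bits)
#'
#' `-sum p log2 p` with the 0 log 0 = 0 convention, so patterns absent from
#' a network contribute nothing.
#'
#' @param dist a `frequency_distribution` (from [frequency_distribution()]
#'   or [uniform_distribution()]) or a plain probability vector.
#' @return Real in \[0, log2(number of patterns)\].
#' @examples
#' shannon_entropy(uniform_distribution(3))  # log2(13) = 3.700
#' @export
shannon_entropy <- function(dist) {
  p <- as_probs(dist)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized Shannon entropy
#'
#' Entropy divided by log2 of the catalog size (13 for k = 3, 199 for
#' k = 4), mapping any distribution into \[0, 1\].
#'
#' @param dist a `frequency_distribution` with `k` of 3 or 4.
#' @return Real in \[0, 1\].
#' @export
normalized_entropy <- function(dist) {
  if (!inherits(dist, "frequency_distribution") || !(dist$k %in% c(3, 4)))
    stop("normalized entropy is defined for 3- and 4-node distributions",
         call. = FALSE)
  shannon_entropy(dist) / log2(length(dist$probs))
}

#' Minimum (competition) ranks
#'
#' Rank of a value = 1 + the number of strictly smaller (ascending) or
#' strictly larger (descending) values; ties share the minimum rank.
#'
#' @param values numeric vector.
#' @param ascending rank smallest value 1 (default TRUE).
#' @return Integer vector of ranks.
#' @export
min_rank <- function(values, ascending = TRUE) {
  stopifnot(length(values) >= 1)
  v <- if (ascending) values else -values
  as.integer(rank(v, ties.method = "min"))
}

#' Spearman rank correlation of two rank vectors
#'
#' Pearson correlation of the two (already ranked) vectors.
#'
#' @param x,y equal-length numeric rank vectors (length >= 3).
#' @return Real in \[-1, 1\].
#' @export
spearman_rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  cor(x, y)
}

#' 2x2 contingency table of a gene set versus the subgraph module
#'
#' The subgraph module is the set of network nodes appearing in at least
#' one 3-node or 4-node occurrence (node-level membership: a gene in any
#' occurrence counts once).  Cells: a = set genes in the module, b = set
#' genes outside it, c/d the same for the remaining network nodes, so
#' a + b + c + d equals the node count.  Genes of the set absent from the
#' network are ignored.
#'
#' @param net a [directed_network()].
#' @param census3,census4 `subgraph_census` objects computed on `net`.
#' @param drivers character vector of gene labels (e.g. driver genes).
#' @return A `contingency_table`: list with counts `a`, `b`, `c`, `d`.
#' @export
contingency_table <- function(net, census3, census4, drivers) {
  if (length(net$nodes) == 0) stop("empty network", call. = FALSE)
  module <- union(census3$covered, census4$covered)
  in_mod <- net$nodes %in% module
  is_drv <- net$nodes %in% drivers
  structure(list(a = sum(is_drv & in_mod), b = sum(is_drv & !in_mod),
                 c = sum(!is_drv & in_mod), d = sum(!is_drv & !in_mod)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> a =", x$a, "b =", x$b,
      "c =", x$c, "d =", x$d, "\n")
  invisible(x)
}

#' Odds ratio of a 2x2 contingency table
#'
#' `(a * d) / (b * c)`, with a pseudo-count added to every cell if (and
#' only if) any cell is zero, since the ratio is otherwise not defined.
#' An odds ratio above one means the gene set is enriched in the subgraph
#' module.
#'
#' @param t a [contingency_table()] (or list with a, b, c, d).
#' @param pseudo non-negative pseudo-count (default 1).
#' @return Positive real.
#' @examples
#' odds_ratio(list(a = 10, b = 5, c = 2, d = 8))  # 8
#' @export
odds_ratio <- function(t, pseudo = 1) {
  stopifnot(pseudo >= 0)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) cells <- cells + pseudo
  if (cells[2] * cells[3] == 0)
    stop("undefined odds ratio: zero denominator after pseudo-correction",
         call. = FALSE)
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}
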