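#' Directed network container
#'
#' A light container for labeled directed networks: an ordered node set and
#' a set of directed edges (source, target).  Self-loops are dropped at
#' construction (the pattern space has a zero diagonal) and duplicate edges
#' are collapsed; both counts are recorded.
#'
#' @param edges two-column character matrix or data.frame (source, target).
#' @param nodes optional extra node labels (isolated nodes).
#' @return A `directed_network`: list with `nodes`, `edges` (2-column
#'   character matrix), `n_selfloops_dropped`, `n_duplicates_collapsed`.
#' @export
directed_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), 0, 2)
  }
  if (ncol(edges) < 2)
    stop("edges must have two columns (source, target)", call. = FALSE)
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  self <- edges[, 1] == edges[, 2]
  n_self <- sum(self)
  if (n_self > 0) {
    warning(n_self, " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  key <- paste(edges[, 1], edges[, 2], sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  structure(list(nodes = nodes, edges = edges,
                 n_selfloops_dropped = n_self,
                 n_duplicates_collapsed = n_dup),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("<directed_network>", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a directed network from a two-column edge list
#'
#' Whitespace/tab-separated, one edge per line (source, target; extra fields
#' ignored), `#` comments allowed.
#'
#' @param path file path.
#' @return A [directed_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0)
    stop("empty network: no edges in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(fields, length, 0L) < 2)
  if (length(bad) > 0)
    stop("parse error at line ", idx[bad[1]], " of ", path,
         ": expected at least two fields", call. = FALSE)
  edges <- t(vapply(fields, function(f) f[1:2], character(2)))
  directed_network(edges)
}

#' Write a directed network as a two-column edge list
#'
#' @param net a [directed_network()].
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  writeLines(paste(net$edges[, 1], net$edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path file path; `#` comments allowed, whitespace trimmed,
#'   duplicates removed.
#' @return Character vector of unique labels.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^(#|$)", lines)]
  out <- unique(lines)
  if (length(out) == 0)
    stop("empty gene set in ", path, call. = FALSE)
  out
}

#' Read a directed network from a minimal KEGG KGML file
#'
#' Entries become nodes (labeled by the first name token of each entry);
#' each `relation` element becomes a directed edge entry1 -> entry2.
#' `group` entries are expanded to their component entries.  Relation
#' subtypes are ignored: KGML is used purely as a source of directed edges.
#'
#' @param path KGML (KEGG XML) file path.
#' @param expand_entries if TRUE, a multi-gene entry (several space-separated
#'   names) becomes one node per name, with its relations duplicated across
#'   the names; if FALSE (default) only the first name labels the entry.
#' @return A [directed_network()].
#' @export
read_kgml <- function(path, expand_entries = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("KGML format error: ",
                                           conditionMessage(e), call. = FALSE))
  entries <- xml2::xml_find_all(doc, ".//entry")
  if (length(entries) == 0)
    stop("KGML format error: no entries", call. = FALSE)
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  enames <- strsplit(xml2::xml_attr(entries, "name"), "\\s+")
  labels_of <- function(i) {
    nm <- enames[[i]]
    nm <- nm[nzchar(nm)]
    if (length(nm) == 0) nm <- paste0("entry_", eid[i])
    if (expand_entries) nm else nm[1]
  }
  # group entries expand to the labels of their components
  comp_of <- lapply(seq_along(entries), function(i) {
    if (identical(etype[i], "group")) {
      cid <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], ".//component"),
                            "id")
      unlist(lapply(match(cid, eid), labels_of))
    } else {
      labels_of(i)
    }
  })
  names(comp_of) <- eid
  rels <- xml2::xml_find_all(doc, ".//relation")
  if (length(rels) == 0) {
    warning("empty network: KGML has no relations", call. = FALSE)
    return(directed_network(matrix(character(0), 0, 2),
                            nodes = unique(unlist(comp_of))))
  }
  e1 <- xml2::xml_attr(rels, "entry1")
  e2 <- xml2::xml_attr(rels, "entry2")
  from <- character(0); to <- character(0)
  for (r in seq_along(rels)) {
    src <- comp_of[[e1[r]]]; dst <- comp_of[[e2[r]]]
    if (is.null(src) || is.null(dst)) next
    grid <- expand.grid(from = src, to = dst, stringsAsFactors = FALSE)
    from <- c(from, grid$from); to <- c(to, grid$to)
  }
  directed_network(cbind(from, to), nodes = unique(unlist(comp_of)))
}

#' Dense adjacency matrix of a directed network
#'
#' @param net a [directed_network()].
#' @return Binary integer matrix with nodes in `net$nodes` order.
#' @export
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  m <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0)
    m[cbind(match(net$edges[, 1], net$nodes),
            match(net$edges[, 2], net$nodes))] <- 1L
  m
}
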