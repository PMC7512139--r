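# Independent oracles written in plain R, deliberately avoiding the
# package's C++ canonicalization / ESU code paths they are used to check.

oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (sub in oracle_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1]] <- append(sub, k, after = pos)
    }
  }
  out
}

oracle_encode <- function(m) {
  k <- nrow(m)
  idx <- k * (row(m) - 1) + col(m)
  sum(m * 2^(k^2 - idx))
}

oracle_connected <- function(m) {
  k <- nrow(m)
  supp <- (m + t(m)) > 0
  seen <- c(TRUE, rep(FALSE, k - 1))
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(apply(supp[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

oracle_canonical <- function(m) {
  k <- nrow(m)
  min(vapply(oracle_perms(k), function(p) oracle_encode(m[p, p]), numeric(1)))
}

# brute-force census: classify every connected C(n,k) subset
oracle_census_counts <- function(net, k) {
  m <- adjacency_matrix(net)
  n <- nrow(m)
  if (n < k) return(integer(0))
  counts <- integer(0)
  for (s in asplit(combn(n, k), 2)) {
    sub <- m[s, s, drop = FALSE]
    if (!oracle_connected(sub)) next
    id <- as.character(oracle_canonical(sub))
    counts[id] <- if (is.na(counts[id])) 1L else counts[id] + 1L
  }
  counts[order(as.integer(names(counts)))]
}

sorted_counts <- function(counts) counts[order(as.integer(names(counts)))]

# Printed reference values for the 13 three-node patterns: the nine graph
# energies, reciprocity r, and cyclomatic complexity CC (2-decimal display
# precision for the energies).
table3_printed <- function() {
  txt <- "id E LE QE AAt LLt QQt ALt AQt LQt
6 0.00 2.67 2.67 1.41 4.32 4.32 1.41 1.41 3.83
12 0.00 2.67 2.67 2.00 4.34 4.34 2.00 2.00 3.93
14 2.00 4.00 4.00 2.41 6.13 6.13 3.00 3.00 5.45
36 0.00 2.67 2.67 1.41 4.32 4.32 1.41 1.41 3.83
38 0.00 4.00 4.00 2.24 6.39 6.34 2.63 2.37 6.01
46 2.00 5.33 5.33 2.73 8.24 8.16 2.00 3.86 7.59
74 2.00 4.00 4.00 2.41 6.13 6.13 3.00 3.00 5.45
78 2.83 5.33 5.33 2.83 8.00 8.00 3.86 3.86 7.29
98 3.00 4.29 4.46 3.00 6.29 6.46 4.25 4.36 6.01
102 3.06 5.33 5.56 3.24 8.17 8.25 4.76 5.02 7.57
108 2.00 5.33 5.33 2.73 8.24 8.16 2.00 3.86 7.59
110 3.24 6.67 6.72 3.49 10.09 10.09 5.38 5.70 9.40
238 4.00 8.00 8.00 4.00 12.00 12.00 6.47 6.93 11.21"
  read.table(text = txt, header = TRUE)
}

# reciprocity r and mean off-diagonal entry abar per pattern
table4_printed <- function() {
  data.frame(
    id = c(6, 12, 14, 36, 38, 46, 74, 78, 98, 102, 108, 110, 238),
    r = c(-0.5, -0.5, 1 / 3, -0.5, -1, -0.5, 1 / 3, 1, -1, -0.5, -0.5,
          -0.2, 1),
    e = c(2, 2, 3, 2, 3, 4, 3, 4, 3, 4, 4, 5, 6))
}

kc_reference <- function() {
  read.table(system.file("extdata", "kc_reference_3node.tsv",
                         package = "netsubgraph"),
             header = TRUE, sep = "\t", comment.char = "#")
}

k3_ids <- c(6, 12, 14, 36, 38, 46, 74, 78, 98, 102, 108, 110, 238)
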