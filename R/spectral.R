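#' Spectral graph energies of directed patterns
#'
#' For a pattern with adjacency matrix A, total-degree diagonal matrix D
#' (degree = in-degree + out-degree), Laplacian L = D - A and signless
#' Laplacian Q = D + A, nine energies are defined:
#' * `E`  = sum of |eigenvalues of A| (moduli for complex eigenvalues),
#' * `LE` = sum of |eigenvalues of L| - 2e/n,
#' * `QE` = sum of |eigenvalues of Q| - 2e/n,
#' * the generalized energies `AAt`, `LLt`, `QQt` and asymmetric
#'   generalized energies `ALt`, `AQt`, `LQt`: for matrices M, N drawn from
#'   {A, L, Q}, the sum of square roots of the eigenvalue moduli of M N^t
#'   (equal to the singular-value sum of M when M = N; no 2e/n correction).
#'
#' @name spectral-module
NULL

#' Names of the nine graph energies
#'
#' @return Character vector: E, LE, QE, AAt, LLt, QQt, ALt, AQt, LQt.
#' @export
energy_names <- function() c("E", "LE", "QE", "AAt", "LLt", "QQt",
                             "ALt", "AQt", "LQt")

# Eigenvalues of a small integer matrix via its exact characteristic
# polynomial (Faddeev-LeVerrier, integer coefficients), with exact zero
# roots deflated before polyroot.  Matrices sharing a characteristic
# polynomial (equienergetic patterns, relabelings) then yield bit-identical
# spectra, and nilpotent patterns yield exact zeros, which plain dgeev
# cannot guarantee for defective eigenvalues.  Falls back to eigen() for
# non-integer or larger matrices.
small_matrix_eigen <- function(M) {
  n <- nrow(M)
  if (n > 6 || any(M != round(M))) {
    return(as.complex(eigen(M, only.values = TRUE)$values))
  }
  cs <- numeric(n + 1)                       # lambda^n ... constant
  cs[1] <- 1
  Mk <- diag(1, n)
  for (k in seq_len(n)) {
    Mk <- M %*% Mk
    cs[k + 1] <- -sum(diag(Mk)) / k
    Mk <- Mk + diag(cs[k + 1], n)
  }
  coefs <- rev(round(cs))                    # constant first, exact integers
  nzero <- 0L
  while (nzero < n && coefs[1] == 0) {       # deflate exact zero roots
    coefs <- coefs[-1]
    nzero <- nzero + 1L
  }
  roots <- if (length(coefs) > 1) polyroot(coefs) else complex(0)
  c(rep(complex(real = 0), nzero), roots)
}

matrix_of <- function(m, which = c("A", "L", "Q")) {
  which <- match.arg(which)
  switch(which, A = m, L = degree_matrix(m) - m, Q = degree_matrix(m) + m)
}

#' Total-degree diagonal matrix
#'
#' @param m binary adjacency matrix with zero diagonal.
#' @return Diagonal matrix with entry i = in-degree(i) + out-degree(i).
#' @export
degree_matrix <- function(m) {
  m <- validate_adjacency(m)
  diag(rowSums(m) + colSums(m), nrow(m))
}

#' Adjacency graph energy
#'
#' Sum of the moduli of the adjacency eigenvalues.
#'
#' @param m binary adjacency matrix with zero diagonal.
#' @return Non-negative real.
#' @examples
#' graph_energy(decode_id(238, 3))  # 4: complete 3-node digraph
#' @export
graph_energy <- function(m) {
  m <- validate_adjacency(m)
  sum(Mod(small_matrix_eigen(m)))
}

#' Laplacian energy
#'
#' `sum |eigenvalues of L| - 2e/n` with L = D - A and total-degree D.
#'
#' @inheritParams graph_energy
#' @export
laplacian_energy <- function(m) {
  m <- validate_adjacency(m)
  L <- degree_matrix(m) - m
  sum(Mod(small_matrix_eigen(L))) - 2 * sum(m) / nrow(m)
}

#' Signless Laplacian energy
#'
#' `sum |eigenvalues of Q| - 2e/n` with Q = D + A and total-degree D.
#'
#' @inheritParams graph_energy
#' @export
signless_laplacian_energy <- function(m) {
  m <- validate_adjacency(m)
  Q <- degree_matrix(m) + m
  sum(Mod(small_matrix_eigen(Q))) - 2 * sum(m) / nrow(m)
}

#' Generalized and asymmetric generalized energies
#'
#' Sum of the square roots of the eigenvalue moduli of M N^t, with M and N
#' drawn from A, L, Q.  For M = N this equals the singular-value sum of M.
#'
#' @inheritParams graph_energy
#' @param left,right one of "A", "L", "Q".
#' @examples
#' generalized_energy(decode_id(238, 3), "L", "Q")  # 11.21
#' @export
generalized_energy <- function(m, left = c("A", "L", "Q"),
                               right = c("A", "L", "Q")) {
  m <- validate_adjacency(m)
  M <- matrix_of(m, match.arg(left))
  N <- matrix_of(m, match.arg(right))
  sum(sqrt(Mod(small_matrix_eigen(M %*% t(N)))))
}

#' Spectrum of a pattern matrix or matrix product
#'
#' Eigenvalues ordered by descending real part, then descending imaginary
#' part; complex values occur in conjugate pairs, and the adjacency
#' spectrum always sums to zero.
#'
#' @inheritParams graph_energy
#' @param which matrix to use: "A", "L", "Q" or a product "AAt", "LLt",
#'   "QQt", "ALt", "AQt", "LQt".
#' @return Complex vector of length n.
#' @export
spectrum_of <- function(m, which = "A") {
  m <- validate_adjacency(m)
  valid <- c("A", "L", "Q", energy_names()[-(1:3)])
  if (!which %in% valid)
    stop("unknown matrix '", which, "'", call. = FALSE)
  M <- if (nchar(which) == 1) {
    matrix_of(m, which)
  } else {
    matrix_of(m, substr(which, 1, 1)) %*% t(matrix_of(m, substr(which, 2, 2)))
  }
  v <- small_matrix_eigen(M)
  v[order(-Re(v), -Im(v))]
}

#' All nine energies of one pattern
#'
#' @inheritParams graph_energy
#' @return Named numeric vector over [energy_names()].
#' @export
energy_vector <- function(m) {
  m <- validate_adjacency(m)
  c(E = graph_energy(m), LE = laplacian_energy(m),
    QE = signless_laplacian_energy(m),
    AAt = generalized_energy(m, "A", "A"),
    LLt = generalized_energy(m, "L", "L"),
    QQt = generalized_energy(m, "Q", "Q"),
    ALt = generalized_energy(m, "A", "L"),
    AQt = generalized_energy(m, "A", "Q"),
    LQt = generalized_energy(m, "L", "Q"))
}

#' Energy table of a pattern catalog
#'
#' @param catalog a `pattern_catalog` from [enumerate_patterns()].
#' @return data.frame with column `id` and the nine energy columns.
#' @export
energy_table <- function(catalog) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  en <- t(vapply(catalog$matrices, energy_vector,
                 stats::setNames(numeric(9), energy_names())))
  data.frame(id = catalog$ids, en, row.names = NULL)
}

#' Energy bounds and ratio across a catalog
#'
#' @param table an [energy_table()] data.frame.
#' @param which one of [energy_names()].
#' @return List with `min`, `max` and `ratio` (= max/min; `NA` when the
#'   minimum is zero, where the ratio is undefined).
#' @export
energy_bounds <- function(table, which) {
  stopifnot(which %in% energy_names(), nrow(table) > 0)
  v <- table[[which]]
  lo <- min(v); hi <- max(v)
  list(min = lo, max = hi, ratio = if (lo == 0) NA_real_ else hi / lo)
}
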