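#' Minimal unique identifiers for patterns
#'
#' Measures how well combinations of descriptors (energies, reciprocity r,
#' cyclomatic complexity CC, energy spectra) distinguish the patterns of a
#' catalog, and searches greedily for a minimal identifying set.
#'
#' @name identity-module
NULL

#' Full descriptor table for a catalog
#'
#' @param k pattern size (2 to 5).
#' @param kc_backend optional `kc_backend` for the KC column (NULL skips KC).
#' @param with_spectra if TRUE (default) store the nine spectra per pattern.
#' @return A `descriptor_table`: list with `k`, `ids`, `energies` (matrix,
#'   one row per pattern), `R`, `r`, `CC`, `KC` (or NULL), and `spectra`
#'   (per matrix name, a list of complex spectra).
#' @export
build_descriptor_table <- function(k, kc_backend = NULL, with_spectra = TRUE) {
  cat <- enumerate_patterns(k)
  mats <- cat$matrices
  en <- t(vapply(mats, energy_vector,
                 stats::setNames(numeric(9), energy_names())))
  spectra <- NULL
  if (with_spectra) {
    mnames <- energy_names()[-(1:3)]
    spectra <- lapply(stats::setNames(mnames, mnames), function(w) {
      lapply(mats, spectrum_of, which = w)
    })
    spectra <- c(spectra, list(
      A = lapply(mats, spectrum_of, which = "A"),
      L = lapply(mats, spectrum_of, which = "L"),
      Q = lapply(mats, spectrum_of, which = "Q")))
  }
  structure(list(
    k = k, ids = cat$ids, energies = en,
    R = vapply(mats, reciprocity_traditional, numeric(1)),
    r = vapply(mats, reciprocity_r, numeric(1)),
    CC = vapply(mats, cyclomatic_complexity, integer(1)),
    KC = if (!is.null(kc_backend)) {
      vapply(mats, kolmogorov_complexity, numeric(1), backend = kc_backend)
    },
    spectra = spectra), class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> k =", x$k, "with", length(x$ids), "patterns;",
      "KC:", if (is.null(x$KC)) "absent" else "present", "\n")
  invisible(x)
}

#' Descriptor key
#'
#' @param components character vector of component names: any of
#'   [energy_names()], `"R"`, `"r"`, `"CC"`, `"KC"`, or `"spectrum:<M>"`
#'   with `<M>` one of A, L, Q, AAt, LLt, QQt, ALt, AQt, LQt.
#' @param tol float-comparison tolerance (> 0, default 1e-6) applied to
#'   full-precision values.
#' @return A `descriptor_key`.
#' @export
descriptor_key <- function(components, tol = 1e-6) {
  stopifnot(length(components) >= 1, tol > 0)
  structure(list(components = components, tol = tol),
            class = "descriptor_key")
}

component_values <- function(table, comp) {
  if (comp %in% energy_names()) return(as.list(table$energies[, comp]))
  if (comp %in% c("R", "r", "CC", "KC")) {
    v <- table[[comp]]
    if (is.null(v)) stop("descriptor table has no ", comp, call. = FALSE)
    return(as.list(as.numeric(v)))
  }
  if (startsWith(comp, "spectrum:")) {
    w <- sub("^spectrum:", "", comp)
    sp <- table$spectra[[w]]
    if (is.null(sp)) stop("no spectra stored for ", w, call. = FALSE)
    return(sp)
  }
  stop("unknown descriptor component '", comp, "'", call. = FALSE)
}

values_equal <- function(a, b, tol) {
  if (length(a) != length(b)) return(FALSE)
  max(Mod(as.complex(a) - as.complex(b))) <= tol
}

#' Partition a catalog by equality under a descriptor key
#'
#' Patterns are grouped when all key components agree (floats within the
#' key's tolerance; spectra compared element-wise after canonical ordering).
#'
#' @param table a [build_descriptor_table()] result.
#' @param key a [descriptor_key()].
#' @return List of integer vectors of pattern ids (the equivalence classes),
#'   in order of first appearance.
#' @export
descriptor_classes <- function(table, key) {
  stopifnot(inherits(key, "descriptor_key"))
  vals <- lapply(key$components, component_values, table = table)
  n <- length(table$ids)
  cls <- integer(n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(reps)) {
      j <- reps[ci]
      same <- all(vapply(vals, function(v) {
        values_equal(v[[i]], v[[j]], key$tol)
      }, logical(1)))
      if (same) { hit <- ci; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    cls[i] <- hit
  }
  unname(split(table$ids, cls)[as.character(seq_along(reps))])
}

#' Count distinguishable patterns under a key
#'
#' @inheritParams descriptor_classes
#' @param mode `"classes"` counts equivalence classes (default);
#'   `"singletons"` counts patterns alone in their class.
#' @return Integer count.
#' @export
distinguishability_count <- function(table, key,
                                     mode = c("classes", "singletons")) {
  mode <- match.arg(mode)
  cl <- descriptor_classes(table, key)
  if (mode == "classes") length(cl) else sum(lengths(cl) == 1)
}

#' Greedy search for a minimal identifying descriptor set
#'
#' Starting from an empty key, repeatedly adds the candidate component that
#' maximizes the class count (ties broken by candidate order) and stops
#' when the class count stops increasing or every pattern is a singleton.
#'
#' @inheritParams descriptor_classes
#' @param candidates character vector of component names to draw from.
#' @param tol float-comparison tolerance for the resulting key.
#' @return A `descriptor_key` of the selected components.
#' @export
greedy_minimal_set <- function(table, candidates, tol = 1e-6) {
  stopifnot(length(candidates) >= 1)
  chosen <- character(0)
  best_count <- 0L
  n <- length(table$ids)
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (length(remaining) == 0 || best_count == n) break
    counts <- vapply(remaining, function(comp) {
      distinguishability_count(
        table, descriptor_key(c(chosen, comp), tol), "classes")
    }, integer(1))
    if (max(counts) <= best_count) break
    pick <- remaining[which.max(counts)]
    chosen <- c(chosen, pick)
    best_count <- max(counts)
  }
  descriptor_key(chosen, tol)
}

#' Preset descriptor keys (cases A, B, C)
#'
#' Case A uses the chosen energy alone; case B adds reciprocity r and
#' cyclomatic complexity CC; case C further adds the spectrum of the same
#' energy matrix (A for E, L for LE, Q for QE, the product matrix for the
#' generalized energies).
#'
#' @param energy one of [energy_names()].
#' @param case `"A"`, `"B"` or `"C"`.
#' @param tol float-comparison tolerance.
#' @return A [descriptor_key()].
#' @export
identifier_case <- function(energy, case = c("A", "B", "C"), tol = 1e-6) {
  stopifnot(energy %in% energy_names())
  case <- match.arg(case)
  spec_matrix <- switch(energy, E = "A", LE = "L", QE = "Q", energy)
  comps <- switch(case,
                  A = energy,
                  B = c(energy, "r", "CC"),
                  C = c(energy, "r", "CC", paste0("spectrum:", spec_matrix)))
  descriptor_key(comps, tol)
}
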