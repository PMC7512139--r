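---
title: "Dissecting directed molecular networks into canonical subgraph patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting directed molecular networks into canonical subgraph patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsubgraph)
```

## The model

Molecular networks — gene regulation, signal transduction, cellular-process
wiring — are directed graphs in which local wiring patterns (feed-forward
loops, cascades, single- and multiple-input modules) carry much of the
functional meaning.  `netsubgraph` decomposes such a network into its
*N-node subgraphs*: every weakly connected induced subgraph on N nodes,
classified up to isomorphism.  These classes are identical in form to
N-node motifs, but **no randomized background ensemble is used**: every
occurrence counts, whether or not it is statistically over-represented.
The premise is that the subgraphs are building blocks of the network, not
statistical anomalies, and the package therefore reports *which genes* sit
in each occurrence rather than only a z-score per class.

### Canonical pattern ids

A pattern on k nodes is encoded by reading its adjacency matrix row-major
into a binary number whose most-significant bit is entry (1,1); entry
(i,j) = 1 means an edge i→j.  The *canonical id* is the minimum of this
number over all k! node relabelings.  This is the mfinder-style naming
used across the motif literature: id 6 is the single-input module (SIM),
12 the cascade, 36 the multiple-input module (MIM), 38 the feed-forward
loop, 98 the 3-cycle, 238 the complete 3-node digraph.  Patterns are
self-loop-free binary digraphs; mutual dyads are allowed, multi-arcs are
not.  Exhaustive enumeration over all off-diagonal bit assignments gives
2, 13, 199 and 9364 classes for k = 2, 3, 4, 5:

```{r catalog}
length(enumerate_patterns(4)$ids)
```

The k = 5 scan covers 2^20 matrices under 120 permutations; the
canonicalization runs in C++ with per-permutation bit-relabeling tables
and finishes in seconds.  The 6-node catalog (1,530,843 classes) is out of
scope.

## Spectral descriptors

For a pattern with adjacency matrix A, let D be the diagonal matrix of
*total* degrees (in + out), L = D − A the Laplacian and Q = D + A the
signless Laplacian.  Nine energies are computed:

* E = Σ|α~i~| over the eigenvalues of A (moduli when complex);
* LE = Σ|β~i~| − 2e/n over the eigenvalues of L, and QE likewise for Q;
* for M, N ∈ {A, L, Q}: the generalized energies AA^t^, LL^t^, QQ^t^ and
  the asymmetric generalized energies AL^t^, AQ^t^, LQ^t^, each defined as
  Σ√|λ~i~(MN^t^)|, with no 2e/n correction.  When M = N this is the sum
  of the singular values of M.

Two conventions matter and both were fixed by validating against the
reference table of all nine energies for the 13 three-node patterns:
degrees in D must be total degrees (out-degree-only fails the LE column),
and the generalized energies must sum *square roots* of eigenvalue moduli
(summing the moduli themselves fails every asymmetric column).

```{r energies}
round(energy_vector(decode_id(238, 3)), 2)
```

### Numerical choices

Patterns are tiny integer matrices, so spectra are computed from the
*exact integer characteristic polynomial* (Faddeev–LeVerrier), deflating
exact zero roots before calling `polyroot()`; `eigen()` is only a
fallback for non-integer or larger input.  This has two consequences a
generic eigensolver cannot offer: nilpotent patterns (the four DAG
patterns with E = 0) give exactly zero energy, and matrices sharing a
characteristic polynomial — relabelings, and *equienergetic* pattern
pairs such as (6, 36) and (14, 74), which are edge-reversals of each
other — give bit-identical energies.  LAPACK's nonsymmetric solver
carries ~1e−8 noise on defective eigenvalues (Jordan blocks are common in
these products), which would otherwise mask the exact degeneracies.
Spectra are ordered by descending real part, then descending imaginary
part, and compared with tolerance 1e−6; energies in descriptor keys are
compared at 1e−6 on full-precision values.

## Reciprocity, cyclomatic and algorithmic complexity

*Traditional reciprocity* R is the fraction of arcs belonging to mutual
dyads, L^↔^/L.  *Correlation reciprocity* r is the Pearson-style
correlation between mirror off-diagonal entries a~ij~ and a~ji~; it is
negative for pure in/out structure (−0.5 for SIM, cascade and MIM) and 1
for symmetric edge sets.  For the complete digraph the expression is 0/0
and r is defined as 1, the value the reference table prints.  One
discrepancy in that table is documented rather than imitated: it prints
R = 0 for ids 14, 46, 74, 102, 108 and 110 although each contains at
least one mutual dyad (their r values confirm the bidirectional links);
the implementation returns the definitional values 2/3, 1/2, 2/3, 1/2,
1/2 and 4/5.

*Cyclomatic complexity* is CC = e − N + 2P with P the number of exit
(out-degree-zero) nodes.  The exit-node reading of P is the only one
consistent with all 13 printed CC values (CC = 3 for the SIM forces
P = 2; CC = 0 for the sink-free cycles forces P = 0).

*Kolmogorov complexity* is estimated from the row-major bit string by a
block decomposition: the string is cut into blocks (12 bits by default),
and the estimate is the sum over unique blocks of a backend code length
plus log2 of the block multiplicity.  The backend is pluggable; the
default is the code length assigned by a depth-3 context-tree-weighting
mixture with Krichevsky–Trofimov estimators, a universal code that plays
the role of a CTM lookup: regular strings get short codes, random-looking
strings long ones.  With this backend the 13 three-node patterns receive
13 distinct values, the all-zero string is the most compressible 9-bit
string, and the values rank-correlate strongly (Spearman ≈ 0.88) with
published calculator-based estimates.  Two limitations are deliberate:
the absolute values of an external CTM-based calculator are not
reproduced (they depend on its Turing-machine enumeration tables, which
this package does not recompute), and on the 4-node catalog the default
backend separates 174 of 199 patterns — the remaining ties are pairs
whose bit strings have identical context-count statistics at every depth,
which no counting-based code can split.

## Unique identifiers

Several patterns share an energy value (the E = 0 and E = 2 classes are
four-fold; QE takes only three values, each three-fold), so single
descriptors are degenerate labels.  `descriptor_classes()` partitions a
catalog by equality of any combination of energies, r, CC, KC and
spectra; `distinguishability_count()` reports either the number of
classes or the number of fully identified patterns (singletons).  Both
modes are exposed because published counts of "distinguishable
subgraphs" mix the two readings; the verified cells (7 classes under E,
6 under LE, 10 under AA^t^ for k = 3) use the class count, which is the
default.  `greedy_minimal_set()` adds, at each step, the candidate that
maximizes the class count, breaking exact ties by candidate order and
stopping when the count stops increasing — with AL^t^, r, CC and the
AL^t^ spectrum available it fully separates all 13 three-node patterns.
The greedy tie-break and stopping rules are this package's own choices;
exhaustive subset search is intentionally not offered.

## Functional subgraphs and irreducibility

A *functional subgraph* of a pattern is obtained by choosing a node
subset and a subset of the induced edges that spans the subset and stays
weakly connected — the structural/functional distinction used in brain
connectomics.  A pattern with no same-size functional subgraph is
*irreducible*; equivalently (and asserted as a property test) the
irreducible patterns are exactly the minimal-edge tree patterns with
k − 1 edges: {6, 12, 36} for k = 3 and {14, 28, 74, 76, 280, 328, 392,
2184} for k = 4.  These irreducible patterns are precisely the ones that
dominate real pathway censuses.  One published claim does not survive
brute force: of the eight irreducible 4-node patterns, only the pure SIM,
cascade and MIM embed exactly *one* 3-node functional pattern; the five
mixed trees embed exactly two (e.g. pattern 28 = a path feeding a star
embeds both the SIM and the cascade).  The containment tables report the
brute-force-verified sets.

## Entropy, ranks and enrichment

Occurrence counts normalized over the full catalog give a frequency
distribution whose Shannon entropy H (bits, 0·log 0 = 0) measures how
evenly a network uses the pattern vocabulary; the normalized entropy
divides by log2 of the catalog size (13 or 199), so 1 means uniform use
and values well below 1 — typical of pathway networks, whose censuses are
dominated by a handful of tree patterns — mean a biased vocabulary.
Rank comparisons between descriptors use minimum (competition) ranks and
Pearson correlation of the rank vectors, the combination that reproduces
the published rank columns and their Spearman coefficient of 0.083
between CC and KC at the 3-node level.

For gene-set enrichment, the *subgraph module* of a network is the set of
nodes appearing in at least one 3- or 4-node occurrence (membership is
node-level: a gene in many occurrences counts once).  The 2×2 table of
gene-set membership against module membership gives an odds ratio
ad/bc; a pseudo-count (default 1) is added to *all four* cells if and
only if some cell is zero.  The magnitude and all-cells scope of the
correction are configurable because the source procedure states only
that a pseudo-count was used when a cell was empty.  No significance
test is attached, by design.

## The synthetic generator

Real inputs are KEGG-style pathways (≤ ~160 nodes); the package reads
edge lists and a minimal KGML subset (entries + relations; relation
subtypes ignored; `group` entries expanded to components; multi-gene
entries labeled by their first name unless `expand_entries = TRUE` splits
them, a choice exposed as a flag because the upstream convention is not
documented).  For testing without downloads, `random_digraph()` draws
each unordered node pair from a four-outcome categorical distribution
(none / i→j / j→i / mutual) with mutual-dyad probability
m = p² + ρp(1−p), so the expected correlation reciprocity equals the
target ρ — dyad-level sampling is necessary because reciprocity is a
dyad property that independent arcs cannot reach.  Infeasible (p, ρ)
combinations raise an error.  `planted_pattern_network()` builds disjoint
unions of chosen patterns with exact ground truth; optional background
nodes form a matching (disjoint single edges), which cannot create
connected triples.  One caveat is inherent: planting a 4-node pattern
necessarily adds 3-node occurrences (the 4-node MIM contains three 3-node
MIMs), so exact ground truth for a census at size k requires planting
only size-k patterns.

The generator emulates size, density and reciprocity, and nothing else:
it has no degree heterogeneity (no hubs), no modular or hierarchical
organization, and no biological edge semantics.  Passing tests on these
fixtures therefore demonstrate correctness of the counting and
descriptor machinery, not fidelity of any biological conclusion drawn
from real pathways.

## Problem sizes and verification

The ESU (exact subgraph enumeration) census is validated against a plain
brute-force classifier over all C(n,k) subsets on 50 seeded random
networks with n ≤ 12 (all at k = 3, ten at k = 4), against `igraph`'s
independent motif counter on larger instances, and against planted
fixtures; the reciprocity target is checked over 20 replicates at
n = 200, p = 0.05 (mean within three standard errors of ρ = 0.3).  These
sizes make the whole suite run in well under a minute while still
exercising every code path; the census itself handles pathway-scale
networks (hundreds of nodes) comfortably at k = 3 and 4.

## Known limitations

* Catalogs stop at k = 5; censuses are intended for k = 3 and 4.
* The default complexity backend is a universal-code stand-in with the
  k = 4 tie limitation described above; plug in a CTM-table backend for
  exact published values.
* The KGML reader is deliberately minimal and resolves a multi-gene
  entry to its first listed name by default.
* Occurrence storage (`with_nodes = TRUE`) costs one permutation search
  per occurrence; disable it for pure counting.
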