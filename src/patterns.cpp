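#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>

using namespace Rcpp;

// Patterns are binary digraphs on k nodes encoded row-major into a single
// integer: entry (i,j) (0-based) occupies bit k*k - 1 - (k*i + j), so the
// most-significant bit is entry (1,1) and the decimal value is the mfinder
// style pattern id (38 = feed-forward loop, 6 = single-input module, ...).
// k <= 5 keeps ids below 2^25, well inside 32-bit integers.

namespace {

inline int bitpos(int k, int i, int j) { return k * k - 1 - (k * i + j); }

std::vector<std::vector<int> > node_permutations(int k) {
  std::vector<int> p(k);
  for (int i = 0; i < k; ++i) p[i] = i;
  std::vector<std::vector<int> > out;
  do {
    out.push_back(p);
  } while (std::next_permutation(p.begin(), p.end()));
  return out;
}

// per permutation: bit-position relabeling table for off-diagonal entries
std::vector<std::vector<int> > perm_bit_tables(
    int k, const std::vector<std::vector<int> >& perms) {
  std::vector<std::vector<int> > tabs;
  tabs.reserve(perms.size());
  for (size_t pi = 0; pi < perms.size(); ++pi) {
    const std::vector<int>& p = perms[pi];
    std::vector<int> tab(k * k, -1);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (i != j) tab[bitpos(k, i, j)] = bitpos(k, p[i], p[j]);
    tabs.push_back(tab);
  }
  return tabs;
}

inline unsigned int apply_perm(unsigned int id, const std::vector<int>& tab,
                               int nbits) {
  unsigned int out = 0;
  for (int b = 0; b < nbits; ++b)
    if ((id >> b) & 1u) out |= (1u << tab[b]);
  return out;
}

int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

bool weakly_connected_id(unsigned int id, int k) {
  std::vector<int> parent(k);
  for (int i = 0; i < k; ++i) parent[i] = i;
  int comps = k;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      bool linked = ((id >> bitpos(k, i, j)) & 1u) ||
                    ((id >> bitpos(k, j, i)) & 1u);
      if (linked) {
        int ri = find_root(parent, i), rj = find_root(parent, j);
        if (ri != rj) {
          parent[ri] = rj;
          --comps;
        }
      }
    }
  return comps == 1;
}

unsigned int canonical_min(unsigned int id, int k,
                           const std::vector<std::vector<int> >& tabs) {
  unsigned int best = id;
  int nbits = k * k;
  for (size_t t = 1; t < tabs.size(); ++t) {  // tabs[0] is the identity
    unsigned int v = apply_perm(id, tabs[t], nbits);
    if (v < best) best = v;
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
bool cpp_is_weakly_connected(int id, int k) {
  return weakly_connected_id((unsigned int)id, k);
}

// [[Rcpp::export]]
int cpp_canonical_id(int id, int k) {
  std::vector<std::vector<int> > perms = node_permutations(k);
  std::vector<std::vector<int> > tabs = perm_bit_tables(k, perms);
  return (int)canonical_min((unsigned int)id, k, tabs);
}

// Exhaustive scan of all 2^(k(k-1)) off-diagonal bit assignments; keeps the
// weakly connected digraphs whose encoding is already minimal over the k!
// relabelings (one representative per isomorphism class).
// [[Rcpp::export]]
IntegerVector cpp_enumerate_patterns(int k) {
  std::vector<std::vector<int> > perms = node_permutations(k);
  std::vector<std::vector<int> > tabs = perm_bit_tables(k, perms);
  int noff = k * (k - 1);
  std::vector<int> offpos;  // off-diagonal bit positions, MSB first
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) offpos.push_back(bitpos(k, i, j));
  unsigned int total = 1u << noff;
  std::vector<int> keep;
  int nbits = k * k;
  for (unsigned int x = 0; x < total; ++x) {
    unsigned int id = 0;
    for (int b = 0; b < noff; ++b)
      if ((x >> b) & 1u) id |= (1u << offpos[b]);
    if (!weakly_connected_id(id, k)) continue;
    bool minimal = true;
    for (size_t t = 1; t < tabs.size(); ++t) {
      if (apply_perm(id, tabs[t], nbits) < id) {
        minimal = false;
        break;
      }
    }
    if (minimal) keep.push_back((int)id);
  }
  std::sort(keep.begin(), keep.end());
  return wrap(keep);
}

// All canonical ids of weakly connected spanning edge-subset subgraphs on
// k_sub-node subsets of the pattern `id` (functional subgraphs in the
// Sporns-Koetter sense).  When k_sub == k the pattern itself is excluded.
// [[Rcpp::export]]
IntegerVector cpp_functional_subgraphs(int id, int k, int k_sub) {
  std::vector<std::vector<int> > perms = node_permutations(k_sub);
  std::vector<std::vector<int> > tabs = perm_bit_tables(k_sub, perms);
  std::set<int> found;

  // iterate over node subsets of size k_sub via combination masks
  std::vector<int> comb(k_sub);
  for (int i = 0; i < k_sub; ++i) comb[i] = i;
  bool more = true;
  while (more) {
    // edges of the induced subgraph, re-encoded on k_sub nodes
    std::vector<int> edge_bits;
    for (int a = 0; a < k_sub; ++a)
      for (int b = 0; b < k_sub; ++b) {
        if (a == b) continue;
        if ((((unsigned int)id) >> bitpos(k, comb[a], comb[b])) & 1u)
          edge_bits.push_back(bitpos(k_sub, a, b));
      }
    int ne = (int)edge_bits.size();
    if (ne > 0 && ne <= 25) {
      unsigned int full = 0;
      for (int b = 0; b < ne; ++b) full |= (1u << edge_bits[b]);
      for (unsigned int mask = 1; mask < (1u << ne); ++mask) {
        unsigned int sub = 0;
        for (int b = 0; b < ne; ++b)
          if ((mask >> b) & 1u) sub |= (1u << edge_bits[b]);
        if (k_sub == k && sub == full && (int)__builtin_popcount(mask) == ne) {
          // proper containment only: skip the pattern's own full edge set
          if (full == (unsigned int)id) continue;
        }
        if (!weakly_connected_id(sub, k_sub)) continue;
        int canon = (int)canonical_min(sub, k_sub, tabs);
        if (k_sub == k && canon == cpp_canonical_id(id, k)) continue;
        found.insert(canon);
      }
    }
    // next combination
    int pos = k_sub - 1;
    while (pos >= 0 && comb[pos] == k - k_sub + pos) --pos;
    if (pos < 0) {
      more = false;
    } else {
      ++comb[pos];
      for (int q = pos + 1; q < k_sub; ++q) comb[q] = comb[q - 1] + 1;
    }
  }
  return wrap(std::vector<int>(found.begin(), found.end()));
}
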