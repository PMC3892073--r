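// Graph primitives behind the screening fingerprint and the substructure
// verifier. Atom codes arrive pre-combined from R (element, formal charge,
// aromatic flag); bond codes are 1,2,3 and 4 for aromatic.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Adj {
  std::vector<std::vector<std::pair<int, int>>> nb; // (neighbour, bond code)
  explicit Adj(int n) : nb(n) {}
};

Adj build_adj(int n, const IntegerMatrix& edges, const IntegerVector& bond) {
  Adj a(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    a.nb[u].push_back(std::make_pair(v, bond[e]));
    a.nb[v].push_back(std::make_pair(u, bond[e]));
  }
  return a;
}

uint64_t fnv1a(const std::vector<int>& seq) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < seq.size(); ++i) {
    uint32_t v = (uint32_t)seq[i];
    for (int b = 0; b < 4; ++b) {
      h ^= (v >> (8 * b)) & 0xFFu;
      h *= 1099511628211ULL;
    }
  }
  return h;
}

// direction-invariant hash of a linear path: the smaller of the forward and
// reverse encodings, so a path contributes the same bit from either end
uint64_t path_hash(const std::vector<int>& atoms, const std::vector<int>& bonds) {
  std::vector<int> fwd, rev;
  size_t n = atoms.size();
  for (size_t i = 0; i < n; ++i) {
    fwd.push_back(atoms[i]);
    if (i + 1 < n) fwd.push_back(bonds[i]);
  }
  for (size_t i = n; i-- > 0;) {
    rev.push_back(atoms[i]);
    if (i > 0) rev.push_back(bonds[i - 1]);
  }
  uint64_t hf = fnv1a(fwd), hr = fnv1a(rev);
  return hf < hr ? hf : hr;
}

} // namespace

// Enumerate all simple linear paths of 1..max_len atoms and set the
// direction-invariant hash bit for each. Returns 0-based bit indices.
// [[Rcpp::export]]
IntegerVector cr_path_bits(IntegerVector atom_code, IntegerMatrix edges,
                           IntegerVector bond_code, int max_len, int nbits) {
  int n = atom_code.size();
  std::set<int> bits;
  if (n == 0) return IntegerVector(0);
  Adj adj = build_adj(n, edges, bond_code);

  std::vector<char> visited(n, 0);
  std::vector<int> patoms, pbonds;

  // iterative DFS with explicit stack of (atom, next-neighbour-index)
  for (int start = 0; start < n; ++start) {
    std::vector<std::pair<int, size_t>> stack;
    std::fill(visited.begin(), visited.end(), 0);
    patoms.clear();
    pbonds.clear();
    visited[start] = 1;
    patoms.push_back(atom_code[start]);
    bits.insert((int)(path_hash(patoms, pbonds) % (uint64_t)nbits));
    stack.push_back(std::make_pair(start, (size_t)0));
    while (!stack.empty()) {
      int cur = stack.back().first;
      size_t& idx = stack.back().second;
      const std::vector<std::pair<int, int>>& nb = adj.nb[cur];
      bool advanced = false;
      while (idx < nb.size()) {
        int nxt = nb[idx].first;
        int bc = nb[idx].second;
        ++idx;
        if (visited[nxt]) continue;
        if ((int)patoms.size() >= max_len) break;
        visited[nxt] = 1;
        patoms.push_back(atom_code[nxt]);
        pbonds.push_back(bc);
        bits.insert((int)(path_hash(patoms, pbonds) % (uint64_t)nbits));
        stack.push_back(std::make_pair(nxt, (size_t)0));
        advanced = true;
        break;
      }
      if (!advanced) {
        stack.pop_back();
        if (!stack.empty()) {
          visited[cur] = 0;
          patoms.pop_back();
          pbonds.pop_back();
        }
      }
    }
  }
  return IntegerVector(bits.begin(), bits.end());
}

// Subgraph monomorphism: does the query embed into the target with equal
// atom codes and equal bond codes on every query bond (extra target bonds
// are allowed)? Returns the 1-based target indices of one embedding, in
// query atom order, or integer(0).
// [[Rcpp::export]]
IntegerVector cr_subgraph_match(IntegerVector q_atom, IntegerMatrix q_edges,
                                IntegerVector q_bond, IntegerVector t_atom,
                                IntegerMatrix t_edges, IntegerVector t_bond) {
  int nq = q_atom.size(), nt = t_atom.size();
  if (nq == 0) return IntegerVector(0);
  if (nq > nt) return IntegerVector(0);
  Adj qa = build_adj(nq, q_edges, q_bond);
  Adj ta = build_adj(nt, t_edges, t_bond);

  // order query atoms so each (where possible) touches an earlier one:
  // BFS over components
  std::vector<int> order;
  std::vector<int> pos(nq, -1);
  {
    std::vector<char> seen(nq, 0);
    for (int root = 0; root < nq; ++root) {
      if (seen[root]) continue;
      std::vector<int> queue;
      queue.push_back(root);
      seen[root] = 1;
      size_t head = 0;
      while (head < queue.size()) {
        int u = queue[head++];
        pos[u] = (int)order.size();
        order.push_back(u);
        for (size_t k = 0; k < qa.nb[u].size(); ++k) {
          int v = qa.nb[u][k].first;
          if (!seen[v]) {
            seen[v] = 1;
            queue.push_back(v);
          }
        }
      }
    }
  }

  // for each query atom (in order) the already-placed neighbours
  std::vector<std::vector<std::pair<int, int>>> back(nq); // (earlier q atom, bond)
  for (int i = 0; i < nq; ++i) {
    int u = order[i];
    for (size_t k = 0; k < qa.nb[u].size(); ++k) {
      int v = qa.nb[u][k].first;
      if (pos[v] < i) back[i].push_back(std::make_pair(v, qa.nb[u][k].second));
    }
  }

  std::vector<int> map(nq, -1);       // query atom -> target atom
  std::vector<char> used(nt, 0);
  std::vector<int> cand_idx(nq, 0);

  int depth = 0;
  std::vector<std::vector<int>> cands(nq);
  while (depth >= 0) {
    if (depth == nq) {
      IntegerVector out(nq);
      for (int i = 0; i < nq; ++i) out[i] = map[i] + 1;
      return out;
    }
    int u = order[depth];
    if (cand_idx[depth] == 0) {
      // build candidate list for this depth
      std::vector<int>& cl = cands[depth];
      cl.clear();
      if (!back[depth].empty()) {
        int anchor_q = back[depth][0].first;
        int anchor_t = map[anchor_q];
        for (size_t k = 0; k < ta.nb[anchor_t].size(); ++k)
          cl.push_back(ta.nb[anchor_t][k].first);
      } else {
        for (int t = 0; t < nt; ++t) cl.push_back(t);
      }
    }
    bool placed = false;
    std::vector<int>& cl = cands[depth];
    while (cand_idx[depth] < (int)cl.size()) {
      int t = cl[cand_idx[depth]++];
      if (used[t]) continue;
      if (t_atom[t] != q_atom[u]) continue;
      if (ta.nb[t].size() < qa.nb[u].size()) continue;
      bool ok = true;
      for (size_t k = 0; k < back[depth].size() && ok; ++k) {
        int qv = back[depth][k].first, bc = back[depth][k].second;
        int tv = map[qv];
        bool found = false;
        for (size_t j = 0; j < ta.nb[t].size(); ++j) {
          if (ta.nb[t][j].first == tv && ta.nb[t][j].second == bc) {
            found = true;
            break;
          }
        }
        if (!found) ok = false;
      }
      if (!ok) continue;
      map[u] = t;
      used[t] = 1;
      placed = true;
      break;
    }
    if (placed) {
      ++depth;
      if (depth < nq) cand_idx[depth] = 0;
    } else {
      cand_idx[depth] = 0;
      --depth;
      if (depth >= 0) {
        int pu = order[depth];
        used[map[pu]] = 0;
        map[pu] = -1;
      }
    }
  }
  return IntegerVector(0);
}
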