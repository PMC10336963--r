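// Canonical atom ranking and canonical SMILES assembly for small
// heavy-atom graphs (C/N/O/F, valence <= 4). Morgan-style iterative
// refinement; residual tied classes are resolved by branching over every
// class member and keeping the lexicographically smallest completed string,
// so the output is invariant under atom reindexing.

#include <Rcpp.h>
#include <array>
#include <algorithm>
#include <set>
#include <string>
#include <vector>

namespace {

struct Graph {
  int n;
  std::vector<int> el;    // 0:C 1:N 2:O 3:F
  std::vector<int> h;     // implicit H count
  std::vector<int> deg;
  std::vector<int> bsum;  // sum of bond orders
  std::vector<std::array<int, 4>> nbr, ord, eid;
  std::vector<int> bi, bj, bo;  // bonds, 0-based
};

const char* ELSYM[4] = {"C", "N", "O", "F"};
const char* BONDSYM[4] = {"", "", "=", "#"};

Graph build_graph(const Rcpp::IntegerVector& el, const Rcpp::IntegerVector& h,
                  const Rcpp::IntegerMatrix& bonds) {
  Graph g;
  g.n = el.size();
  g.el.assign(el.begin(), el.end());
  g.h.assign(h.begin(), h.end());
  g.deg.assign(g.n, 0);
  g.bsum.assign(g.n, 0);
  g.nbr.assign(g.n, {0, 0, 0, 0});
  g.ord.assign(g.n, {0, 0, 0, 0});
  g.eid.assign(g.n, {0, 0, 0, 0});
  int nb = bonds.nrow();
  for (int k = 0; k < nb; ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1, o = bonds(k, 2);
    if (g.deg[i] >= 4 || g.deg[j] >= 4) Rcpp::stop("degree exceeds 4");
    g.nbr[i][g.deg[i]] = j; g.ord[i][g.deg[i]] = o; g.eid[i][g.deg[i]] = k;
    g.deg[i]++;
    g.nbr[j][g.deg[j]] = i; g.ord[j][g.deg[j]] = o; g.eid[j][g.deg[j]] = k;
    g.deg[j]++;
    g.bsum[i] += o; g.bsum[j] += o;
    g.bi.push_back(i); g.bj.push_back(j); g.bo.push_back(o);
  }
  return g;
}

int relabel(std::vector<long long>& key, std::vector<int>& ranks) {
  int n = (int)key.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return key[a] < key[b]; });
  int r = 0;
  for (int k = 0; k < n; ++k) {
    if (k > 0 && key[idx[k]] != key[idx[k - 1]]) ++r;
    ranks[idx[k]] = r;
  }
  return r + 1;
}

int ndistinct(const std::vector<int>& ranks) {
  std::vector<int> s(ranks);
  std::sort(s.begin(), s.end());
  return (int)(std::unique(s.begin(), s.end()) - s.begin());
}

void refine(const Graph& g, std::vector<int>& ranks) {
  int n = g.n;
  std::vector<long long> key(n);
  int nd = ndistinct(ranks);
  for (;;) {
    for (int i = 0; i < n; ++i) {
      std::array<long long, 4> c = {0, 0, 0, 0};
      for (int k = 0; k < g.deg[i]; ++k)
        c[k] = (long long)g.ord[i][k] * (4 * n + 8) + ranks[g.nbr[i][k]];
      std::sort(c.begin(), c.end(), std::greater<long long>());
      long long base = (long long)4 * (4 * n + 8);
      long long v = ranks[i];
      for (int k = 0; k < 4; ++k) v = v * base + c[k];
      key[i] = v;
    }
    std::vector<int> newranks(n);
    int nd2 = relabel(key, newranks);
    ranks.swap(newranks);
    if (nd2 == nd) return;
    nd = nd2;
  }
}

struct Writer {
  const Graph* g;
  const std::vector<int>* ranks;
  std::vector<int> visited, parent_edge;
  std::vector<std::vector<int>> children, child_order;
  std::vector<std::vector<std::pair<int, int>>> ring_at;  // (digit, order)
  std::vector<char> edge_used;
  int ring_count;
  std::vector<std::array<int, 3>> ring_edges;  // a, b, order

  void dfs(int v) {
    int d = g->deg[v];
    std::array<int, 4> ks = {0, 1, 2, 3};
    std::sort(ks.begin(), ks.begin() + d, [&](int a, int b) {
      return (*ranks)[g->nbr[v][a]] < (*ranks)[g->nbr[v][b]];
    });
    for (int t = 0; t < d; ++t) {
      int k = ks[t];
      int u = g->nbr[v][k], o = g->ord[v][k], e = g->eid[v][k];
      if (edge_used[e]) continue;
      edge_used[e] = 1;
      if (!visited[u]) {
        visited[u] = 1;
        children[v].push_back(u);
        child_order[v].push_back(o);
        dfs(u);
      } else {
        ring_edges.push_back({v, u, o});
      }
    }
  }

  void emit(int v, std::string& out) {
    out += ELSYM[g->el[v]];
    for (auto& rd : ring_at[v]) {
      out += BONDSYM[rd.second];
      out += (char)('0' + rd.first);
    }
    int nc = (int)children[v].size();
    for (int k = 0; k < nc; ++k) {
      if (k < nc - 1) {
        out += '(';
        out += BONDSYM[child_order[v][k]];
        emit(children[v][k], out);
        out += ')';
      } else {
        out += BONDSYM[child_order[v][k]];
        emit(children[v][k], out);
      }
    }
  }
};

std::string smiles_from_ranks(const Graph& g, const std::vector<int>& ranks) {
  int root = 0;
  for (int i = 1; i < g.n; ++i)
    if (ranks[i] < ranks[root]) root = i;
  Writer w;
  w.g = &g;
  w.ranks = &ranks;
  w.visited.assign(g.n, 0);
  w.children.assign(g.n, {});
  w.child_order.assign(g.n, {});
  w.ring_at.assign(g.n, {});
  w.edge_used.assign(g.bi.size(), 0);
  w.visited[root] = 1;
  w.dfs(root);
  if (w.ring_edges.size() > 9)
    Rcpp::stop("more than 9 simultaneous ring closures are not supported");
  for (size_t d = 0; d < w.ring_edges.size(); ++d) {
    auto& e = w.ring_edges[d];
    w.ring_at[e[0]].push_back({(int)d + 1, e[2]});
    w.ring_at[e[1]].push_back({(int)d + 1, e[2]});
  }
  std::string out;
  w.emit(root, out);
  return out;
}

std::string canon_recurse(const Graph& g, const std::vector<int>& ranks) {
  if (ndistinct(ranks) == g.n) return smiles_from_ranks(g, ranks);
  // smallest rank value that is duplicated
  std::vector<int> count(g.n, 0);
  for (int r : ranks) count[r]++;
  int tied = -1;
  for (int r = 0; r < g.n; ++r)
    if (count[r] > 1) { tied = r; break; }
  std::string best;
  bool have = false;
  for (int a = 0; a < g.n; ++a) {
    if (ranks[a] != tied) continue;
    std::vector<int> r2(g.n);
    for (int i = 0; i < g.n; ++i) r2[i] = ranks[i] * 2;
    r2[a] -= 1;
    refine(g, r2);
    std::string s = canon_recurse(g, r2);
    if (!have || s < best) { best = s; have = true; }
  }
  return best;
}

std::string canon_of_graph(const Graph& g) {
  std::vector<long long> key(g.n);
  for (int i = 0; i < g.n; ++i)
    key[i] = (((long long)g.el[i] * 8 + g.h[i]) * 8 + g.deg[i]) * 16 +
             g.bsum[i];
  std::vector<int> ranks(g.n);
  relabel(key, ranks);
  refine(g, ranks);
  return canon_recurse(g, ranks);
}

const int VALENCE_OF[4] = {4, 3, 2, 1};

int sample_index(const std::vector<double>& cumprob) {
  double u = unif_rand();
  for (size_t k = 0; k < cumprob.size(); ++k)
    if (u <= cumprob[k]) return (int)k;
  return (int)cumprob.size() - 1;
}

// seeded random growth: attach atoms to free-valence sites (bond orders
// weighted toward single bonds), then up to two ring-closure attempts
Graph grow_molecule(int max_heavy, const std::vector<int>& els,
                    const std::vector<double>& el_cum,
                    const std::vector<double>& size_cum, double ring_prob) {
  int m = sample_index(size_cum) + 1;
  Graph g;
  g.n = 0;
  const double order_w[3] = {0.85, 0.12, 0.03};
  std::vector<int> free_val;
  int first = els[sample_index(el_cum)];
  g.el.push_back(first);
  free_val.push_back(VALENCE_OF[first]);
  g.n = 1;
  while (g.n < m) {
    std::vector<int> open;
    for (int i = 0; i < g.n; ++i)
      if (free_val[i] > 0) open.push_back(i);
    if (open.empty()) break;
    int parent = open[(int)(unif_rand() * open.size()) % open.size()];
    int el = els[sample_index(el_cum)];
    int maxo = std::min(3, std::min(free_val[parent], VALENCE_OF[el]));
    int o = 1;
    if (maxo > 1) {
      double tot = 0;
      for (int k = 0; k < maxo; ++k) tot += order_w[k];
      double u = unif_rand() * tot, acc = 0;
      for (int k = 0; k < maxo; ++k) {
        acc += order_w[k];
        if (u <= acc) { o = k + 1; break; }
      }
    }
    g.el.push_back(el);
    free_val.push_back(VALENCE_OF[el] - o);
    free_val[parent] -= o;
    g.bi.push_back(parent); g.bj.push_back(g.n); g.bo.push_back(o);
    g.n++;
  }
  for (int t = 0; t < 2; ++t) {
    if (unif_rand() >= ring_prob) continue;
    std::vector<int> open;
    for (int i = 0; i < g.n; ++i)
      if (free_val[i] > 0) open.push_back(i);
    if (open.size() < 2) continue;
    int a = open[(int)(unif_rand() * open.size()) % open.size()];
    int b = a;
    while (b == a) b = open[(int)(unif_rand() * open.size()) % open.size()];
    if (a > b) std::swap(a, b);
    bool adjacent = false;
    for (size_t k = 0; k < g.bi.size(); ++k)
      if ((g.bi[k] == a && g.bj[k] == b) || (g.bi[k] == b && g.bj[k] == a))
        adjacent = true;
    if (adjacent) continue;
    g.bi.push_back(a); g.bj.push_back(b); g.bo.push_back(1);
    free_val[a] -= 1; free_val[b] -= 1;
  }
  // finalize degrees / H counts / adjacency
  g.h.assign(g.n, 0);
  g.deg.assign(g.n, 0);
  g.bsum.assign(g.n, 0);
  g.nbr.assign(g.n, {0, 0, 0, 0});
  g.ord.assign(g.n, {0, 0, 0, 0});
  g.eid.assign(g.n, {0, 0, 0, 0});
  for (size_t k = 0; k < g.bi.size(); ++k) {
    int i = g.bi[k], j = g.bj[k], o = g.bo[k];
    g.nbr[i][g.deg[i]] = j; g.ord[i][g.deg[i]] = o; g.eid[i][g.deg[i]] = (int)k;
    g.deg[i]++;
    g.nbr[j][g.deg[j]] = i; g.ord[j][g.deg[j]] = o; g.eid[j][g.deg[j]] = (int)k;
    g.deg[j]++;
    g.bsum[i] += o; g.bsum[j] += o;
  }
  for (int i = 0; i < g.n; ++i) g.h[i] = VALENCE_OF[g.el[i]] - g.bsum[i];
  return g;
}

long long poly_hash_str(const std::string& s) {
  long long h = 0;
  for (unsigned char c : s) h = (h * 31 + c) % 2147483647LL;
  return h;
}

// environment strings per atom, radii 0..radius (matches the documented
// radius-0 invariant: element / H count / degree)
std::vector<std::string> env_strings(const Graph& g, int radius) {
  std::vector<std::string> prev(g.n), out;
  for (int i = 0; i < g.n; ++i)
    prev[i] = std::string(ELSYM[g.el[i]]) + "/H" + std::to_string(g.h[i]) +
              "/D" + std::to_string(g.deg[i]);
  std::vector<std::string> r0 = prev;
  out.insert(out.end(), prev.begin(), prev.end());
  for (int r = 1; r <= radius; ++r) {
    std::vector<std::string> cur(g.n);
    for (int i = 0; i < g.n; ++i) {
      std::vector<std::string> toks;
      for (int k = 0; k < g.deg[i]; ++k)
        toks.push_back(std::to_string(g.ord[i][k]) + "~" + prev[g.nbr[i][k]]);
      std::sort(toks.begin(), toks.end());
      std::string s = r0[i] + "(";
      for (size_t k = 0; k < toks.size(); ++k) {
        if (k) s += ",";
        s += toks[k];
      }
      s += ")";
      cur[i] = s;
    }
    out.insert(out.end(), cur.begin(), cur.end());
    prev.swap(cur);
  }
  return out;
}

std::vector<std::string> group_keys_of(const Graph& g) {
  std::vector<std::string> keys(g.n);
  for (int i = 0; i < g.n; ++i) {
    std::vector<std::string> toks;
    for (int k = 0; k < g.deg[i]; ++k)
      toks.push_back(std::to_string(g.ord[i][k]) + ELSYM[g.el[g.nbr[i][k]]]);
    std::sort(toks.begin(), toks.end());
    std::string s = std::string(ELSYM[g.el[i]]) + ";H" +
                    std::to_string(g.h[i]) + ";";
    for (size_t k = 0; k < toks.size(); ++k) {
      if (k) s += "+";
      s += toks[k];
    }
    keys[i] = s;
  }
  return keys;
}

}  // namespace

// [[Rcpp::export]]
std::string canonical_smiles_cpp(Rcpp::IntegerVector el, Rcpp::IntegerVector h,
                                 Rcpp::IntegerMatrix bonds) {
  Graph g = build_graph(el, h, bonds);
  return canon_of_graph(g);
}

// [[Rcpp::export]]
Rcpp::CharacterVector group_keys_cpp(Rcpp::IntegerVector el,
                                     Rcpp::IntegerVector h,
                                     Rcpp::IntegerMatrix bonds) {
  Graph g = build_graph(el, h, bonds);
  std::vector<std::string> keys = group_keys_of(g);
  return Rcpp::wrap(keys);
}

// [[Rcpp::export]]
Rcpp::IntegerVector fp_fold_cpp(Rcpp::IntegerVector el, Rcpp::IntegerVector h,
                                Rcpp::IntegerMatrix bonds, int radius,
                                int nbits) {
  Graph g = build_graph(el, h, bonds);
  std::vector<std::string> envs = env_strings(g, radius);
  Rcpp::IntegerVector counts(nbits);
  for (auto& e : envs) counts[(int)(poly_hash_str(e) % nbits)]++;
  return counts;
}

// Generate `n` unique molecules (dedup by canonical SMILES). Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
Rcpp::List generate_pool_cpp(int n, int max_heavy, Rcpp::IntegerVector els,
                             Rcpp::NumericVector el_prob,
                             Rcpp::NumericVector size_prob, double ring_prob,
                             int max_tries) {
  std::vector<int> elv(els.begin(), els.end());
  std::vector<double> el_cum(el_prob.size()), size_cum(size_prob.size());
  double acc = 0;
  for (int k = 0; k < el_prob.size(); ++k) {
    acc += el_prob[k];
    el_cum[k] = acc;
  }
  acc = 0;
  for (int k = 0; k < size_prob.size(); ++k) {
    acc += size_prob[k];
    size_cum[k] = acc;
  }
  std::set<std::string> seen;
  Rcpp::List out(n);
  int got = 0, tries = 0;
  while (got < n && tries < max_tries) {
    ++tries;
    Graph g = grow_molecule(max_heavy, elv, el_cum, size_cum, ring_prob);
    std::string smi = canon_of_graph(g);
    if (!seen.insert(smi).second) continue;
    Rcpp::IntegerMatrix bonds((int)g.bi.size(), 3);
    for (size_t k = 0; k < g.bi.size(); ++k) {
      bonds(k, 0) = g.bi[k] + 1;
      bonds(k, 1) = g.bj[k] + 1;
      bonds(k, 2) = g.bo[k];
    }
    out[got++] = Rcpp::List::create(
        Rcpp::Named("element") = Rcpp::wrap(g.el),
        Rcpp::Named("hcount") = Rcpp::wrap(g.h),
        Rcpp::Named("bonds") = bonds, Rcpp::Named("smiles") = smi);
  }
  if (got < n)
    Rcpp::stop("could only generate %d of %d unique molecules", got, n);
  return out;
}
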