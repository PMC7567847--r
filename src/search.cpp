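// BDeu scoring and greedy structure search over discrete data.
//
// States are 0-based integers; column j takes values in 0..arity[j]-1.
// Family scores are cached per (child, sorted parent set) so repeated
// hill-climbing sweeps cost a hash lookup rather than a pass over the data.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static double family_logscore(const IntegerMatrix& S, const IntegerVector& arity,
                              int child, const std::vector<int>& pa, double ess) {
  const int n = S.nrow();
  const int r = arity[child];
  long q = 1;
  for (size_t t = 0; t < pa.size(); ++t) q *= arity[pa[t]];
  std::vector<double> njk(static_cast<size_t>(q) * r, 0.0);
  std::vector<double> nj(q, 0.0);
  for (int i = 0; i < n; ++i) {
    long idx = 0;
    for (size_t t = 0; t < pa.size(); ++t) idx = idx * arity[pa[t]] + S(i, pa[t]);
    njk[static_cast<size_t>(idx) * r + S(i, child)] += 1.0;
    nj[idx] += 1.0;
  }
  const double ajk = ess / (static_cast<double>(q) * r);
  const double aj  = ess / static_cast<double>(q);
  double score = 0.0;
  for (long j = 0; j < q; ++j) {
    if (nj[j] == 0.0) continue;  // unobserved configurations contribute 0
    score += std::lgamma(aj) - std::lgamma(aj + nj[j]);
    for (int k = 0; k < r; ++k) {
      const double c = njk[static_cast<size_t>(j) * r + k];
      if (c > 0.0) score += std::lgamma(ajk + c) - std::lgamma(ajk);
    }
  }
  return score;
}

// key = child then sorted parents, base-64 digits (node index < 63)
static uint64_t family_key(int child, const std::vector<int>& sorted_pa) {
  uint64_t key = static_cast<uint64_t>(child + 1);
  for (size_t t = 0; t < sorted_pa.size(); ++t)
    key = key * 64u + static_cast<uint64_t>(sorted_pa[t] + 1);
  return key;
}

// [[Rcpp::export]]
double cpp_bde_score(IntegerMatrix states, IntegerVector arity, List parent_list,
                     double ess) {
  const int p = states.ncol();
  double total = 0.0;
  for (int v = 0; v < p; ++v) {
    IntegerVector pa0 = parent_list[v];  // 0-based
    std::vector<int> pa(pa0.begin(), pa0.end());
    total += family_logscore(states, arity, v, pa, ess);
  }
  return total;
}

namespace {

struct Searcher {
  const IntegerMatrix& S;
  const IntegerVector& arity;
  const LogicalMatrix& allowed;
  int p, max_parents;
  double ess;
  std::vector<std::vector<bool> > adj;           // adj[u][v]: edge u -> v
  std::vector<std::vector<int> > parents;        // sorted parent sets
  std::vector<double> fam;                       // current family scores
  std::unordered_map<uint64_t, double> cache;
  long proposals;

  Searcher(const IntegerMatrix& S_, const IntegerVector& arity_,
           const LogicalMatrix& allowed_, int max_parents_, double ess_)
    : S(S_), arity(arity_), allowed(allowed_), p(S_.ncol()),
      max_parents(max_parents_), ess(ess_), proposals(0) {
    reset();
  }

  void reset() {
    adj.assign(p, std::vector<bool>(p, false));
    parents.assign(p, std::vector<int>());
    fam.assign(p, 0.0);
    for (int v = 0; v < p; ++v) fam[v] = score_family(v, parents[v]);
  }

  double score_family(int child, const std::vector<int>& pa) {
    const uint64_t key = family_key(child, pa);
    std::unordered_map<uint64_t, double>::iterator it = cache.find(key);
    if (it != cache.end()) return it->second;
    const double s = family_logscore(S, arity, child, pa, ess);
    cache[key] = s;
    return s;
  }

  double total_score() const {
    double s = 0.0;
    for (int v = 0; v < p; ++v) s += fam[v];
    return s;
  }

  bool has_path(int from, int to) const {
    if (from == to) return true;
    std::vector<bool> seen(p, false);
    std::vector<int> stack(1, from);
    seen[from] = true;
    while (!stack.empty()) {
      const int u = stack.back(); stack.pop_back();
      for (int v = 0; v < p; ++v) {
        if (adj[u][v] && !seen[v]) {
          if (v == to) return true;
          seen[v] = true;
          stack.push_back(v);
        }
      }
    }
    return false;
  }

  static std::vector<int> with(const std::vector<int>& pa, int add) {
    std::vector<int> out(pa);
    out.insert(std::lower_bound(out.begin(), out.end(), add), add);
    return out;
  }
  static std::vector<int> without(const std::vector<int>& pa, int drop) {
    std::vector<int> out;
    for (size_t t = 0; t < pa.size(); ++t) if (pa[t] != drop) out.push_back(pa[t]);
    return out;
  }

  void add_edge(int u, int v) {
    adj[u][v] = true;
    parents[v] = with(parents[v], u);
    fam[v] = score_family(v, parents[v]);
  }
  void drop_edge(int u, int v) {
    adj[u][v] = false;
    parents[v] = without(parents[v], u);
    fam[v] = score_family(v, parents[v]);
  }

  // one steepest-ascent sweep; returns true if a move was applied
  bool sweep() {
    const double eps = 1e-10;
    double best_delta = eps;
    int best_u = -1, best_v = -1, best_type = -1;
    for (int u = 0; u < p; ++u) {
      for (int v = 0; v < p; ++v) {
        if (u == v) continue;
        // add u -> v
        if (!adj[u][v] && !adj[v][u] && allowed(u, v) &&
            static_cast<int>(parents[v].size()) < max_parents && !has_path(v, u)) {
          ++proposals;
          const double d = score_family(v, with(parents[v], u)) - fam[v];
          if (d > best_delta) { best_delta = d; best_u = u; best_v = v; best_type = 0; }
        }
        // delete u -> v
        if (adj[u][v]) {
          ++proposals;
          const double d = score_family(v, without(parents[v], u)) - fam[v];
          if (d > best_delta) { best_delta = d; best_u = u; best_v = v; best_type = 1; }
        }
        // reverse u -> v (becomes v -> u)
        if (adj[u][v] && static_cast<int>(parents[u].size()) < max_parents) {
          adj[u][v] = false;
          const bool cyclic = has_path(u, v);
          adj[u][v] = true;
          if (!cyclic) {
            ++proposals;
            const double d =
              (score_family(v, without(parents[v], u)) - fam[v]) +
              (score_family(u, with(parents[u], v)) - fam[u]);
            if (d > best_delta) { best_delta = d; best_u = u; best_v = v; best_type = 2; }
          }
        }
      }
    }
    if (best_type < 0) return false;
    if (best_type == 0) add_edge(best_u, best_v);
    else if (best_type == 1) drop_edge(best_u, best_v);
    else { drop_edge(best_u, best_v); add_edge(best_v, best_u); }
    return true;
  }

  // random legal DAG: each ordered pair visited in random order, edge
  // attempted with probability init_prob, cycles and caps rejected
  void random_restart(double init_prob) {
    reset();
    const int npairs = p * (p - 1);
    std::vector<int> us(npairs), vs(npairs);
    int t = 0;
    for (int u = 0; u < p; ++u)
      for (int v = 0; v < p; ++v)
        if (u != v) { us[t] = u; vs[t] = v; ++t; }
    for (int i = npairs - 1; i > 0; --i) {  // Fisher-Yates on R's RNG stream
      const int j = static_cast<int>(std::floor(unif_rand() * (i + 1)));
      std::swap(us[i], us[j]); std::swap(vs[i], vs[j]);
    }
    for (int i = 0; i < npairs; ++i) {
      const int u = us[i], v = vs[i];
      if (unif_rand() >= init_prob) continue;
      if (!allowed(u, v) || adj[u][v] || adj[v][u]) continue;
      if (static_cast<int>(parents[v].size()) >= max_parents) continue;
      if (has_path(v, u)) continue;
      add_edge(u, v);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_greedy_search(IntegerMatrix states, IntegerVector arity,
                       LogicalMatrix allowed, int max_parents, int n_restarts,
                       double budget, double ess, double init_prob) {
  Searcher s(states, arity, allowed, max_parents, ess);
  // the empty DAG is always a candidate answer
  std::vector<std::vector<int> > best_parents(s.parents);
  double best_score = s.total_score();
  int restarts_run = 0;
  for (int r = 0; r < n_restarts; ++r) {
    if (r == 0) s.reset(); else s.random_restart(init_prob);
    ++restarts_run;
    while (s.sweep()) {
      if (static_cast<double>(s.proposals) >= budget) break;
    }
    if (s.total_score() > best_score) {
      best_score = s.total_score();
      best_parents = s.parents;
    }
    if (static_cast<double>(s.proposals) >= budget) break;
  }
  const int p = states.ncol();
  List out_parents(p);
  for (int v = 0; v < p; ++v) {
    IntegerVector pv(best_parents[v].begin(), best_parents[v].end());
    out_parents[v] = pv + 1;  // 1-based for R
  }
  return List::create(_["parents"] = out_parents,
                      _["score"] = best_score,
                      _["proposals"] = static_cast<double>(s.proposals),
                      _["restarts"] = restarts_run);
}
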