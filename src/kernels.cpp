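#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Number of sequences within strict identity threshold of each sequence
// (self included). codes: B x N integer matrix.
// [[Rcpp::export]]
IntegerVector identity_neighbor_counts(const IntegerMatrix& codes,
                                       double threshold) {
  const int B = codes.nrow(), N = codes.ncol();
  IntegerVector cnt(B, 1);  // self always counts
  // row-major copy for cache-friendly pairwise scans
  std::vector<int> rows((size_t)B * N);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < N; ++j) rows[(size_t)b * N + j] = codes(b, j);
  const double cut = threshold * N;
  for (int a = 0; a < B; ++a) {
    const int* ra = &rows[(size_t)a * N];
    for (int b = a + 1; b < B; ++b) {
      const int* rb = &rows[(size_t)b * N];
      int m = 0;
      for (int j = 0; j < N; ++j) m += (ra[j] == rb[j]);
      if ((double)m > cut) { ++cnt[a]; ++cnt[b]; }
    }
  }
  return cnt;
}

// ---- lattice enumeration ---------------------------------------------------

namespace {

struct Enumerator {
  int edge, n;
  std::vector<std::vector<int>> nb;      // lattice adjacency
  std::vector<std::vector<int>> sym;     // 48 cell-index maps
  std::vector<int> orbit_min;            // min image of a cell over symmetries
  std::vector<std::vector<int>> kept;    // canonical representatives
  std::vector<int> path;
  std::vector<char> used;
  long long n_directed = 0;

  int cell(int x, int y, int z) const { return x + edge * (y + edge * z); }

  explicit Enumerator(int e) : edge(e), n(e * e * e), nb(n), used(n, 0) {
    for (int x = 0; x < edge; ++x)
      for (int y = 0; y < edge; ++y)
        for (int z = 0; z < edge; ++z) {
          int c = cell(x, y, z);
          if (x > 0) nb[c].push_back(cell(x - 1, y, z));
          if (x < edge - 1) nb[c].push_back(cell(x + 1, y, z));
          if (y > 0) nb[c].push_back(cell(x, y - 1, z));
          if (y < edge - 1) nb[c].push_back(cell(x, y + 1, z));
          if (z > 0) nb[c].push_back(cell(x, y, z - 1));
          if (z < edge - 1) nb[c].push_back(cell(x, y, z + 1));
        }
    static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                    {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
    for (int p = 0; p < 6; ++p)
      for (int r = 0; r < 8; ++r) {
        std::vector<int> map(n);
        for (int x = 0; x < edge; ++x)
          for (int y = 0; y < edge; ++y)
            for (int z = 0; z < edge; ++z) {
              int co[3] = {x, y, z}, t[3];
              for (int k = 0; k < 3; ++k) {
                t[k] = co[perms[p][k]];
                if ((r >> k) & 1) t[k] = edge - 1 - t[k];
              }
              map[cell(x, y, z)] = cell(t[0], t[1], t[2]);
            }
        sym.push_back(map);
      }
    orbit_min.assign(n, n);
    for (int c = 0; c < n; ++c)
      for (int s = 0; s < 48; ++s)
        orbit_min[c] = std::min(orbit_min[c], sym[s][c]);
  }

  // A directed path is kept iff it equals the lexicographically smallest
  // image of its equivalence class under the 48 cube symmetries — exactly
  // one directed path per class satisfies this. A chain and its reverse are
  // distinct conformations (contact energies depend on sequence direction),
  // so reversal is not quotiented. Early-exit comparisons make the test
  // cheap; a start-cell orbit filter rejects most paths immediately.
  void record() {
    ++n_directed;
    if (path.front() != orbit_min[path.front()]) return;
    for (int s = 0; s < 48; ++s) {
      const std::vector<int>& mp = sym[s];
      for (int k = 0; k < n; ++k) {
        int v = mp[path[k]];
        if (v < path[k]) return;   // a strictly smaller variant exists
        if (v > path[k]) break;    // this variant cannot beat the path
      }
    }
    kept.push_back(path);
  }

  void dfs(int c, int depth) {
    used[c] = 1;
    path.push_back(c);
    if (depth == n) {
      record();
    } else {
      for (int nxt : nb[c])
        if (!used[nxt]) dfs(nxt, depth + 1);
    }
    path.pop_back();
    used[c] = 0;
  }

  void run() {
    for (int c = 0; c < n; ++c) dfs(c, 1);
  }
};

}  // namespace

// All Hamiltonian self-avoiding walks on the edge^3 cube, deduplicated
// under the 48 cube symmetries (reversal kept distinct), in deterministic
// (lexicographic canonical) order. Returns an S x n matrix of 0-based cell indices; the
// total directed-path count is attached as attribute "n_directed" for
// cross-checking against independent enumerators.
// [[Rcpp::export]]
IntegerMatrix enumerate_saw_cpp(int edge) {
  if (edge < 2 || edge > 3) stop("cube_edge must be 2 or 3");
  Enumerator en(edge);
  en.run();
  const int n = en.n;
  std::sort(en.kept.begin(), en.kept.end());
  IntegerMatrix out(en.kept.size(), n);
  for (size_t r = 0; r < en.kept.size(); ++r)
    for (int k = 0; k < n; ++k) out(r, k) = en.kept[r][k];
  out.attr("n_directed") = (double)en.n_directed;
  return out;
}

// Contact energies of one sequence on every structure.
// seq: 1-based residue codes (length n); ci, cj: S x K matrices of 1-based
// sequence positions in contact; table: 20 x 20 symmetric energy matrix.
// [[Rcpp::export]]
NumericVector fold_energies_cpp(const IntegerVector& seq,
                                const IntegerMatrix& ci,
                                const IntegerMatrix& cj,
                                const NumericMatrix& table) {
  const int S = ci.nrow(), K = ci.ncol(), q = table.nrow();
  // row-major contact lists for cache-friendly per-structure scans
  std::vector<int> rci((size_t)S * K), rcj((size_t)S * K);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) {
      rci[(size_t)s * K + k] = ci(s, k) - 1;
      rcj[(size_t)s * K + k] = cj(s, k) - 1;
    }
  const double* tb = REAL(table);
  NumericVector E(S);
  for (int s = 0; s < S; ++s) {
    const int* a = &rci[(size_t)s * K];
    const int* b = &rcj[(size_t)s * K];
    double e = 0;
    for (int k = 0; k < K; ++k) e += tb[(seq[a[k]] - 1) + q * (seq[b[k]] - 1)];
    E[s] = e;
  }
  return E;
}

static double logsumexp_neg(const std::vector<double>& E) {
  // log sum_s exp(-E_s)
  double m = -E[0];
  for (size_t s = 1; s < E.size(); ++s) m = std::max(m, -E[s]);
  double acc = 0;
  for (size_t s = 0; s < E.size(); ++s) acc += std::exp(-E[s] - m);
  return m + std::log(acc);
}

// Metropolis sequence design targeting pnat^beta for a chosen native fold.
// Single-site substitution proposals uniform over the 19 alternative
// residues; beta annealed linearly from beta0 to beta1 over the burn-in
// sweeps, then held at beta1. After burn-in the current sequence is recorded
// every `stride` sweeps provided its exact (full-ensemble) pnat exceeds
// pnat_min, until n_samples are collected (or a proposal budget is
// exhausted).
//
// Cost control: the Metropolis target evaluates the fold-probability
// denominator over an adaptive active set of the `active_size` lowest-energy
// competitor structures (plus the native), refreshed every `refresh_every`
// sweeps by an exact recomputation of every structure energy; structures
// outside the active set are exponentially suppressed and contribute
// negligibly between refreshes. Recorded sequences are always scored with
// the exact log-sum-exp over the complete ensemble. Uses R's RNG.
// [[Rcpp::export]]
List design_mcmc_cpp(const IntegerMatrix& ci, const IntegerMatrix& cj,
                     int native, const NumericMatrix& table,
                     IntegerVector seq0, int n_samples, double pnat_min,
                     int stride, int burnin, double beta0, double beta1,
                     double max_sweep_factor, int active_size = 2000,
                     int refresh_every = 5, int reheat_after = 300) {
  const int S = ci.nrow(), K = ci.ncol(), n = seq0.size(), q = table.nrow();
  std::vector<int> seq(n);
  for (int i = 0; i < n; ++i) seq[i] = seq0[i] - 1;  // 0-based residues
  // row-major 0-based contact lists: full-energy passes are cache-friendly
  std::vector<int> rci((size_t)S * K), rcj((size_t)S * K);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) {
      rci[(size_t)s * K + k] = ci(s, k) - 1;
      rcj[(size_t)s * K + k] = cj(s, k) - 1;
    }
  const double* tb = REAL(table);
  std::vector<double> E(S);
  auto recompute_all = [&]() {
    for (int s = 0; s < S; ++s) {
      const int* a = &rci[(size_t)s * K];
      const int* b = &rcj[(size_t)s * K];
      double e = 0;
      for (int k = 0; k < K; ++k) e += tb[seq[a[k]] + q * seq[b[k]]];
      E[s] = e;
    }
  };
  recompute_all();

  const int L = std::min(active_size, S - 1);
  std::vector<int> active;                       // structure ids, native first
  // per-site incidence restricted to the active set:
  // (active-slot, partner-site) pairs
  std::vector<std::vector<std::pair<int, int>>> act_inc(n);
  std::vector<double> Eact, Eact_new;
  auto refresh_active = [&]() {
    recompute_all();
    std::vector<int> ids(S);
    for (int s = 0; s < S; ++s) ids[s] = s;
    ids.erase(ids.begin() + native);
    if ((int)ids.size() > L) {
      std::nth_element(ids.begin(), ids.begin() + L, ids.end(),
                       [&](int a, int b) { return E[a] < E[b]; });
      ids.resize(L);
    }
    active.clear();
    active.push_back(native);
    active.insert(active.end(), ids.begin(), ids.end());
    Eact.resize(active.size());
    for (size_t t = 0; t < active.size(); ++t) Eact[t] = E[active[t]];
    for (int k = 0; k < n; ++k) act_inc[k].clear();
    for (size_t t = 0; t < active.size(); ++t) {
      int s = active[t];
      for (int k = 0; k < K; ++k) {
        int a = rci[(size_t)s * K + k], b = rcj[(size_t)s * K + k];
        act_inc[a].push_back({(int)t, b});
        act_inc[b].push_back({(int)t, a});
      }
    }
  };
  refresh_active();
  auto act_logpnat = [&]() {
    double m = -Eact[0];
    for (size_t t = 1; t < Eact.size(); ++t) m = std::max(m, -Eact[t]);
    double acc = 0;
    for (size_t t = 0; t < Eact.size(); ++t) acc += std::exp(-Eact[t] - m);
    return -Eact[0] - (m + std::log(acc));
  };
  double logpnat = act_logpnat();

  IntegerMatrix samples(n_samples, n);
  NumericVector pnats(n_samples);
  int got = 0;
  long long accepted = 0, proposed = 0;
  const long long max_sweeps =
      (long long)((burnin + (double)n_samples * stride) * max_sweep_factor);
  long long sweep = 0;
  // annealing restarts: if the chain froze below the retention threshold
  // (no sample for `reheat_after` sweeps), re-anneal from beta0
  long long ramp_start = 0, last_success = 0;
  Eact_new.resize(Eact.size());
  while (got < n_samples && sweep < max_sweeps) {
    ++sweep;
    double beta =
        sweep <= ramp_start + burnin
            ? beta0 + (beta1 - beta0) *
                  ((double)(sweep - ramp_start) / (double)burnin)
            : beta1;
    for (int rep = 0; rep < n; ++rep) {
      ++proposed;
      int site = (int)(unif_rand() * n);
      if (site >= n) site = n - 1;
      int old = seq[site];
      int prop = (int)(unif_rand() * (q - 1));
      if (prop >= q - 1) prop = q - 2;
      if (prop >= old) ++prop;
      Eact_new = Eact;
      for (const auto& pr : act_inc[site]) {
        Eact_new[pr.first] +=
            tb[prop + q * seq[pr.second]] - tb[old + q * seq[pr.second]];
      }
      double m = -Eact_new[0];
      for (size_t t = 1; t < Eact_new.size(); ++t)
        m = std::max(m, -Eact_new[t]);
      double acc = 0;
      for (size_t t = 0; t < Eact_new.size(); ++t)
        acc += std::exp(-Eact_new[t] - m);
      double logpnat_new = -Eact_new[0] - (m + std::log(acc));
      double dlog = beta * (logpnat_new - logpnat);
      if (dlog >= 0 || unif_rand() < std::exp(dlog)) {
        seq[site] = prop;
        Eact.swap(Eact_new);
        logpnat = logpnat_new;
        ++accepted;
      }
    }
    if (sweep % refresh_every == 0) {
      refresh_active();
      logpnat = act_logpnat();
    }
    if (sweep > burnin && ((sweep - burnin) % stride == 0)) {
      recompute_all();
      double exact_lp = -E[native] - logsumexp_neg(E);
      if (exact_lp > std::log(pnat_min)) {
        for (int i = 0; i < n; ++i) samples(got, i) = seq[i] + 1;
        pnats[got] = std::exp(exact_lp);
        ++got;
        last_success = sweep;
      }
    }
    if (reheat_after > 0 &&
        sweep - std::max(last_success, ramp_start + burnin) >
            (long long)reheat_after) {
      ramp_start = sweep;
    }
  }
  return List::create(_["samples"] = samples, _["pnat"] = pnats,
                      _["n_collected"] = got, _["accept_rate"] =
                          (double)accepted / (double)proposed,
                      _["sweeps"] = (double)sweep);
}
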