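// Core simulation engine: synchronous threshold dynamics on binary gene
// states, population-level evolution, and degree-preserving edge switching.
// All randomness is drawn from R's RNG so set.seed() in R governs every draw.
//
// States are bitmasks (bit i set <=> gene i active), which caps N at 31;
// the study's networks have N = 10-16.

#include <Rcpp.h>
#include <cstdint>
#include <memory>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const int MAX_N = 31;

// ---------------------------------------------------------------------------
// genotype representation

struct Geno {
  int N;
  std::vector<double> g;      // column-major, g[i + N*j] = g_ij (j regulates i)
  std::vector<double> theta;  // 0.5 * row sum
  std::vector<int> nreg;      // nonzero entries per row
  long id;                    // cache key component, unique within a run
};

typedef std::shared_ptr<const Geno> GenoPtr;

static GenoPtr geno_from_matrix(const NumericMatrix& m, long id) {
  int N = m.nrow();
  if (m.ncol() != N) stop("genotype matrix must be square");
  if (N < 1 || N > MAX_N) stop("engine supports 1 <= N <= 31 genes");
  auto G = std::make_shared<Geno>();
  G->N = N;
  G->id = id;
  G->g.assign(m.begin(), m.end());
  G->theta.assign(N, 0.0);
  G->nreg.assign(N, 0);
  for (int i = 0; i < N; ++i) {
    double rs = 0.0;
    int nr = 0;
    for (int j = 0; j < N; ++j) {
      double v = G->g[i + N * j];
      if (v != 0.0) { rs += v; ++nr; }
    }
    G->theta[i] = 0.5 * rs;
    G->nreg[i] = nr;
  }
  return G;
}

static NumericMatrix geno_to_matrix(const Geno& G) {
  NumericMatrix m(G.N, G.N);
  std::copy(G.g.begin(), G.g.end(), m.begin());
  return m;
}

// ---------------------------------------------------------------------------
// dynamics

static inline uint32_t step_state(const Geno& G, uint32_t s, bool theta_zero) {
  const int N = G.N;
  uint32_t out = 0;
  for (int i = 0; i < N; ++i) {
    double sum = 0.0;
    for (uint32_t m = s; m; m &= m - 1) {
      int j = __builtin_ctz(m);
      sum += G.g[i + N * j];
    }
    double x = sum - (theta_zero ? 0.0 : G.theta[i]);
    uint32_t bit;
    if (x > 0.0) bit = 1u;
    else if (x < 0.0) bit = 0u;
    else bit = (s >> i) & 1u;  // exact tie holds the current state
    out |= bit << i;
  }
  return out;
}

// Iterate until a previously visited state recurs; fill `cycle` with the
// attractor states in dynamical order starting at the first-reached one.
static int develop_state(const Geno& G, uint32_t s0, bool theta_zero,
                         std::vector<uint32_t>& cycle) {
  std::vector<uint32_t> seq;
  std::unordered_map<uint32_t, int> pos;
  uint32_t s = s0;
  size_t cap = (G.N >= 31) ? 0x80000001u : ((1u << G.N) + 1u);
  while (true) {
    auto it = pos.find(s);
    if (it != pos.end()) {
      cycle.assign(seq.begin() + it->second, seq.end());
      return it->second;  // transient length
    }
    pos.emplace(s, (int)seq.size());
    seq.push_back(s);
    if (seq.size() > cap)
      stop("internal error: dynamics failed to recur within 2^N + 1 steps");
    s = step_state(G, s, theta_zero);
  }
}

static inline int popcount32(uint32_t x) { return __builtin_popcount(x); }

// mean Hamming distance between target and the attractor's cycle states
static double attractor_distance(const std::vector<uint32_t>& cycle,
                                 uint32_t target) {
  double acc = 0.0;
  for (uint32_t s : cycle) acc += popcount32(s ^ target);
  return acc / (double)cycle.size();
}

// ---------------------------------------------------------------------------
// attractor cache: (genotype id, initial state) -> cycle states

struct AttrCache {
  std::unordered_map<uint64_t, std::vector<uint32_t>> map;
  bool enabled;
  const std::vector<uint32_t>& get(const Geno& G, uint32_t s0, bool theta_zero,
                                   std::vector<uint32_t>& scratch) {
    if (!enabled) {
      scratch.clear();
      develop_state(G, s0, theta_zero, scratch);
      return scratch;
    }
    uint64_t key = ((uint64_t)(uint32_t)G.id << 32) | s0;
    auto it = map.find(key);
    if (it != map.end()) return it->second;
    if (map.size() > 4000000) map.clear();  // memory safety valve
    std::vector<uint32_t> cyc;
    develop_state(G, s0, theta_zero, cyc);
    return map.emplace(key, std::move(cyc)).first->second;
  }
};

// ---------------------------------------------------------------------------
// perturbed initial states: Binomial(N, kappa) flips at distinct uniform
// positions (identical in distribution to independent per-bit flips)

static inline uint32_t perturb_bits(uint32_t s, int N, double kappa) {
  if (kappa <= 0.0) return s;
  int flips = (int)R::rbinom((double)N, kappa);
  if (flips == 0) return s;
  uint32_t mask = 0;
  while (popcount32(mask) < flips) {
    int p = (int)(unif_rand() * N);
    if (p >= N) p = N - 1;
    mask |= (1u << p);
  }
  return s ^ mask;
}

// ---------------------------------------------------------------------------
// fitness

struct Stage {
  std::vector<uint32_t> targets;
  std::vector<int> cells;
  int generations;
  double gamma;
  double kappa;
};

static double organism_fitness_engine(const Geno& G, const Stage& st, double S,
                                      bool theta_zero, AttrCache& cache,
                                      const std::vector<double>& powtab) {
  std::vector<uint32_t> scratch;
  double w = 1.0;
  for (size_t t = 0; t < st.targets.size(); ++t) {
    uint32_t target = st.targets[t];
    int K = st.cells[t];
    double acc = 0.0;
    for (int c = 0; c < K; ++c) {
      uint32_t s0 = perturb_bits(target, G.N, st.kappa);
      const std::vector<uint32_t>& cyc = cache.get(G, s0, theta_zero, scratch);
      double D = attractor_distance(cyc, target);
      double Di;
      if (cyc.size() == 1)
        acc += powtab[(int)D];
      else if (std::modf(D, &Di) == 0.0 && Di >= 0 && Di <= G.N)
        acc += powtab[(int)Di];
      else
        acc += std::pow(1.0 - S, D);
    }
    w *= acc / (double)K;
  }
  return w;
}

// ---------------------------------------------------------------------------
// mutation (variant 0 = biased, 1 = unbiased, 2 = continuous-weight)

enum MutEvent { MUT_NONE, MUT_LOSS, MUT_GAIN, MUT_REDRAW };

// Decide the (mutually exclusive) mutation event for one gene; consumes
// exactly one uniform draw (plus one more for the unbiased gain/loss coin).
static MutEvent decide_event(int R, int N, double mu, double gamma,
                             int variant) {
  double u = unif_rand();
  if (variant == 1) {
    if (u >= mu) return MUT_NONE;
    bool gain = unif_rand() < 0.5;
    if (gain) return (R < N) ? MUT_GAIN : MUT_NONE;
    return (R > 0) ? MUT_LOSS : MUT_NONE;
  }
  double ploss = mu * (1.0 - gamma) * R / (double)N;
  double pgain = mu * gamma * (N - R) / (double)N;
  if (u < ploss) return MUT_LOSS;
  if (u < ploss + pgain) return MUT_GAIN;
  if (variant == 2 && u < ploss + pgain + mu * gamma * R / (double)N)
    return MUT_REDRAW;
  return MUT_NONE;
}

static void apply_event(Geno& G, int i, MutEvent ev, int variant) {
  const int N = G.N;
  int R = G.nreg[i];
  if (ev == MUT_LOSS && R > 0) {
    int pick = (int)(unif_rand() * R);
    if (pick >= R) pick = R - 1;
    for (int j = 0, seen = 0; j < N; ++j) {
      double& v = G.g[i + N * j];
      if (v != 0.0 && seen++ == pick) { v = 0.0; break; }
    }
    G.nreg[i]--;
  } else if (ev == MUT_GAIN && R < N) {
    int Z = N - R;
    int pick = (int)(unif_rand() * Z);
    if (pick >= Z) pick = Z - 1;
    double w = (variant == 2) ? norm_rand()
                              : ((unif_rand() < 0.5) ? 1.0 : -1.0);
    if (w == 0.0) w = 1.0;  // astronomically unlikely in continuous mode
    for (int j = 0, seen = 0; j < N; ++j) {
      double& v = G.g[i + N * j];
      if (v == 0.0 && seen++ == pick) { v = w; break; }
    }
    G.nreg[i]++;
  } else if (ev == MUT_REDRAW && R > 0) {
    int pick = (int)(unif_rand() * R);
    if (pick >= R) pick = R - 1;
    for (int j = 0, seen = 0; j < N; ++j) {
      double& v = G.g[i + N * j];
      if (v != 0.0 && seen++ == pick) {
        double x = std::fabs(norm_rand());
        v = (v > 0) ? x : -x;  // sign forced to the pre-mutation sign
        break;
      }
    }
  } else {
    return;  // no change; threshold untouched
  }
  double rs = 0.0;
  for (int j = 0; j < N; ++j) rs += G.g[i + N * j];
  G.theta[i] = 0.5 * rs;
}

// Returns the (possibly shared) genotype after mutation; clones lazily so
// unmutated offspring keep sharing their parent's matrix and cache id.
static GenoPtr mutate_geno(const GenoPtr& parent, double mu, double gamma,
                           int variant, long& next_id) {
  const int N = parent->N;
  std::shared_ptr<Geno> mine;
  for (int i = 0; i < N; ++i) {
    int R = (mine ? mine->nreg[i] : parent->nreg[i]);
    MutEvent ev = decide_event(R, N, mu, gamma, variant);
    if (ev == MUT_NONE) continue;
    if (!mine) {
      mine = std::make_shared<Geno>(*parent);
      mine->id = next_id++;
    }
    apply_event(*mine, i, ev, variant);
  }
  return mine ? GenoPtr(mine) : parent;
}

static int count_interactions(const Geno& G) {
  int L = 0;
  for (int i = 0; i < G.N; ++i) L += G.nreg[i];
  return L;
}

// ---------------------------------------------------------------------------
// exported: single-step / develop / mutate for the R-level wrappers

// [[Rcpp::export]]
IntegerVector cpp_step(NumericMatrix g, IntegerVector state, bool theta_zero) {
  GenoPtr G = geno_from_matrix(g, 0);
  if ((int)state.size() != G->N) stop("state length must equal the network size");
  uint32_t s = 0;
  for (int i = 0; i < G->N; ++i)
    if (state[i] != 0) s |= (1u << i);
  uint32_t out = step_state(*G, s, theta_zero);
  IntegerVector res(G->N);
  for (int i = 0; i < G->N; ++i) res[i] = (out >> i) & 1u;
  return res;
}

// [[Rcpp::export]]
List cpp_develop(NumericMatrix g, IntegerVector state, bool theta_zero) {
  GenoPtr G = geno_from_matrix(g, 0);
  if ((int)state.size() != G->N) stop("state length must equal the network size");
  uint32_t s = 0;
  for (int i = 0; i < G->N; ++i)
    if (state[i] != 0) s |= (1u << i);
  std::vector<uint32_t> cyc;
  int transient = develop_state(*G, s, theta_zero, cyc);
  IntegerMatrix states((int)cyc.size(), G->N);
  for (int k = 0; k < (int)cyc.size(); ++k)
    for (int i = 0; i < G->N; ++i)
      states(k, i) = (cyc[k] >> i) & 1u;
  return List::create(_["states"] = states, _["period"] = (int)cyc.size(),
                      _["transient"] = transient);
}

// [[Rcpp::export]]
NumericMatrix cpp_mutate(NumericMatrix g, double mu, double gamma, int variant) {
  GenoPtr G = geno_from_matrix(g, 0);
  Geno work(*G);
  for (int i = 0; i < work.N; ++i) {
    MutEvent ev = decide_event(work.nreg[i], work.N, mu, gamma, variant);
    apply_event(work, i, ev, variant);
  }
  return geno_to_matrix(work);
}

// ---------------------------------------------------------------------------
// exported: population run

// [[Rcpp::export]]
List cpp_run_population(NumericMatrix founder, List stages, double mu, double S,
                        int M, int variant, bool theta_zero, bool use_cache) {
  if (M < 1) stop("population size must be at least 1");
  long next_id = 1;
  GenoPtr F = geno_from_matrix(founder, 0);
  const int N = F->N;

  std::vector<Stage> st;
  int total_gens = 0;
  for (int k = 0; k < stages.size(); ++k) {
    List sk = stages[k];
    IntegerMatrix tg = sk["targets"];
    IntegerVector cells = sk["cells"];
    if (tg.ncol() != N) stop("target length must equal the founder's N");
    if (tg.nrow() != cells.size()) stop("one cell count per target required");
    Stage s;
    for (int t = 0; t < tg.nrow(); ++t) {
      uint32_t x = 0;
      for (int i = 0; i < N; ++i)
        if (tg(t, i) != 0) x |= (1u << i);
      s.targets.push_back(x);
      s.cells.push_back(cells[t]);
    }
    s.generations = as<int>(sk["generations"]);
    s.gamma = as<double>(sk["gamma"]);
    s.kappa = as<double>(sk["kappa"]);
    st.push_back(s);
    total_gens += s.generations;
  }

  std::vector<double> powtab(N + 1);
  for (int d = 0; d <= N; ++d) powtab[d] = std::pow(1.0 - S, (double)d);

  AttrCache cache;
  cache.enabled = use_cache;

  std::vector<GenoPtr> pop(M, F), next(M);
  std::vector<double> fit(M), cum(M);

  IntegerVector tr_gen(total_gens), tr_stage(total_gens);
  NumericVector tr_max(total_gens), tr_mean(total_gens), tr_int(total_gens);
  List snapshots(st.size());

  int g_abs = 0;
  for (size_t sidx = 0; sidx < st.size(); ++sidx) {
    const Stage& stage = st[sidx];
    for (int gen = 0; gen < stage.generations; ++gen, ++g_abs) {
      double fmax = 0.0, fsum = 0.0;
      long isum = 0;
      for (int m = 0; m < M; ++m) {
        fit[m] = organism_fitness_engine(*pop[m], stage, S, theta_zero, cache,
                                         powtab);
        if (fit[m] > fmax) fmax = fit[m];
        fsum += fit[m];
        isum += count_interactions(*pop[m]);
      }
      tr_gen[g_abs] = g_abs + 1;
      tr_stage[g_abs] = (int)sidx + 1;
      tr_max[g_abs] = fmax;
      tr_mean[g_abs] = fsum / M;
      tr_int[g_abs] = (double)isum / M;
      if (fsum <= 0.0) stop("all fitness values are zero; selection undefined");
      // roulette-wheel selection: M draws with replacement, P(i) ~ fitness
      double acc = 0.0;
      for (int m = 0; m < M; ++m) { acc += fit[m]; cum[m] = acc; }
      for (int m = 0; m < M; ++m) {
        double u = unif_rand() * acc;
        int lo = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (lo >= M) lo = M - 1;
        next[m] = pop[lo];
      }
      // mutation, every offspring
      for (int m = 0; m < M; ++m)
        next[m] = mutate_geno(next[m], mu, stage.gamma, variant, next_id);
      pop.swap(next);
      if ((g_abs & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    // stage-end snapshot: evaluate the resulting population once more
    NumericVector sfit(M);
    IntegerVector sint(M);
    List sgeno(M);
    for (int m = 0; m < M; ++m) {
      sfit[m] = organism_fitness_engine(*pop[m], stage, S, theta_zero, cache,
                                        powtab);
      sint[m] = count_interactions(*pop[m]);
      sgeno[m] = geno_to_matrix(*pop[m]);
    }
    snapshots[sidx] = List::create(_["fitness"] = sfit,
                                   _["n_interactions"] = sint,
                                   _["genotypes"] = sgeno);
  }

  DataFrame trace = DataFrame::create(
      _["generation"] = tr_gen, _["stage"] = tr_stage, _["max_fitness"] = tr_max,
      _["mean_fitness"] = tr_mean, _["mean_interactions"] = tr_int);
  return List::create(_["trace"] = trace, _["stage_end"] = snapshots);
}

// ---------------------------------------------------------------------------
// exported: degree-preserving edge switching and its Q_P null ensemble

static inline uint64_t ekey(int s, int t, int n) {
  return (uint64_t)s * (uint64_t)n + (uint64_t)t;
}

// edges: 0-based src/tgt vectors, modified in place
static void switch_edges(std::vector<int>& src, std::vector<int>& tgt, int n,
                         int n_attempts) {
  const int L = (int)src.size();
  std::unordered_set<uint64_t> have;
  have.reserve(L * 2);
  std::vector<int> pool;  // indices of non-self-loop edges (swappable)
  for (int e = 0; e < L; ++e) {
    have.insert(ekey(src[e], tgt[e], n));
    if (src[e] != tgt[e]) pool.push_back(e);
  }
  const int np = (int)pool.size();
  if (np < 2) return;
  for (int a = 0; a < n_attempts; ++a) {
    int i1 = pool[(int)(unif_rand() * np) % np];
    int i2 = pool[(int)(unif_rand() * np) % np];
    if (i1 == i2) continue;
    int sa = src[i1], ta = tgt[i1], sc = src[i2], tc = tgt[i2];
    if (sa == tc || sc == ta) continue;  // would create a self-loop
    if (have.count(ekey(sa, tc, n)) || have.count(ekey(sc, ta, n))) continue;
    have.erase(ekey(sa, ta, n));
    have.erase(ekey(sc, tc, n));
    have.insert(ekey(sa, tc, n));
    have.insert(ekey(sc, ta, n));
    tgt[i1] = tc;
    tgt[i2] = ta;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_switch_randomize(IntegerMatrix edges, int n_nodes,
                                   int n_attempts) {
  const int L = edges.nrow();
  std::vector<int> src(L), tgt(L);
  for (int e = 0; e < L; ++e) {
    src[e] = edges(e, 0) - 1;
    tgt[e] = edges(e, 1) - 1;
  }
  switch_edges(src, tgt, n_nodes, n_attempts);
  IntegerMatrix out(L, 2);
  for (int e = 0; e < L; ++e) {
    out(e, 0) = src[e] + 1;
    out(e, 1) = tgt[e] + 1;
  }
  return out;
}

static double qscore_edges(const std::vector<int>& src,
                           const std::vector<int>& tgt,
                           const std::vector<int>& memb, int K) {
  const int L = (int)src.size();
  std::vector<double> din(K, 0.0), dout(K, 0.0);
  long internal = 0;
  for (int e = 0; e < L; ++e) {
    int ms = memb[src[e]], mt = memb[tgt[e]];
    dout[ms] += 1.0;
    din[mt] += 1.0;
    if (ms == mt) ++internal;
  }
  double q = (double)internal / L;
  for (int k = 0; k < K; ++k) q -= din[k] * dout[k] / ((double)L * L);
  return q;
}

// Q_P of n_rand independent switching randomizations of `edges`
// [[Rcpp::export]]
NumericVector cpp_null_qp(IntegerMatrix edges, int n_nodes,
                          IntegerVector membership, int n_rand,
                          int n_attempts) {
  const int L = edges.nrow();
  if ((int)membership.size() != n_nodes)
    stop("membership must assign every node");
  std::vector<int> memb(n_nodes);
  int K = 0;
  for (int i = 0; i < n_nodes; ++i) {
    memb[i] = membership[i] - 1;
    if (memb[i] < 0) stop("module ids must be positive");
    if (memb[i] + 1 > K) K = memb[i] + 1;
  }
  std::vector<int> src0(L), tgt0(L);
  for (int e = 0; e < L; ++e) {
    src0[e] = edges(e, 0) - 1;
    tgt0[e] = edges(e, 1) - 1;
  }
  NumericVector out(n_rand);
  std::vector<int> src, tgt;
  for (int r = 0; r < n_rand; ++r) {
    src = src0;
    tgt = tgt0;
    switch_edges(src, tgt, n_nodes, n_attempts);
    out[r] = qscore_edges(src, tgt, memb, K);
  }
  return out;
}
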