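// Structured-coalescent engine for dated (heterochronous) samples on a deme
// graph, with piecewise-constant deme size K(t), per-lineage migration at
// rate m (destination uniform over adjacent demes), and range-expansion
// events: at each deme's colonization time an instantaneous founder
// bottleneck (pair-coalescence probability x) followed by forced migration
// of the remaining lineages into a source deme.
//
// Times are in ky BP and increase backwards into the past. K is the mean
// pairwise within-deme coalescence time, so the pair rate is 1/K.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// -- deterministic, portable RNG (xoshiro256++, seeded via splitmix64) ------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
    // warm-up: decorrelates the first outputs of generators created from
    // consecutive seeds (splitmix-seeded states are close in hamming terms)
    for (int i = 0; i < 8; ++i) next();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  inline double rexp(double rate) { return -std::log(unif_pos()) / rate; }
  inline int unif_int(int n) {           // uniform on 0..n-1, n small
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// -- simulation state -------------------------------------------------------

struct Lin {
  int node;      // node id (0-based; tips 0..n-1, internal n..2n-2)
  int deme;
  int grp[4];    // tip counts per summary-statistic group in this clade
};

// index of unordered group pair (g <= h) in the 10-entry sum vector:
// within 0..3 -> 0..3; (0,1)=4 (0,2)=5 (0,3)=6 (1,2)=7 (1,3)=8 (2,3)=9
static const int PAIR_IDX[4][4] = {
  {0, 4, 5, 6},
  {4, 1, 7, 8},
  {5, 7, 2, 9},
  {6, 8, 9, 3}
};

struct SimOut {
  std::vector<double> mrec;  // n-1 rows x 5: child1, child2, parent, time, deme (0-based ids)
  double sums[10];
  bool capped;
  int n_merges;
};

struct SimInput {
  int n_demes;
  std::vector< std::vector<int> > adj;
  std::vector<int> sdeme;            // per sample
  std::vector<double> sage;
  std::vector<int> sgrp;             // 0..3
  std::vector<int> act_order;        // sample indices sorted by (age, index)
  std::vector<double> bounds;        // epoch boundaries, ascending (may be empty)
  std::vector< std::vector<int> > sources;  // per deme, colonization sources
  double time_cap;
};

static void merge_pair(std::vector<Lin> &L, int i, int j, double t, int deme,
                       int &next_node, SimOut &out) {
  // order children deterministically by node id
  int c1 = L[i].node, c2 = L[j].node;
  if (c1 > c2) std::swap(c1, c2);
  for (int g = 0; g < 4; ++g)
    for (int h = g; h < 4; ++h) {
      double p = (g == h) ? (double)L[i].grp[g] * L[j].grp[g]
                          : (double)L[i].grp[g] * L[j].grp[h] +
                            (double)L[i].grp[h] * L[j].grp[g];
      if (p > 0) out.sums[PAIR_IDX[g][h]] += t * p;
    }
  int parent = next_node++;
  size_t r = 5 * (size_t)out.n_merges;
  out.mrec[r] = c1; out.mrec[r + 1] = c2; out.mrec[r + 2] = parent;
  out.mrec[r + 3] = t; out.mrec[r + 4] = deme;
  out.n_merges++;
  // merged lineage replaces slot i; remove slot j by swap-pop
  L[i].node = parent;
  for (int g = 0; g < 4; ++g) L[i].grp[g] += L[j].grp[g];
  L[j] = L.back();
  L.pop_back();
}

// founder bottleneck: instantaneous Kingman burst of intensity tau=-log(1-x),
// run among the lineages currently in deme d, all merges dated at time t.
static void bottleneck_burst(std::vector<Lin> &L, int d, double x, double t,
                             int &next_node, SimOut &out, Xoshiro &rng) {
  if (x <= 0.0) return;
  double tau = (x >= 1.0) ? R_PosInf : -std::log1p(-x);
  double used = 0.0;
  // lineage indices are refreshed after each merge because merge_pair
  // swap-pops the active vector
  while (true) {
    std::vector<int> idx;
    for (int i = 0; i < (int)L.size(); ++i)
      if (L[i].deme == d) idx.push_back(i);
    int k = (int)idx.size();
    if (k < 2) break;
    if (x < 1.0) {
      used += rng.rexp(k * (k - 1) / 2.0);
      if (used > tau) break;
    }
    int a = rng.unif_int(k);
    int b = rng.unif_int(k - 1);
    if (b >= a) ++b;
    merge_pair(L, idx[a], idx[b], t, d, next_node, out);
  }
}

// one genealogy; col_time[d] < 0 means "no colonization event for deme d"
static void simulate_one(const SimInput &in, const std::vector<double> &K,
                         double m, const std::vector<double> &col_time,
                         double x, uint64_t seed, SimOut &out) {
  const int n = (int)in.sdeme.size();
  Xoshiro rng(seed);
  out.capped = false;
  out.n_merges = 0;
  out.mrec.assign(5 * (size_t)(n > 1 ? n - 1 : 0), 0.0);
  for (int i = 0; i < 10; ++i) out.sums[i] = 0.0;

  std::vector<Lin> L;
  L.reserve(n);
  std::vector<int> kd(in.n_demes, 0);

  // colonization events sorted by (time, deme)
  std::vector< std::pair<double,int> > colev;
  for (int d = 0; d < in.n_demes; ++d)
    if (col_time[d] > 0) colev.push_back(std::make_pair(col_time[d], d));
  std::sort(colev.begin(), colev.end());

  size_t na = 0;            // next activation (into act_order)
  size_t nc = 0;            // next colonization event
  size_t ep = 0;            // current epoch index; K[ep] valid while t < bounds[ep]
  int next_node = n;
  double t = 0.0;

  while ((int)L.size() + (int)(in.act_order.size() - na) > 1) {
    // advance epoch pointer (t may have jumped past a boundary exactly)
    while (ep < in.bounds.size() && t >= in.bounds[ep]) ++ep;

    // next scheduled time
    double t_act = (na < in.act_order.size())
                     ? in.sage[in.act_order[na]] : R_PosInf;
    double t_col = (nc < colev.size()) ? colev[nc].first : R_PosInf;
    double t_ep  = (ep < in.bounds.size()) ? in.bounds[ep] : R_PosInf;
    double t_sched = std::min(std::min(t_act, t_col),
                              std::min(t_ep, in.time_cap));

    // total event rate under the current epoch's K
    double Know = K[ep < K.size() ? ep : K.size() - 1];
    double pair_units = 0.0;
    for (int d = 0; d < in.n_demes; ++d)
      pair_units += kd[d] * (kd[d] - 1) / 2.0;
    double coal_rate = pair_units / Know;
    double mig_rate = m * (double)L.size();
    double R = coal_rate + mig_rate;

    double te = (R > 0) ? t + rng.rexp(R) : R_PosInf;
    if (te < t_sched) {
      t = te;
      double u = rng.unif() * R;
      if (u < coal_rate) {
        // choose deme proportional to within-deme pair count
        double cum = 0.0, target = u * Know;  // back to pair units
        int d = -1;
        for (int dd = 0; dd < in.n_demes; ++dd) {
          cum += kd[dd] * (kd[dd] - 1) / 2.0;
          if (target < cum) { d = dd; break; }
        }
        if (d < 0) d = in.n_demes - 1;
        std::vector<int> idx;
        for (int i = 0; i < (int)L.size(); ++i)
          if (L[i].deme == d) idx.push_back(i);
        int k = (int)idx.size();
        int a = rng.unif_int(k), b = rng.unif_int(k - 1);
        if (b >= a) ++b;
        merge_pair(L, idx[a], idx[b], t, d, next_node, out);
        kd[d] -= 1;
      } else {
        int i = rng.unif_int((int)L.size());
        int from = L[i].deme;
        const std::vector<int> &nb = in.adj[from];
        int to = nb[rng.unif_int((int)nb.size())];
        L[i].deme = to;
        kd[from] -= 1; kd[to] += 1;
      }
      continue;
    }

    // scheduled item(s) at t_sched
    t = t_sched;
    if (t >= in.time_cap && ((int)L.size() + (int)(in.act_order.size() - na)) > 1) {
      out.capped = true;
      return;
    }
    // activations first (sample-id order within equal ages)
    bool did = false;
    while (na < in.act_order.size() && in.sage[in.act_order[na]] <= t) {
      int s = in.act_order[na++];
      Lin li;
      li.node = s; li.deme = in.sdeme[s];
      for (int g = 0; g < 4; ++g) li.grp[g] = 0;
      li.grp[in.sgrp[s]] = 1;
      L.push_back(li);
      kd[li.deme] += 1;
      did = true;
    }
    if (did) continue;
    // colonization events at this time (deme order via sort key)
    while (nc < colev.size() && colev[nc].first <= t) {
      int d = colev[nc].second;
      ++nc;
      int before = (int)L.size();
      bottleneck_burst(L, d, x, t, next_node, out, rng);
      int merged = before - (int)L.size();
      for (int i = 0; i < (int)L.size(); ++i) {
        if (L[i].deme == d) {
          const std::vector<int> &src = in.sources[d];
          int to = src[rng.unif_int((int)src.size())];
          kd[d] -= 1; kd[to] += 1;
          L[i].deme = to;
        }
      }
      kd[d] = 0;
      (void)merged;
      did = true;
    }
    // epoch boundary: nothing to do beyond the pointer advance on re-entry
  }
}

static SimInput build_input(List adj, IntegerVector sample_deme,
                            NumericVector sample_age, IntegerVector sample_group,
                            NumericVector epoch_bounds, List col_sources,
                            double time_cap) {
  SimInput in;
  in.n_demes = adj.size();
  in.adj.resize(in.n_demes);
  for (int d = 0; d < in.n_demes; ++d) {
    IntegerVector nb = adj[d];
    in.adj[d].assign(nb.begin(), nb.end());
    for (size_t j = 0; j < in.adj[d].size(); ++j) in.adj[d][j] -= 1;  // 1- to 0-based
  }
  int n = sample_deme.size();
  in.sdeme.resize(n); in.sage.resize(n); in.sgrp.resize(n);
  for (int i = 0; i < n; ++i) {
    in.sdeme[i] = sample_deme[i] - 1;
    in.sage[i] = sample_age[i];
    in.sgrp[i] = sample_group[i] - 1;
  }
  in.act_order.resize(n);
  for (int i = 0; i < n; ++i) in.act_order[i] = i;
  std::stable_sort(in.act_order.begin(), in.act_order.end(),
                   [&](int a, int b) { return in.sage[a] < in.sage[b]; });
  in.bounds.assign(epoch_bounds.begin(), epoch_bounds.end());
  in.sources.resize(in.n_demes);
  if (col_sources.size() > 0) {
    for (int d = 0; d < in.n_demes; ++d) {
      SEXP el = col_sources[d];
      if (el != R_NilValue) {
        IntegerVector src(el);
        in.sources[d].assign(src.begin(), src.end());
        for (size_t j = 0; j < in.sources[d].size(); ++j) in.sources[d][j] -= 1;
      }
    }
  }
  in.time_cap = time_cap;
  return in;
}

// [[Rcpp::export(".sim_core_cpp")]]
List sim_core_cpp(List adj, IntegerVector sample_deme, NumericVector sample_age,
                  IntegerVector sample_group, NumericVector epoch_bounds,
                  NumericVector K_epoch, double m, NumericVector col_time,
                  List col_sources, double x, double time_cap, double seed) {
  SimInput in = build_input(adj, sample_deme, sample_age, sample_group,
                            epoch_bounds, col_sources, time_cap);
  std::vector<double> K(K_epoch.begin(), K_epoch.end());
  std::vector<double> ct(col_time.begin(), col_time.end());
  SimOut out;
  simulate_one(in, K, m, ct, x, (uint64_t)seed, out);
  int nm = out.n_merges;
  NumericMatrix mrec(nm, 5);
  for (int i = 0; i < nm; ++i)
    for (int j = 0; j < 5; ++j) mrec(i, j) = out.mrec[5 * (size_t)i + j];
  colnames(mrec) = CharacterVector::create("child1", "child2", "parent",
                                           "time", "deme");
  NumericVector sums(10);
  for (int i = 0; i < 10; ++i) sums[i] = out.sums[i];
  return List::create(_["merges"] = mrec, _["sums"] = sums,
                      _["capped"] = out.capped);
}

// Batch simulation for one scenario: parameter matrix with columns
// m, x, T, dT followed by one K column per epoch. hop[d] is the graph hop
// distance from the (fixed) origin, or NA/-1 when the scenario has no
// expansion. Deme d is colonized at T - (hop[d]-1+col_offset)*dT.
// Returns n_sims x 11: the 10 mean TMRCA entries (NA where the group
// combination has no pairs, or everywhere when the run hit the time cap)
// plus a 'capped' indicator column.
// [[Rcpp::export(".sim_batch_cpp")]]
NumericMatrix sim_batch_cpp(List adj, IntegerVector sample_deme,
                            NumericVector sample_age, IntegerVector sample_group,
                            NumericVector epoch_bounds, NumericMatrix par,
                            IntegerVector hop, List col_sources, int col_offset,
                            double time_cap, double seed_base) {
  SimInput in = build_input(adj, sample_deme, sample_age, sample_group,
                            epoch_bounds, col_sources, time_cap);
  const int n_epochs = (int)epoch_bounds.size() + 1;
  const int n_sims = par.nrow();
  const bool expansion = hop.size() == in.n_demes && !IntegerVector::is_na(hop[0]);

  // pair counts per group combination, from the sample group composition
  double npairs[10] = {0,0,0,0,0,0,0,0,0,0};
  {
    int ng[4] = {0, 0, 0, 0};
    for (int i = 0; i < (int)in.sgrp.size(); ++i) ng[in.sgrp[i]] += 1;
    for (int g = 0; g < 4; ++g)
      for (int h = g; h < 4; ++h)
        npairs[PAIR_IDX[g][h]] = (g == h) ? ng[g] * (ng[g] - 1) / 2.0
                                          : (double)ng[g] * ng[h];
  }

  NumericMatrix res(n_sims, 11);
  std::vector<double> K(n_epochs), ct(in.n_demes, -1.0);
  SimOut out;
  for (int s = 0; s < n_sims; ++s) {
    if (s % 1024 == 0) Rcpp::checkUserInterrupt();
    double m = par(s, 0), x = par(s, 1), T = par(s, 2), dT = par(s, 3);
    for (int e = 0; e < n_epochs; ++e) K[e] = par(s, 4 + e);
    if (expansion) {
      for (int d = 0; d < in.n_demes; ++d)
        ct[d] = (hop[d] > 0) ? T - (hop[d] - 1 + col_offset) * dT : -1.0;
    }
    simulate_one(in, K, m, ct, x, (uint64_t)seed_base + (uint64_t)s, out);
    if (out.capped) {
      for (int j = 0; j < 10; ++j) res(s, j) = NA_REAL;
      res(s, 10) = 1.0;
    } else {
      for (int j = 0; j < 10; ++j)
        res(s, j) = npairs[j] > 0 ? out.sums[j] / npairs[j] : NA_REAL;
      res(s, 10) = 0.0;
    }
  }
  return res;
}

// Standalone founder-bottleneck burst among k exchangeable lineages:
// returns the sequence of merges as a matrix with columns (a, b, new),
// where a and b are ids of the merging lineages (1..k initially, k+1, ...
// for merge products) -- the same mechanism the full simulator uses.
// [[Rcpp::export(".bottleneck_burst_cpp")]]
IntegerMatrix bottleneck_burst_cpp(int k, double x, double seed) {
  Xoshiro rng((uint64_t)seed);
  std::vector<int> ids(k);
  for (int i = 0; i < k; ++i) ids[i] = i + 1;
  std::vector< std::array<int,3> > rec;
  int next_id = k + 1;
  if (x > 0.0 && k >= 2) {
    double tau = (x >= 1.0) ? R_PosInf : -std::log1p(-x);
    double used = 0.0;
    while ((int)ids.size() >= 2) {
      int kk = (int)ids.size();
      if (x < 1.0) {
        used += rng.rexp(kk * (kk - 1) / 2.0);
        if (used > tau) break;
      }
      int a = rng.unif_int(kk), b = rng.unif_int(kk - 1);
      if (b >= a) ++b;
      std::array<int,3> r = {{ids[a], ids[b], next_id}};
      if (r[0] > r[1]) std::swap(r[0], r[1]);
      rec.push_back(r);
      ids[a] = next_id++;
      ids[b] = ids.back();
      ids.pop_back();
    }
  }
  IntegerMatrix m((int)rec.size(), 3);
  for (int i = 0; i < (int)rec.size(); ++i)
    for (int j = 0; j < 3; ++j) m(i, j) = rec[i][j];
  colnames(m) = CharacterVector::create("a", "b", "new");
  return m;
}
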