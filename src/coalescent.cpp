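// Backward-time coalescent engine for multi-deme demographies with
// population splits, pulse admixture and stepwise size changes.
//
// Time is measured in generations before present.  Within a deme of diploid
// effective size N, each pair of lineages coalesces at rate 1/(2N) per
// generation.  Mutations follow the infinite-sites model: a branch of
// duration T receives Poisson(mu_len * T) mutations, each defining one
// biallelic site whose derived allele is carried by the leaves descending
// from that branch.
//
// Events (rows of the `events` matrix, sorted by time ascending):
//   type 1  split:        all lineages in deme `a` move to deme `b`
//   type 2  pulse:        each lineage in deme `a` moves to deme `b`
//                         with probability `param` (backward in time; this is
//                         a forward-time admixture pulse of proportion
//                         `param` from b into a)
//   type 3  size change:  deme `a` takes diploid size `param`
//
// Reproducibility: each locus uses an independent RNG stream seeded by a
// splitmix64 hash of (seed, locus index), so locus i is identical whatever
// n_loci is requested.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct Lineage {
  int deme;
  double birth;                 // time the lineage was created
  std::vector<uint64_t> mask;   // descendant leaves (bitset over genes)
  int id;                       // node id for genealogy export
};

// [[Rcpp::export(name = ".sim_coalescent_cpp")]]
List sim_coalescent_cpp(int n_demes,
                        NumericVector sizes0,
                        NumericMatrix events,
                        IntegerVector samples_genes,
                        double mu_len,
                        int n_loci,
                        double seed,
                        int mode) {
  // mode: 0 = site deme-counts only, 1 = + per-gene carrier matrix,
  //       2 = + genealogy history (requires n_loci == 1)
  const int D = n_demes;
  int n = 0;
  for (int d = 0; d < D; ++d) n += samples_genes[d];
  if (n < 2) stop("need at least two sampled genes");
  const int W = (n + 63) / 64;
  const int n_ev = events.nrow();

  // deme membership masks for counting
  std::vector<std::vector<uint64_t>> deme_mask(D, std::vector<uint64_t>(W, 0));
  {
    int g = 0;
    for (int d = 0; d < D; ++d)
      for (int i = 0; i < samples_genes[d]; ++i, ++g)
        deme_mask[d][g / 64] |= (1ULL << (g % 64));
  }

  std::vector<int> site_counts;   // n_sites * D
  std::vector<int> site_locus;
  std::vector<int> site_carriers; // n_sites * n (mode 1)
  NumericVector tmrca(n_loci), tlen(n_loci);
  std::vector<double> hist;       // rows of (child1, child2, parent, time)

  const uint64_t base_seed = (uint64_t)seed;

  for (int loc = 0; loc < n_loci; ++loc) {
    uint64_t s = splitmix64(base_seed ^ splitmix64((uint64_t)loc));
    std::mt19937_64 rng(s);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<Lineage> lin;
    lin.reserve(n);
    {
      int g = 0;
      for (int d = 0; d < D; ++d)
        for (int i = 0; i < samples_genes[d]; ++i, ++g) {
          Lineage L;
          L.deme = d; L.birth = 0.0; L.id = g;
          L.mask.assign(W, 0);
          L.mask[g / 64] |= (1ULL << (g % 64));
          lin.push_back(std::move(L));
        }
    }

    std::vector<double> N(sizes0.begin(), sizes0.end());
    double t = 0.0, total_len = 0.0;
    int ev = 0, next_id = n;
    std::vector<int> kd(D);
    std::vector<double> lam(D);

    auto emit_mutations = [&](const Lineage& L, double now) {
      double dur = now - L.birth;
      total_len += dur;
      if (mu_len <= 0.0 || dur <= 0.0) return;
      std::poisson_distribution<int> pois(mu_len * dur);
      int nm = pois(rng);
      for (int m = 0; m < nm; ++m) {
        for (int d = 0; d < D; ++d) {
          int c = 0;
          for (int w = 0; w < W; ++w) c += popcount64(L.mask[w] & deme_mask[d][w]);
          site_counts.push_back(c);
        }
        site_locus.push_back(loc + 1);
        if (mode == 1) {
          for (int g = 0; g < n; ++g)
            site_carriers.push_back((L.mask[g / 64] >> (g % 64)) & 1ULL);
        }
      }
    };

    while ((int)lin.size() > 1) {
      std::fill(kd.begin(), kd.end(), 0);
      for (const Lineage& L : lin) kd[L.deme]++;
      double tot = 0.0;
      for (int d = 0; d < D; ++d) {
        lam[d] = (kd[d] > 1 && N[d] > 0.0)
                   ? (double)kd[d] * (kd[d] - 1) / 2.0 / (2.0 * N[d]) : 0.0;
        tot += lam[d];
      }
      double dt = (tot > 0.0) ? -std::log(1.0 - unif(rng)) / tot : R_PosInf;
      if (ev < n_ev && (tot == 0.0 || t + dt > events(ev, 0))) {
        t = events(ev, 0);
        int type = (int)events(ev, 1);
        int a = (int)events(ev, 2) - 1, b = (int)events(ev, 3) - 1;
        double par = events(ev, 4);
        if (type == 1) {            // split: a merges into b
          for (Lineage& L : lin) if (L.deme == a) L.deme = b;
        } else if (type == 2) {     // pulse: a -> b with prob par
          for (Lineage& L : lin) if (L.deme == a && unif(rng) < par) L.deme = b;
        } else if (type == 3) {     // size change on a
          N[a] = par;
        }
        ++ev;
        continue;
      }
      if (tot == 0.0)
        stop("lineages cannot coalesce: multiple demes remain after all events");
      t += dt;
      // choose deme proportional to lam, then a uniform pair within it
      double u = unif(rng) * tot, acc = 0.0;
      int d_sel = D - 1;
      for (int d = 0; d < D; ++d) { acc += lam[d]; if (u <= acc) { d_sel = d; break; } }
      int k = kd[d_sel];
      int r1 = (int)(unif(rng) * k); if (r1 >= k) r1 = k - 1;
      int r2 = (int)(unif(rng) * (k - 1)); if (r2 >= k - 1) r2 = k - 2;
      if (r2 >= r1) ++r2;
      int i1 = -1, i2 = -1, seen = 0;
      for (int i = 0; i < (int)lin.size(); ++i) {
        if (lin[i].deme == d_sel) {
          if (seen == r1) i1 = i;
          if (seen == r2) i2 = i;
          ++seen;
        }
      }
      if (i2 < i1) std::swap(i1, i2);
      emit_mutations(lin[i1], t);
      emit_mutations(lin[i2], t);
      if (mode == 2) {
        hist.push_back(lin[i1].id); hist.push_back(lin[i2].id);
        hist.push_back(next_id); hist.push_back(t);
      }
      Lineage merged;
      merged.deme = d_sel; merged.birth = t; merged.id = next_id++;
      merged.mask.assign(W, 0);
      for (int w = 0; w < W; ++w)
        merged.mask[w] = lin[i1].mask[w] | lin[i2].mask[w];
      lin[i1] = std::move(merged);
      lin.erase(lin.begin() + i2);
    }
    tmrca[loc] = t;
    tlen[loc] = total_len;
  }

  const int S = (int)site_locus.size();
  IntegerMatrix counts(S, D);
  for (int i = 0; i < S; ++i)
    for (int d = 0; d < D; ++d)
      counts(i, d) = site_counts[(size_t)i * D + d];
  List out = List::create(_["counts"] = counts,
                          _["locus"] = IntegerVector(site_locus.begin(), site_locus.end()),
                          _["tmrca"] = tmrca,
                          _["tlen"] = tlen);
  if (mode == 1) {
    IntegerMatrix carr(S, n);
    for (int i = 0; i < S; ++i)
      for (int g = 0; g < n; ++g)
        carr(i, g) = site_carriers[(size_t)i * n + g];
    out["carriers"] = carr;
  }
  if (mode == 2) {
    const int M = (int)hist.size() / 4;
    NumericMatrix h(M, 4);
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < 4; ++j) h(i, j) = hist[(size_t)i * 4 + j];
    colnames(h) = CharacterVector::create("child1", "child2", "parent", "time");
    out["history"] = h;
  }
  return out;
}
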