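// Forward Wright-Fisher simulation with recombination and a steady influx of
// neutral and selected mutations. Individuals are diploid; fitness is
// multiplicative across loci with dominance h within a locus. Haplotypes are
// sparse sorted vectors of mutation ids; positions are continuous in [0, L)
// so crossover breakpoints never coincide with mutations. Each haplotype
// carries a parallel vector of its selected mutation ids so that fitness
// evaluation does not touch the (much larger) neutral load.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct WFSim {
  int N;             // diploid individuals (total)
  double L;          // genome length, bp
  double r, mu;      // per bp per generation
  double U;          // selected mutations per diploid per generation
  double s_sel, h;
  int n_demes;
  double m;
  std::mt19937_64 rng;

  std::vector<double> mpos, ms;
  std::vector<int> morigin;
  // 2N haplotypes, ids sorted by position; *_sel holds the selected subset
  std::vector<std::vector<int>> hap, hap_sel;
  std::vector<std::vector<int>> hap_next, hap_sel_next;  // reused buffers
  int gen = 0;
  long n_fixed = 0;
  std::vector<char> fixed_flag;  // per mutation id, fixed at some purge

  WFSim(int N_, double L_, double r_, double mu_, double U_, double s_,
        double h_, int n_demes_, double m_, uint64_t seed)
      : N(N_), L(L_), r(r_), mu(mu_), U(U_), s_sel(s_), h(h_),
        n_demes(n_demes_), m(m_), rng(seed) {
    hap.assign(2 * N, {});
    hap_sel.assign(2 * N, {});
    hap_next.assign(2 * N, {});
    hap_sel_next.assign(2 * N, {});
  }

  int deme_of(int ind) const { return (n_demes == 2 && ind >= N / 2) ? 1 : 0; }
  int deme_begin(int d) const { return d == 0 ? 0 : N / 2; }
  int deme_end(int d) const { return d == 0 ? (n_demes == 2 ? N / 2 : N) : N; }

  bool pos_less(int a, int b) const {
    return mpos[a] < mpos[b] || (mpos[a] == mpos[b] && a < b);
  }

  // fitness from the two selected-id vectors of an individual, merged by
  // position; the same id on both haplotypes is a homozygote
  double fitness_of(const std::vector<int>& sa,
                    const std::vector<int>& sb) const {
    double wi = 1.0;
    size_t a = 0, b = 0;
    while (a < sa.size() || b < sb.size()) {
      if (b == sb.size() || (a < sa.size() && pos_less(sa[a], sb[b]))) {
        wi *= (1.0 + h * ms[sa[a]]);
        ++a;
      } else if (a == sa.size() || pos_less(sb[b], sa[a])) {
        wi *= (1.0 + h * ms[sb[b]]);
        ++b;
      } else {  // same id: homozygote
        wi *= (1.0 + ms[sa[a]]);
        ++a;
        ++b;
      }
    }
    return wi;
  }

  void fitness(std::vector<double>& w) {
    w.assign(N, 1.0);
    if (U == 0.0) return;
    for (int i = 0; i < N; ++i) {
      w[i] = fitness_of(hap_sel[2 * i], hap_sel[2 * i + 1]);
    }
  }

  // copy the crossover mosaic of A and B (both sorted by position) into out;
  // xs must end with a sentinel beyond L
  void mosaic(const std::vector<int>& A, const std::vector<int>& B,
              const std::vector<double>& xs, bool useA,
              std::vector<int>& out) const {
    out.clear();
    out.reserve(A.size() + 8);
    size_t ia = 0, ib = 0;
    for (double x : xs) {
      const std::vector<int>& src = useA ? A : B;
      size_t& isrc = useA ? ia : ib;
      while (isrc < src.size() && mpos[src[isrc]] < x) {
        out.push_back(src[isrc]);
        ++isrc;
      }
      const std::vector<int>& oth = useA ? B : A;
      size_t& ioth = useA ? ib : ia;
      while (ioth < oth.size() && mpos[oth[ioth]] < x) ++ioth;
      useA = !useA;
    }
  }

  // recombinant gamete from individual `par`
  void meiosis(int par, std::vector<int>& child, std::vector<int>& child_sel) {
    const std::vector<int>& A = hap[2 * par];
    const std::vector<int>& B = hap[2 * par + 1];
    std::poisson_distribution<int> pois_x(r * L);
    int k = pois_x(rng);
    std::uniform_real_distribution<double> unif(0.0, L);
    std::bernoulli_distribution coin(0.5);
    bool useA = coin(rng);
    if (k == 0) {
      const std::vector<int>& src = useA ? A : B;
      child.assign(src.begin(), src.end());
      const std::vector<int>& ssrc = useA ? hap_sel[2 * par]
                                          : hap_sel[2 * par + 1];
      child_sel.assign(ssrc.begin(), ssrc.end());
    } else {
      std::vector<double> xs(k);
      for (int j = 0; j < k; ++j) xs[j] = unif(rng);
      std::sort(xs.begin(), xs.end());
      xs.push_back(L + 1.0);
      mosaic(A, B, xs, useA, child);
      mosaic(hap_sel[2 * par], hap_sel[2 * par + 1], xs, useA, child_sel);
    }
    // new mutations
    std::poisson_distribution<int> pois_neut(mu * L);
    int nn = pois_neut(rng);
    int ns = 0;
    if (U > 0) {
      std::poisson_distribution<int> pois_sel(U / 2.0);
      ns = pois_sel(rng);
    }
    for (int j = 0; j < nn + ns; ++j) {
      double pos = unif(rng);
      bool is_sel = j >= nn;
      int id = (int)mpos.size();
      mpos.push_back(pos);
      ms.push_back(is_sel ? s_sel : 0.0);
      morigin.push_back(gen);
      fixed_flag.push_back(0);
      auto cmp = [&](int a, double p) { return mpos[a] < p; };
      child.insert(std::lower_bound(child.begin(), child.end(), pos, cmp),
                   id);
      if (is_sel) {
        child_sel.insert(std::lower_bound(child_sel.begin(), child_sel.end(),
                                          pos, cmp),
                         id);
      }
    }
  }

  void step() {
    std::vector<double> w;
    fitness(w);
    // per-deme cumulative fitness
    std::vector<std::vector<double>> cum(n_demes);
    for (int d = 0; d < n_demes; ++d) {
      cum[d].resize(deme_end(d) - deme_begin(d));
      double acc = 0.0;
      for (int i = deme_begin(d); i < deme_end(d); ++i) {
        acc += w[i];
        cum[d][i - deme_begin(d)] = acc;
      }
    }
    std::uniform_real_distribution<double> u01(0.0, 1.0);
    for (int i = 0; i < N; ++i) {
      int d = deme_of(i);
      for (int c = 0; c < 2; ++c) {
        int sd = d;
        if (n_demes == 2 && u01(rng) < m) sd = 1 - d;
        const std::vector<double>& cw = cum[sd];
        double x = u01(rng) * cw.back();
        int j = (int)(std::upper_bound(cw.begin(), cw.end(), x) - cw.begin());
        if (j >= (int)cw.size()) j = (int)cw.size() - 1;
        meiosis(deme_begin(sd) + j, hap_next[2 * i + c],
                hap_sel_next[2 * i + c]);
      }
    }
    hap.swap(hap_next);
    hap_sel.swap(hap_sel_next);
    ++gen;
  }

  std::vector<int> occurrence_counts() const {
    std::vector<int> cnt(mpos.size(), 0);
    for (const auto& hp : hap) {
      for (int id : hp) ++cnt[id];
    }
    return cnt;
  }

  // remove fixed mutations from all haplotypes (relative fitness unchanged)
  void purge_fixed() {
    std::vector<int> cnt = occurrence_counts();
    int full = 2 * N;
    bool any = false;
    for (size_t id = 0; id < cnt.size(); ++id) {
      if (cnt[id] == full) {
        any = true;
        fixed_flag[id] = 1;
        ++n_fixed;
      }
    }
    if (!any) return;
    auto drop = [&](std::vector<int>& hp) {
      hp.erase(std::remove_if(hp.begin(), hp.end(),
                              [&](int id) { return cnt[id] == full; }),
               hp.end());
    };
    for (auto& hp : hap) drop(hp);
    for (auto& hp : hap_sel) drop(hp);
  }

  void run(int gens) {
    for (int g = 0; g < gens; ++g) {
      step();
      if (gen % 10 == 0) {
        purge_fixed();
        Rcpp::checkUserInterrupt();
      }
    }
  }
};

// [[Rcpp::export]]
List wf_sim_cpp(int N, double genome_length, double r, double mu_neutral,
                double U, double s_sel, double h, int burn_in, int t_interval,
                int n_demes, double m, double seed, bool return_state) {
  if (N < 2) stop("N must be >= 2");
  if (n_demes == 2 && N % 2 != 0) stop("structured runs need even N");
  WFSim sim(N, genome_length, r, mu_neutral, U, s_sel, h, n_demes, m,
            (uint64_t)seed);
  sim.run(burn_in);
  sim.purge_fixed();

  // snapshot at generation G: segregating mutations, frequencies, s_total
  std::vector<int> cnt = sim.occurrence_counts();
  std::vector<int> seg;
  for (size_t id = 0; id < cnt.size(); ++id) {
    if (cnt[id] > 0 && cnt[id] < 2 * N) seg.push_back((int)id);
  }
  int S = (int)seg.size();
  std::vector<int> seg_index(cnt.size(), -1);
  for (int k = 0; k < S; ++k) seg_index[seg[k]] = k;

  std::vector<double> w;
  sim.fitness(w);
  double Wtot = 0.0;
  for (double wi : w) Wtot += wi;
  double wbar = Wtot / N;

  // per-copy fitness accumulation: an individual carrying two copies of the
  // focal allele counts twice (allele-dosage weighting)
  std::vector<double> sumw(S, 0.0);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < 2; ++c) {
      for (int id : sim.hap[2 * i + c]) {
        int k = seg_index[id];
        if (k >= 0) sumw[k] += w[i];
      }
    }
  }
  NumericVector pos(S), sval(S), freq0(S), freq1(S), s_total(S);
  IntegerVector origin(S);
  for (int k = 0; k < S; ++k) {
    int id = seg[k];
    pos[k] = sim.mpos[id];
    sval[k] = sim.ms[id];
    origin[k] = sim.morigin[id];
    freq0[k] = (double)cnt[id] / (2.0 * N);
    double wF = sumw[k] / cnt[id];
    double wNF = (2.0 * Wtot - sumw[k]) / (2.0 * N - cnt[id]);
    s_total[k] = (wF - wNF) / wbar;
  }

  IntegerMatrix geno;
  if (return_state) {
    if ((double)S * 2.0 * N > 5e6) stop("state too large to export");
    geno = IntegerMatrix(2 * N, S);
    for (int hpi = 0; hpi < 2 * N; ++hpi) {
      for (int id : sim.hap[hpi]) {
        int k = seg_index[id];
        if (k >= 0) geno(hpi, k) = 1;
      }
    }
  }

  // advance to generation G + t_interval, then re-measure the snapshot loci
  sim.run(t_interval);
  std::vector<int> cnt1 = sim.occurrence_counts();
  for (int k = 0; k < S; ++k) {
    int id = seg[k];
    if (sim.fixed_flag[id]) {
      freq1[k] = 1.0;
    } else {
      freq1[k] = (double)cnt1[id] / (2.0 * N);
    }
  }

  List out = List::create(
      _["pos"] = pos, _["s"] = sval, _["origin"] = origin,
      _["freq0"] = freq0, _["freq1"] = freq1, _["s_total"] = s_total,
      _["mean_fitness"] = wbar, _["n_fixed"] = (double)sim.n_fixed,
      _["n_mutations"] = (double)sim.mpos.size());
  if (return_state) out["genotypes"] = geno;
  return out;
}
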