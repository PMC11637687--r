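#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Discrete-generation Wright-Fisher forward simulator on a continuous
// region: infinite-sites mutations at per-gamete rate mu*L, crossovers at
// per-meiosis rate r*L, optional additive selection at one site with
// genotype fitnesses 1 : 1+s : 1+2s. Haplotypes are sorted vectors of
// mutation positions (doubles in [0, L)).

typedef std::vector<double> Hap;

static Hap make_gamete(const Hap& h1, const Hap& h2, double L, double rec) {
  int ncx = (int)R::rpois(rec * L);
  bool first = R::unif_rand() < 0.5;
  if (ncx == 0) return first ? h1 : h2;
  std::vector<double> bp(ncx);
  for (int i = 0; i < ncx; ++i) bp[i] = R::unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  Hap out;
  out.reserve(std::max(h1.size(), h2.size()));
  const Hap* src[2] = {&h1, &h2};
  int active = first ? 0 : 1;
  double lo = 0.0;
  for (int seg = 0; seg <= ncx; ++seg) {
    double hi = (seg == ncx) ? L : bp[seg];
    const Hap& h = *src[active];
    auto a = std::lower_bound(h.begin(), h.end(), lo);
    auto b = std::lower_bound(h.begin(), h.end(), hi);
    out.insert(out.end(), a, b);
    active = 1 - active;
    lo = hi;
  }
  return out;
}

static void add_mutations(Hap& h, double L, double mu) {
  int nm = (int)R::rpois(mu * L);
  for (int i = 0; i < nm; ++i) {
    double p = R::unif_rand() * L;
    h.insert(std::lower_bound(h.begin(), h.end(), p), p);
  }
}

static inline bool carries(const Hap& h, double pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

static void wf_generation(std::vector<Hap>& pop, int n_diploid,
                          double region_bp, double mu, double rec,
                          double sel_pos, double s, bool selected) {
  const int nhap = 2 * n_diploid;
  std::vector<double> w(n_diploid, 1.0);
  if (selected) {
    for (int d = 0; d < n_diploid; ++d) {
      int gt = carries(pop[2 * d], sel_pos) + carries(pop[2 * d + 1], sel_pos);
      w[d] = 1.0 + s * gt;
    }
  }
  std::vector<double> cw(n_diploid);
  double tot = 0;
  for (int d = 0; d < n_diploid; ++d) { tot += w[d]; cw[d] = tot; }
  std::vector<Hap> next(nhap);
  for (int d = 0; d < n_diploid; ++d) {
    for (int h = 0; h < 2; ++h) {
      double u = R::unif_rand() * tot;
      int par = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (par >= n_diploid) par = n_diploid - 1;
      Hap gam = make_gamete(pop[2 * par], pop[2 * par + 1], region_bp, rec);
      add_mutations(gam, region_bp, mu);
      next[2 * d + h] = std::move(gam);
    }
  }
  pop.swap(next);
}

// [[Rcpp::export(name = ".wf_forward")]]
List wf_forward(int n_diploid, double region_bp, double mu, double rec,
                int generations, double sel_pos, double s, int init_count,
                bool condition_survival, int max_restarts,
                double stop_freq, int burn_in) {
  const int nhap = 2 * n_diploid;
  bool selected = (s > 0 && sel_pos >= 0);
  int restarts = 0;

  // neutral burn-in towards mutation-drift equilibrium
  std::vector<Hap> base(nhap);
  for (int g = 0; g < burn_in; ++g)
    wf_generation(base, n_diploid, region_bp, mu, rec, -1, 0, false);

  std::vector<Hap> pop;
  for (;;) {
    pop = base;
    if (selected) {
      // drop the selected mutation onto init_count random haplotypes
      for (int i = 0; i < init_count && i < nhap; ++i) {
        int h = (int)(R::unif_rand() * nhap);
        Hap& hp = pop[h];
        if (!carries(hp, sel_pos))
          hp.insert(std::lower_bound(hp.begin(), hp.end(), sel_pos), sel_pos);
      }
    }
    bool lost = false;
    for (int g = 0; g < generations; ++g) {
      wf_generation(pop, n_diploid, region_bp, mu, rec, sel_pos, s, selected);
      if (selected) {
        int cnt = 0;
        for (auto& h : pop) cnt += carries(h, sel_pos);
        if (cnt == 0 && condition_survival) { lost = true; break; }
        if (stop_freq > 0 && (double)cnt / nhap >= stop_freq) break;
      }
    }
    if (!lost || !condition_survival || restarts >= max_restarts) break;
    restarts++;
  }

  // tabulate positions
  std::map<double, int> counts;
  for (auto& h : pop)
    for (double p : h) counts[p]++;
  std::vector<double> pos;
  for (auto& kv : counts)
    if (kv.second > 0 && kv.second < nhap) pos.push_back(kv.first);
  IntegerMatrix H(nhap, (int)pos.size());
  for (int r = 0; r < nhap; ++r)
    for (size_t c = 0; c < pos.size(); ++c)
      H(r, c) = carries(pop[r], pos[c]) ? 1 : 0;
  double sel_freq = NA_REAL;
  if (selected) {
    int cnt = 0;
    for (auto& h : pop) cnt += carries(h, sel_pos);
    sel_freq = (double)cnt / nhap;
  }
  return List::create(_["haplotypes"] = H,
                      _["positions"] = NumericVector(pos.begin(), pos.end()),
                      _["sel_freq"] = sel_freq,
                      _["restarts"] = restarts);
}
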