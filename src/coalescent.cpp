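#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent for two demes that merge into a single ancestral
// deme at time T1 (time in units of 2N_ref generations, backwards).
// Migration epochs (epoch_mode):
//   0: never (strict isolation)
//   1: throughout [0, T1)            (continuous symmetric migration)
//   2: only in (T2, T1)              (ancestral/early migration)
//   3: only in [0, T2)               (secondary contact)
// Each lineage carries the number of pop1/pop2 samples it subtends; a
// branch of length t subtending (i, j) samples contributes t to cell
// (i, j) of the branch-length spectrum.

struct Lineage {
  int deme;
  int i;  // pop1 samples subtended
  int j;  // pop2 samples subtended
  double birth;
};

static inline bool migration_active(int mode, double t, double T1, double T2) {
  switch (mode) {
  case 1: return t < T1;
  case 2: return t > T2 && t < T1;
  case 3: return t < T2;
  default: return false;
  }
}

// Simulate one genealogy, accumulating branch lengths into L (row-major
// (n1+1) x (n2+1)).
static void one_genealogy(int n1, int n2, double nu1, double nu2,
                          double T1, double T2, double m, int mode,
                          std::vector<double>& L) {
  std::vector<Lineage> lin;
  lin.reserve(n1 + n2);
  for (int a = 0; a < n1; ++a) lin.push_back({0, 1, 0, 0.0});
  for (int a = 0; a < n2; ++a) lin.push_back({1, 0, 1, 0.0});
  double t = 0.0;
  const int ncol = n2 + 1;

  while (lin.size() > 1) {
    int k = (int)lin.size();
    double rate_c0 = 0, rate_c1 = 0, rate_m = 0;
    bool ancestral = (t >= T1);
    int k0 = 0, k1 = 0;
    if (ancestral) {
      rate_c0 = k * (k - 1) / 2.0;  // ancestral deme size = 1 (reference)
    } else {
      for (auto& l : lin) (l.deme == 0 ? k0 : k1)++;
      rate_c0 = k0 * (k0 - 1) / 2.0 / nu1;
      rate_c1 = k1 * (k1 - 1) / 2.0 / nu2;
      if (migration_active(mode, t, T1, T2)) rate_m = (k0 + k1) * m / 2.0;
    }
    double total = rate_c0 + rate_c1 + rate_m;

    // next epoch boundary ahead of t
    double boundary = R_PosInf;
    if (!ancestral) {
      if ((mode == 2 || mode == 3) && t < T2) boundary = T2;
      else boundary = T1;
    }

    if (total <= 0) { t = boundary; continue; }
    double dt = R::exp_rand() / total;
    if (t + dt >= boundary) { t = boundary; continue; }
    t += dt;

    double u = R::unif_rand() * total;
    if (u < rate_c0 + rate_c1) {
      int deme = (ancestral || u < rate_c0) ? 0 : 1;
      // pick two distinct lineages in `deme`
      std::vector<int> idx;
      for (int a = 0; a < k; ++a)
        if (ancestral || lin[a].deme == deme) idx.push_back(a);
      int a1 = (int)(R::unif_rand() * idx.size());
      int a2 = (int)(R::unif_rand() * (idx.size() - 1));
      if (a2 >= a1) a2++;
      int x = idx[a1], y = idx[a2];
      L[lin[x].i * ncol + lin[x].j] += t - lin[x].birth;
      L[lin[y].i * ncol + lin[y].j] += t - lin[y].birth;
      Lineage merged {lin[x].deme, lin[x].i + lin[y].i, lin[x].j + lin[y].j, t};
      if (x > y) std::swap(x, y);
      lin[x] = merged;
      lin.erase(lin.begin() + y);
    } else {
      // migration: uniform over lineages (symmetric per-lineage rate m/2)
      int a = (int)(R::unif_rand() * k);
      lin[a].deme = 1 - lin[a].deme;
    }
  }
}

// [[Rcpp::export(name = ".coal_branch_sfs")]]
NumericMatrix coal_branch_sfs(int n1, int n2, double nu1, double nu2,
                              double T1, double T2, double m, int mode,
                              int n_reps) {
  std::vector<double> L((n1 + 1) * (n2 + 1), 0.0);
  for (int r = 0; r < n_reps; ++r)
    one_genealogy(n1, n2, nu1, nu2, T1, T2, m, mode, L);
  NumericMatrix out(n1 + 1, n2 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j)
      out(i, j) = L[i * (n2 + 1) + j] / n_reps;
  return out;
}

// [[Rcpp::export(name = ".coal_sample_sfs")]]
IntegerMatrix coal_sample_sfs(int n1, int n2, double nu1, double nu2,
                              double T1, double T2, double m, int mode,
                              int n_loci, double theta, bool one_per_locus) {
  const int ncol = n2 + 1;
  IntegerMatrix out(n1 + 1, n2 + 1);
  std::vector<double> L((n1 + 1) * ncol);
  for (int loc = 0; loc < n_loci; ++loc) {
    std::fill(L.begin(), L.end(), 0.0);
    one_genealogy(n1, n2, nu1, nu2, T1, T2, m, mode, L);
    double total = 0;
    for (double v : L) total += v;
    if (total <= 0) continue;
    int nmut = one_per_locus ? 1 : (int)R::rpois(theta * total / 2.0);
    for (int mt = 0; mt < nmut; ++mt) {
      double u = R::unif_rand() * total, acc = 0;
      for (size_t c = 0; c < L.size(); ++c) {
        acc += L[c];
        if (u <= acc) { out((int)(c / ncol), (int)(c % ncol))++; break; }
      }
    }
  }
  return out;
}
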