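#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity: at flank distance x, the probability
// that two random haplotypes of the core allele class are identical over
// [core, x]. Computed by refining a partition of the class outward from
// the core; EHH(x) = sum_g C(n_g,2) / C(n,2).

static inline double pair_sum(const std::vector<int>& sizes) {
  double s = 0;
  for (int n : sizes) s += n * (n - 1) / 2.0;
  return s;
}

// One-directional EHH curve for the haplotypes carrying `allele` at `core`.
// dir = +1 (right) or -1 (left). Records EHH at each successive flanking
// site until the value drops below `cutoff` (that value is recorded) or the
// data end. Returns site indices (0-based) and EHH values.
static void ehh_dir(const IntegerMatrix& hap, int core, int allele, int dir,
                    double cutoff, std::vector<int>& idx,
                    std::vector<double>& val) {
  int nhap = hap.nrow(), nsite = hap.ncol();
  std::vector<int> members;
  for (int r = 0; r < nhap; ++r)
    if (hap(r, core) == allele) members.push_back(r);
  int n = (int)members.size();
  if (n < 2) return;
  double denom = n * (n - 1) / 2.0;
  std::vector<int> grp(n, 0);
  int ngrp = 1;
  for (int j = core + dir; j >= 0 && j < nsite; j += dir) {
    // split each group by the allele at j
    std::map<std::pair<int, int>, int> remap;
    std::vector<int> newgrp(n);
    std::vector<int> sizes;
    for (int a = 0; a < n; ++a) {
      std::pair<int, int> key(grp[a], hap(members[a], j));
      auto it = remap.find(key);
      if (it == remap.end()) {
        int id = (int)sizes.size();
        remap[key] = id;
        sizes.push_back(0);
        newgrp[a] = id;
      } else newgrp[a] = it->second;
      sizes[newgrp[a]]++;
    }
    grp.swap(newgrp);
    ngrp = (int)sizes.size();
    double e = pair_sum(sizes) / denom;
    idx.push_back(j);
    val.push_back(e);
    if (e < cutoff) break;
    if (ngrp == n) break;  // fully resolved; EHH stays 0... (= e here)
  }
}

// [[Rcpp::export(name = ".ehh_decay_cpp")]]
List ehh_decay_cpp(IntegerMatrix hap, int core, int allele, double cutoff) {
  std::vector<int> il, ir;
  std::vector<double> vl, vr;
  ehh_dir(hap, core, allele, -1, cutoff, il, vl);
  ehh_dir(hap, core, allele, +1, cutoff, ir, vr);
  return List::create(
    _["left_index"] = IntegerVector(il.begin(), il.end()),
    _["left_ehh"] = NumericVector(vl.begin(), vl.end()),
    _["right_index"] = IntegerVector(ir.begin(), ir.end()),
    _["right_ehh"] = NumericVector(vr.begin(), vr.end()));
}

// Trapezoidal iHH for one allele class at one core. Integrates the EHH
// curve against physical position outward in both directions, stopping at
// the first value below cutoff (segment down to it included). truncated is
// set when either direction hits the data end with EHH still >= cutoff.
static double ihh_class(const IntegerMatrix& hap, const NumericVector& pos,
                        int core, int allele, double cutoff, bool& truncated) {
  double ihh = 0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> idx;
    std::vector<double> val;
    ehh_dir(hap, core, allele, dir, cutoff, idx, val);
    double prev_e = 1.0, prev_x = pos[core];
    bool fell = false;
    for (size_t k = 0; k < idx.size(); ++k) {
      double x = pos[idx[k]], e = val[k];
      ihh += 0.5 * (prev_e + e) * std::fabs(x - prev_x);
      prev_e = e;
      prev_x = x;
      if (e < cutoff) { fell = true; break; }
    }
    if (!fell) truncated = true;
  }
  return ihh;
}

// [[Rcpp::export(name = ".ihs_core_cpp")]]
List ihs_core_cpp(IntegerMatrix hap, NumericVector pos, int core,
                  double cutoff) {
  bool trunc = false;
  double ihh_a = ihh_class(hap, pos, core, 0, cutoff, trunc);
  double ihh_d = ihh_class(hap, pos, core, 1, cutoff, trunc);
  return List::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["truncated"] = trunc);
}
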