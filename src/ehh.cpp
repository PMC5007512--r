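#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Haplotype homozygosity of a carrier set once partitioned into groups:
// sum over groups of C(size,2) / C(n,2).
static double group_homozygosity(const std::vector<int>& grp, int n) {
  std::unordered_map<int, int> cnt;
  for (int g : grp) cnt[g]++;
  double num = 0.0;
  for (auto& kv : cnt) num += (double)kv.second * (kv.second - 1.0);
  return num / ((double)n * (n - 1.0));
}

// EHH curve outward from a core column for a carrier set.
// H: haplotypes x markers 0/1 matrix; carriers: 0-based row indices;
// cols: 0-based marker columns in scan order (moving away from core).
// Returns EHH at each column of `cols`.
// [[Rcpp::export(name = ".ehh_curve_cpp")]]
NumericVector ehh_curve_cpp(const IntegerMatrix& H, const IntegerVector& carriers,
                            const IntegerVector& cols) {
  int n = carriers.size();
  NumericVector out(cols.size());
  if (n < 2) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  std::vector<int> grp(n, 0);
  for (int k = 0; k < cols.size(); ++k) {
    int j = cols[k];
    // refine partition by the allele at column j
    std::unordered_map<long long, int> remap;
    for (int i = 0; i < n; ++i) {
      long long key = (long long)grp[i] * 2LL + H(carriers[i], j);
      auto it = remap.find(key);
      int ng;
      if (it == remap.end()) { ng = remap.size(); remap[key] = ng; }
      else ng = it->second;
      grp[i] = ng;
    }
    out[k] = group_homozygosity(grp, n);
  }
  return out;
}

// Integrated EHH (trapezoid over bp) in one direction from the core.
// pos: marker positions (bp, full map); core: 0-based core column;
// dir: +1 scan right, -1 scan left. Integration starts at EHH(core)=1,
// distance 0, and stops when EHH < cutoff (the sub-cutoff segment is
// excluded), at a gap > max_gap (truncated before the gap), or at the
// chromosome end (flagged).
// Returns [area, truncated_at_end, truncated_at_gap].
// [[Rcpp::export(name = ".ihh_one_side_cpp")]]
NumericVector ihh_one_side_cpp(const IntegerMatrix& H, const IntegerVector& carriers,
                               int core, const NumericVector& pos, int dir,
                               double cutoff, double max_gap) {
  int n = carriers.size();
  int M = pos.size();
  NumericVector res(3);
  if (n < 2) { res[0] = NA_REAL; return res; }
  std::vector<int> grp(n, 0);
  double area = 0.0, prev_ehh = 1.0, prev_pos = pos[core];
  int j = core + dir;
  bool below = false;
  while (j >= 0 && j < M) {
    double gap = std::abs(pos[j] - prev_pos);
    if (gap > max_gap) { res[2] = 1.0; break; }
    std::unordered_map<long long, int> remap;
    for (int i = 0; i < n; ++i) {
      long long key = (long long)grp[i] * 2LL + H(carriers[i], j);
      auto it = remap.find(key);
      int ng;
      if (it == remap.end()) { ng = remap.size(); remap[key] = ng; }
      else ng = it->second;
      grp[i] = ng;
    }
    double e = group_homozygosity(grp, n);
    if (e < cutoff) { below = true; break; }  // sub-cutoff segment excluded
    area += 0.5 * (prev_ehh + e) * gap;
    prev_ehh = e; prev_pos = pos[j];
    j += dir;
  }
  if (!below && res[2] == 0.0) res[1] = 1.0;  // ran off the chromosome end
  res[0] = area;
  return res;
}
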