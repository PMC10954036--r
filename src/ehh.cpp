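// Pooled EHH decay and integrated EHH (iHH) for every core SNP on one
// scaffold. EHH at extension k is the probability that two random
// haplotypes are identical over the closed span [core..k]; iHH is the
// trapezoidal integral of EHH over physical distance until decay below the
// cutoff, summed over both directions. Haplotype grouping is incremental:
// extending the span by one SNP refines the current identity partition.

#include <Rcpp.h>
using namespace Rcpp;

// refine groups g by alleles in column c; returns new group count
static int refine(std::vector<int>& g, const IntegerMatrix& al, int c,
                  int ngroup) {
  const int n = g.size();
  std::vector<int> remap(2 * ngroup, -1);
  int nxt = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * g[i] + al(i, c);
    if (remap[key] < 0) remap[key] = nxt++;
    g[i] = remap[key];
  }
  return nxt;
}

static double ehh_of(const std::vector<int>& g, int ngroup) {
  const int n = g.size();
  std::vector<int> cnt(ngroup, 0);
  for (int i = 0; i < n; ++i) cnt[g[i]]++;
  double pairs = 0.0;
  for (int h = 0; h < ngroup; ++h)
    pairs += 0.5 * cnt[h] * (cnt[h] - 1.0);
  return pairs / (0.5 * n * (n - 1.0));
}

// one direction from core; step = +1 or -1. Appends (col, ehh) pairs and
// reports how the extension ended: 0 = decayed below cutoff, 1 = scaffold
// boundary reached while still above cutoff.
static int extend_dir(const IntegerMatrix& al, const NumericVector& pos,
                      int core, int step, double cutoff,
                      std::vector<int>& cols, std::vector<double>& vals) {
  const int n = al.nrow(), S = al.ncol();
  std::vector<int> g(n, 0);
  int ngroup = refine(g, al, core, 1); // groups from core alleles
  double e = ehh_of(g, ngroup);
  cols.push_back(core);
  vals.push_back(e);
  if (e < cutoff) return 0;
  int c = core + step;
  while (c >= 0 && c < S) {
    ngroup = refine(g, al, c, ngroup);
    e = ehh_of(g, ngroup);
    cols.push_back(c);
    vals.push_back(e);
    if (e < cutoff) return 0;
    c += step;
  }
  return 1;
}

// [[Rcpp::export]]
List ehh_profile_cpp(IntegerMatrix alleles, NumericVector pos, int core,
                     int step, double cutoff) {
  std::vector<int> cols;
  std::vector<double> vals;
  int status = extend_dir(alleles, pos, core, step, cutoff, cols, vals);
  return List::create(_["cols"] = wrap(cols), _["ehh"] = wrap(vals),
                      _["boundary"] = (status == 1));
}

static void dir_area(const IntegerMatrix& al, const NumericVector& pos,
                     int core, int step, double cutoff, double& area,
                     bool& censored) {
  std::vector<int> cols;
  std::vector<double> vals;
  int status = extend_dir(al, pos, core, step, cutoff, cols, vals);
  area = 0.0;
  double dprev = 0.0, eprev = vals[0];
  for (size_t j = 1; j < vals.size(); ++j) {
    double d = std::fabs(pos[cols[j]] - pos[core]);
    area += 0.5 * (eprev + vals[j]) * (d - dprev);
    dprev = d;
    eprev = vals[j];
  }
  censored = (status == 1);
}

// [[Rcpp::export]]
List ihh_scan_cpp(IntegerMatrix alleles, NumericVector pos, double cutoff) {
  const int S = alleles.ncol();
  NumericVector ihh(S);
  LogicalVector censored(S);
  for (int core = 0; core < S; ++core) {
    double a_up, a_dn;
    bool c_up, c_dn;
    dir_area(alleles, pos, core, +1, cutoff, a_up, c_up);
    dir_area(alleles, pos, core, -1, cutoff, a_dn, c_dn);
    ihh[core] = a_up + a_dn;
    censored[core] = c_up || c_dn;
  }
  return List::create(_["ihh"] = ihh, _["censored"] = censored);
}
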