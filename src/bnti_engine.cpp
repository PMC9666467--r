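#include <Rcpp.h>
using namespace Rcpp;

// Weighted beta mean nearest taxon distance for one sample pair given
// tip indices already mapped through the (null) permutation. D is the
// symmetric cophenetic matrix (column-major, p x p); using column `a`
// for row-a lookups keeps accesses within one contiguous column.
static double bmntd_pair_mapped(const double* D, const int p,
                                const std::vector<int>& pa,
                                const std::vector<int>& pb,
                                const NumericVector& wa,
                                const NumericVector& wb,
                                std::vector<double>& bmin) {
  const int na = pa.size(), nb = pb.size();
  double sa = 0.0, sb = 0.0;
  std::fill(bmin.begin(), bmin.end(), R_PosInf);
  for (int k = 0; k < na; ++k) {
    const double* col = D + static_cast<size_t>(pa[k]) * p;
    double best = R_PosInf;
    for (int l = 0; l < nb; ++l) {
      const double d = col[pb[l]];
      if (d < best) best = d;
      if (d < bmin[l]) bmin[l] = d;
    }
    sa += wa[k] * best;
  }
  for (int l = 0; l < nb; ++l) sb += wb[l] * bmin[l];
  return 0.5 * (sa + sb);
}

// Observed betaMNTD plus null mean/sd per pair under pre-drawn
// whole-matrix tip permutations (columns of `perms`, 0-based).
// [[Rcpp::export]]
NumericMatrix bnti_engine(const NumericMatrix& D, const List& pres,
                          const List& wts, const IntegerMatrix& pairs,
                          const IntegerMatrix& perms) {
  const int npair = pairs.nrow();
  const int n_null = perms.ncol();
  const int p = D.nrow();
  const double* Dp = REAL(D);
  NumericMatrix out(npair, 3);
  std::vector<double> bmin(p);
  std::vector<int> ia, ib, pa, pb;
  for (int k = 0; k < npair; ++k) {
    const IntegerVector iav = pres[pairs(k, 0)];
    const IntegerVector ibv = pres[pairs(k, 1)];
    const NumericVector wa = wts[pairs(k, 0)];
    const NumericVector wb = wts[pairs(k, 1)];
    ia.assign(iav.begin(), iav.end());
    ib.assign(ibv.begin(), ibv.end());
    const double obs = bmntd_pair_mapped(Dp, p, ia, ib, wa, wb, bmin);
    double s = 0.0, s2 = 0.0;
    pa.resize(ia.size()); pb.resize(ib.size());
    const int* permp = INTEGER(perms);
    for (int r = 0; r < n_null; ++r) {
      const int* pr = permp + static_cast<size_t>(r) * p;
      for (size_t k2 = 0; k2 < ia.size(); ++k2) pa[k2] = pr[ia[k2]];
      for (size_t l2 = 0; l2 < ib.size(); ++l2) pb[l2] = pr[ib[l2]];
      const double v = bmntd_pair_mapped(Dp, p, pa, pb, wa, wb, bmin);
      s += v; s2 += v * v;
    }
    const double mu = s / n_null;
    const double var = (s2 - n_null * mu * mu) / (n_null - 1);
    out(k, 0) = obs;
    out(k, 1) = mu;
    out(k, 2) = var > 0 ? std::sqrt(var) : 0.0;
  }
  return out;
}
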