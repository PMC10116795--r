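#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise UniFrac distances from per-edge branch proportions.
// PT is edges x samples; bl the branch lengths. Per-sample sparse edge
// lists are merged with two pointers, so cost scales with the number of
// branches actually present rather than the full tree. Returns the
// unweighted, weighted normalized (alpha = 1) and generalized (given
// alpha) distance matrices in one pass.
// [[Rcpp::export]]
List unifrac_pairwise_cpp(NumericMatrix PT, NumericVector bl, double alpha) {
  const int E = PT.nrow(), n = PT.ncol();
  const bool half = std::abs(alpha - 0.5) < 1e-12;
  const bool one = std::abs(alpha - 1.0) < 1e-12;
  const double *p = PT.begin();
  const double *b = bl.begin();
  std::vector< std::vector<int> > idx(n);
  std::vector< std::vector<double> > val(n);
  std::vector<double> btot(n, 0.0); // total branch length present per sample
  for (int i = 0; i < n; ++i) {
    const double *pi = p + (size_t)i * E;
    for (int e = 0; e < E; ++e) {
      if (pi[e] > 0.0) {
        idx[i].push_back(e);
        val[i].push_back(pi[e]);
        btot[i] += b[e];
      }
    }
  }
  NumericMatrix Du(n, n), Dw(n, n), Dg(n, n);
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &ii = idx[i];
    const std::vector<double> &vi = val[i];
    for (int j = i + 1; j < n; ++j) {
      const std::vector<int> &jj = idx[j];
      const std::vector<double> &vj = val[j];
      double shared = 0.0;               // branch length present in both
      double numw = 0.0, denw = 0.0, numg = 0.0, deng = 0.0;
      size_t a = 0, c = 0;
      while (a < ii.size() && c < jj.size()) {
        int ea = ii[a], ec = jj[c];
        if (ea == ec) {
          double x = vi[a], y = vj[c];
          double s = x + y, d = std::fabs(x - y);
          double be = b[ea];
          shared += be;
          numw += be * d;
          denw += be * s;
          double w = one ? be * s : (half ? be * std::sqrt(s)
                                          : be * std::pow(s, alpha));
          numg += w * (d / s);
          deng += w;
          ++a; ++c;
        } else if (ea < ec) {
          double x = vi[a], be = b[ea];
          numw += be * x;
          denw += be * x;
          double w = one ? be * x : (half ? be * std::sqrt(x)
                                          : be * std::pow(x, alpha));
          numg += w;
          deng += w;
          ++a;
        } else {
          double y = vj[c], be = b[ec];
          numw += be * y;
          denw += be * y;
          double w = one ? be * y : (half ? be * std::sqrt(y)
                                          : be * std::pow(y, alpha));
          numg += w;
          deng += w;
          ++c;
        }
      }
      for (; a < ii.size(); ++a) {
        double x = vi[a], be = b[ii[a]];
        numw += be * x; denw += be * x;
        double w = one ? be * x : (half ? be * std::sqrt(x)
                                        : be * std::pow(x, alpha));
        numg += w; deng += w;
      }
      for (; c < jj.size(); ++c) {
        double y = vj[c], be = b[jj[c]];
        numw += be * y; denw += be * y;
        double w = one ? be * y : (half ? be * std::sqrt(y)
                                        : be * std::pow(y, alpha));
        numg += w; deng += w;
      }
      double uni = btot[i] + btot[j] - shared;          // union branch length
      double du = (uni > 0.0) ? (uni - shared) / uni : 0.0;
      double dw = (denw > 0.0) ? numw / denw : 0.0;
      double dg = (deng > 0.0) ? numg / deng : 0.0;
      Du(i, j) = du; Du(j, i) = du;
      Dw(i, j) = dw; Dw(j, i) = dw;
      Dg(i, j) = dg; Dg(j, i) = dg;
    }
  }
  return List::create(_["unweighted"] = Du, _["weighted"] = Dw,
                      _["generalized"] = Dg);
}

// Pairwise Bray-Curtis from a taxa x samples count matrix, exploiting
// sparsity of the count rows: D = sum |x - y| / sum (x + y).
// [[Rcpp::export]]
NumericMatrix bray_curtis_cpp(NumericMatrix XT) {
  const int q = XT.nrow(), n = XT.ncol();
  const double *p = XT.begin();
  std::vector< std::vector<int> > idx(n);
  std::vector< std::vector<double> > val(n);
  std::vector<double> tot(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *xi = p + (size_t)i * q;
    for (int t = 0; t < q; ++t) {
      if (xi[t] > 0.0) {
        idx[i].push_back(t);
        val[i].push_back(xi[t]);
        tot[i] += xi[t];
      }
    }
  }
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    const std::vector<int> &ii = idx[i];
    const std::vector<double> &vi = val[i];
    for (int j = i + 1; j < n; ++j) {
      const std::vector<int> &jj = idx[j];
      const std::vector<double> &vj = val[j];
      double num = 0.0;
      size_t a = 0, c = 0;
      while (a < ii.size() && c < jj.size()) {
        if (ii[a] == jj[c]) {
          num += std::fabs(vi[a] - vj[c]);
          ++a; ++c;
        } else if (ii[a] < jj[c]) {
          num += vi[a]; ++a;
        } else {
          num += vj[c]; ++c;
        }
      }
      for (; a < ii.size(); ++a) num += vi[a];
      for (; c < jj.size(); ++c) num += vj[c];
      double den = tot[i] + tot[j];
      double d = (den > 0.0) ? num / den : 0.0;
      D(i, j) = d; D(j, i) = d;
    }
  }
  return D;
}
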