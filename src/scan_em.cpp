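#include <Rcpp.h>
using namespace Rcpp;

// Two-penetrance binomial mixture likelihood for a binary trait in a
// backcross, maximized by EM over the latent genotype at one position.
//
//   L(p1, p0) = prod_i [ q_i * f(y_i | p1) + (1 - q_i) * f(y_i | p0) ]
//
// q_i = P(heterozygous | marker data) from the flanking-marker HMM,
// f(y|p) = p^y (1-p)^(1-y).  The null collapses to a single overall
// phenotype probability (its MLE is the phenotype mean).

static double em_loglik(const NumericVector& q, const IntegerVector& y,
                        double p1_init, double p0_init,
                        int maxit, double tol) {
  int n = q.size();
  double p1 = p1_init, p0 = p0_init;
  double ll_prev = R_NegInf, ll = R_NegInf;
  for (int it = 0; it < maxit; ++it) {
    double sw = 0.0, swy = 0.0, su = 0.0, suy = 0.0;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double f1 = y[i] ? p1 : 1.0 - p1;
      double f0 = y[i] ? p0 : 1.0 - p0;
      double a = q[i] * f1, b = (1.0 - q[i]) * f0;
      double denom = a + b;
      double w = denom > 0.0 ? a / denom : q[i];
      ll += denom > 0.0 ? std::log(denom) : -745.0;
      sw += w;  swy += w * y[i];
      su += 1.0 - w;  suy += (1.0 - w) * y[i];
    }
    p1 = sw > 0.0 ? swy / sw : 0.5;
    p0 = su > 0.0 ? suy / su : 0.5;
    if (it > 0 && std::fabs(ll - ll_prev) < tol) break;
    ll_prev = ll;
  }
  return ll;
}

// [[Rcpp::export(name = ".scan_em_cpp")]]
NumericVector scan_em_cpp(NumericMatrix probs, IntegerVector y,
                          int maxit = 1000, double tol = 1e-13,
                          int n_extra_starts = 4) {
  int n = y.size();
  int npos = probs.ncol();
  if (probs.nrow() != n) stop("probs rows must match phenotype length");

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double ll0 = 0.0;
  for (int i = 0; i < n; ++i) {
    double f = y[i] ? ybar : 1.0 - ybar;
    ll0 += f > 0.0 ? std::log(f) : -745.0;
  }

  NumericVector lod(npos);
  const double starts[4][2] = {
    {0.9, 0.1}, {0.1, 0.9}, {0.99, 0.5}, {0.5, 0.5}
  };
  for (int j = 0; j < npos; ++j) {
    NumericVector q = probs(_, j);
    // data-driven start: phenotype means weighted by genotype probability
    double sw = 0.0, swy = 0.0, su = 0.0, suy = 0.0;
    for (int i = 0; i < n; ++i) {
      sw += q[i];  swy += q[i] * y[i];
      su += 1.0 - q[i];  suy += (1.0 - q[i]) * y[i];
    }
    double p1s = sw > 0.0 ? swy / sw : ybar;
    double p0s = su > 0.0 ? suy / su : ybar;
    double best = em_loglik(q, y, p1s, p0s, maxit, tol);
    int ns = n_extra_starts < 4 ? n_extra_starts : 4;
    for (int s = 0; s < ns; ++s) {
      double ll = em_loglik(q, y, starts[s][0], starts[s][1], maxit, tol);
      if (ll > best) best = ll;
    }
    double l = (best - ll0) / std::log(10.0);
    lod[j] = l > 0.0 ? l : 0.0;
  }
  return lod;
}
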