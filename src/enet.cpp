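#include <Rcpp.h>
using namespace Rcpp;

// Soft-threshold operator used by the coordinate-descent elastic net.
static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Coordinate-descent elastic net in covariance form.
//
// Minimises (1/2n)||y - Xb||^2 + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)
// given G = X'X/n and c = X'y/n, over a decreasing lambda path with warm
// starts. Coordinates are cycled in fixed column order; convergence when the
// maximum absolute coefficient change in a sweep falls below tol.
// [[Rcpp::export(name = ".enetCdPath")]]
List enetCdPath(NumericMatrix G, NumericVector c, NumericVector lambda,
                double alpha, double tol, int maxit) {
  const int p = c.size();
  const int nlam = lambda.size();
  NumericMatrix beta(p, nlam);
  IntegerVector iters(nlam);
  LogicalVector converged(nlam);
  std::vector<double> b(p, 0.0);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    const double l1 = lam * alpha;
    const double l2 = lam * (1.0 - alpha);
    int it = 0;
    double delta = R_PosInf;
    while (it < maxit && delta >= tol) {
      delta = 0.0;
      for (int j = 0; j < p; ++j) {
        // partial residual correlation for coordinate j
        double r = c[j];
        for (int k = 0; k < p; ++k) {
          if (k != j) r -= G(j, k) * b[k];
        }
        double bj = soft(r, l1) / (G(j, j) + l2);
        double d = std::fabs(bj - b[j]);
        if (d > delta) delta = d;
        b[j] = bj;
      }
      ++it;
    }
    iters[l] = it;
    converged[l] = (delta < tol);
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = converged);
}
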