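// Extended-infomax ICA inner loop on pre-whitened data.
//
// Natural-gradient block updates with the per-component sub/super-Gaussian
// switch: dW = lrate * (block*I - K*tanh(u)*u' - u*u') * W, where K is a
// diagonal of +/-1 signs re-estimated each pass from the kurtosis proxy
// k_i = E[sech^2 u_i] E[u_i^2] - E[u_i tanh u_i]  (k > 0: super-Gaussian).
// Learning-rate annealing, weight-blowup restarts and the weight-change
// stopping rule follow the standard published algorithm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List ext_infomax_core(const arma::mat& X, int max_iter, double tol,
                            double lrate, int ext_points, int rng_seed,
                            bool extended, double anneal_deg,
                            double anneal_step) {
  const uword nc = X.n_rows;
  const uword n = X.n_cols;
  const double MAX_W = 1e8;
  const double MIN_LRATE = 1e-12;
  const double degconst = 180.0 / datum::pi;

  uword block = (uword) std::ceil(std::min(5.0 * std::log((double) n),
                                           0.3 * (double) n));
  if (block < 2) block = 2;

  std::mt19937 rng((unsigned) rng_seed);

  mat W = eye<mat>(nc, nc);
  mat oldW = W;
  vec signs = ones<vec>(nc);
  mat olddelta;
  double oldchange = 0.0;
  double wchange = datum::inf;
  bool converged = false;
  int step = 0;

  // fixed subsample for the sign estimate (deterministic given seed)
  uword npts = std::min((uword) ext_points, n);
  uvec sub(npts);
  {
    std::uniform_int_distribution<uword> pick(0, n - 1);
    for (uword i = 0; i < npts; ++i) sub(i) = pick(rng);
  }
  mat Xs = X.cols(sub);

  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;

  const mat BI = eye<mat>(nc, nc);

  while (step < max_iter) {
    std::shuffle(perm.begin(), perm.end(), rng);
    bool blowup = false;

    for (uword t = 0; t + block <= n; t += block) {
      mat Xb(nc, block);
      for (uword j = 0; j < block; ++j) Xb.col(j) = X.col(perm[t + j]);
      mat u = W * Xb;
      mat y = tanh(u);
      mat dW;
      if (extended) {
        mat K = diagmat(signs);
        dW = lrate * (((double) block) * BI - K * (y * u.t()) - u * u.t()) * W;
      } else {
        dW = lrate * (((double) block) * BI - y * u.t() - u * u.t()) * W;
      }
      W += dW;
      if (!W.is_finite() || abs(W).max() > MAX_W) { blowup = true; break; }
    }

    if (blowup) {
      lrate *= 0.9;
      if (lrate < MIN_LRATE)
        return Rcpp::List::create(Rcpp::Named("W") = W,
                                  Rcpp::Named("converged") = false,
                                  Rcpp::Named("iterations") = step,
                                  Rcpp::Named("wchange") = wchange,
                                  Rcpp::Named("signs") = signs);
      W = eye<mat>(nc, nc);
      oldW = W;
      olddelta.reset();
      oldchange = 0.0;
      step = 0;
      continue;
    }

    if (extended) {
      mat u = W * Xs;
      mat tu = tanh(u);
      vec k = mean(1.0 - square(tu), 1) % mean(square(u), 1)
              - mean(u % tu, 1);
      for (uword i = 0; i < nc; ++i) signs(i) = (k(i) >= 0) ? 1.0 : -1.0;
    }

    mat delta = W - oldW;
    double prev_wchange = wchange;
    wchange = accu(square(delta));
    oldW = W;

    // plateau guard: on a stochastic plateau the step-to-step change
    // stops shrinking; damp the learning rate so the iteration settles
    if (step > 1 && std::isfinite(prev_wchange) && wchange > prev_wchange)
      lrate *= anneal_step;

    if (step > 0 && olddelta.n_elem > 0 && wchange > 0 && oldchange > 0) {
      double c = accu(delta % olddelta) / std::sqrt(wchange * oldchange);
      c = std::max(-1.0, std::min(1.0, c));
      double angledelta = std::acos(c) * degconst;
      if (angledelta > anneal_deg) {
        lrate *= anneal_step;
        olddelta = delta;
        oldchange = wchange;
      }
    } else {
      olddelta = delta;
      oldchange = wchange;
    }

    ++step;
    if (wchange < tol) { converged = true; break; }
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = step,
                            Rcpp::Named("wchange") = wchange,
                            Rcpp::Named("signs") = signs);
}
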