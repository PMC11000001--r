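// Steady-state recurrence of the prior-knowledge signaling network and its
// backward pass (backpropagation through time). States are (samples x nodes);
// W[i, j] is the weight of edge j -> i, so one update step is
//   x <- mml(x * W^T + b + u)
// with the Michaelis-Menten-like activation
//   mml(z) = leak * z          for z < 0
//          = z                 for 0 <= z <= knot
//          = 1 - knot^2 / z    for z > knot
// which is continuous and once-differentiable at both knots.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void mml_inplace(arma::mat& z, double leak, double knot) {
  const double k2 = knot * knot;
  for (arma::uword i = 0; i < z.n_elem; ++i) {
    double v = z[i];
    if (v < 0.0) z[i] = leak * v;
    else if (v > knot) z[i] = 1.0 - k2 / v;
    // else identity
  }
}

// derivative of mml recovered from the *activation* value x (mml is strictly
// monotone, so the branch is identified by x itself):
//   x < 0      -> leak
//   x <= knot  -> 1
//   x > knot   -> (1 - x)^2 / knot^2   (since z = knot^2 / (1 - x))
static inline arma::mat mml_deriv_from_state(const arma::mat& x,
                                             double leak, double knot) {
  const double k2 = knot * knot;
  arma::mat d(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double v = x[i];
    if (v < 0.0) d[i] = leak;
    else if (v > knot) { double o = 1.0 - v; d[i] = o * o / k2; }
    else d[i] = 1.0;
  }
  return d;
}

// [[Rcpp::export(name = ".cpp_forward_rnn")]]
List cpp_forward_rnn(const arma::mat& U, const arma::mat& W,
                     const arma::vec& b, const arma::mat& x0,
                     int max_steps, int min_steps, double tol,
                     double leak, double knot, bool keep_trajectory) {
  const arma::uword n = U.n_rows, p = U.n_cols;
  arma::mat Wt = W.t();
  arma::rowvec br = b.t();
  arma::mat x = x0;
  arma::cube traj;
  if (keep_trajectory) {
    traj.set_size(n, p, max_steps + 1);
    traj.slice(0) = x;
  }
  double delta = arma::datum::inf;
  int steps = 0;
  arma::vec sample_delta(n, arma::fill::value(arma::datum::inf));
  for (int t = 1; t <= max_steps; ++t) {
    arma::mat z = x * Wt;
    z.each_row() += br;
    z += U;
    mml_inplace(z, leak, knot);
    if (!z.is_finite())
      stop("non-finite signaling state at iteration %d (divergence)", t);
    arma::mat diff = arma::abs(z - x);
    sample_delta = arma::max(diff, 1);
    delta = sample_delta.max();
    x = z;
    steps = t;
    if (keep_trajectory) traj.slice(t) = x;
    if (t >= min_steps && delta < tol) break;
  }
  List out = List::create(
      Named("state") = x,
      Named("steps") = steps,
      Named("delta") = delta,
      Named("sample_delta") = NumericVector(sample_delta.begin(), sample_delta.end()),
      Named("converged") = delta < tol);
  if (keep_trajectory) {
    arma::cube kept = traj.slices(0, steps);
    out["trajectory"] = kept;
  }
  return out;
}

// Backward pass given the stored trajectory. dxT is dL/d(final state).
// Returns gradients for W (dense, caller masks to the edge support), b and
// the per-step input U (constant across steps, so contributions accumulate).
// [[Rcpp::export(name = ".cpp_backward_rnn")]]
List cpp_backward_rnn(const arma::cube& traj, const arma::mat& W,
                      const arma::mat& dxT, double leak, double knot) {
  const arma::uword steps = traj.n_slices - 1;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::rowvec db(W.n_rows, arma::fill::zeros);
  arma::mat dU(dxT.n_rows, dxT.n_cols, arma::fill::zeros);
  arma::mat dx = dxT;
  for (arma::uword t = steps; t >= 1; --t) {
    arma::mat d = mml_deriv_from_state(traj.slice(t), leak, knot);
    arma::mat dz = dx % d;
    dW += dz.t() * traj.slice(t - 1);
    db += arma::sum(dz, 0);
    dU += dz;
    dx = dz * W;
  }
  return List::create(Named("dW") = dW,
                      Named("db") = NumericVector(db.begin(), db.end()),
                      Named("dU") = dU);
}

// Batched power iteration for the per-sample spectral radius of the
// steady-state Jacobian J_s = diag(mml'(x_s)) * W. Uses a fixed deterministic
// start vector; returns the radius estimate per sample and a convergence flag
// based on the change of the estimate over the last iteration.
// [[Rcpp::export(name = ".cpp_power_radius")]]
List cpp_power_radius(const arma::mat& states, const arma::mat& W,
                      double leak, double knot, int iters, double tol) {
  const arma::uword n = states.n_rows, p = states.n_cols;
  arma::mat D = mml_deriv_from_state(states, leak, knot); // n x p
  arma::mat V(n, p, arma::fill::ones);
  V /= std::sqrt((double)p);
  // growth rates oscillate when the dominant eigenvalue is complex; the
  // geometric mean of the per-step growth after a burn-in converges to the
  // radius in either case
  int burn = iters / 2;
  arma::vec logsum(n, arma::fill::zeros);
  arma::vec rho(n, arma::fill::zeros), prev(n, arma::fill::zeros);
  arma::mat Wt = W.t();
  int kept = 0;
  for (int it = 0; it < iters; ++it) {
    arma::mat Vn = (V * Wt) % D;       // per-sample J_s v_s
    arma::vec nr = arma::sqrt(arma::sum(arma::square(Vn), 1));
    prev = rho;
    if (it >= burn) {
      ++kept;
      for (arma::uword s = 0; s < n; ++s) {
        logsum[s] += std::log(std::max(nr[s], 1e-300));
      }
      rho = arma::exp(logsum / kept);
    } else {
      rho = nr;
    }
    for (arma::uword s = 0; s < n; ++s) {
      if (nr[s] > 1e-300) Vn.row(s) /= nr[s];
    }
    V = Vn;
  }
  arma::vec diff = arma::abs(rho - prev);
  return List::create(Named("rho") = NumericVector(rho.begin(), rho.end()),
                      Named("converged") = diff.max() <= tol,
                      Named("last_change") = diff.max());
}
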