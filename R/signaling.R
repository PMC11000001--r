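#' Michaelis-Menten-like activation function
#'
#' Piecewise activation used by the recurrent signaling network: a small
#' linear leak `beta * x` for negative input, the identity on `[0, knot]`,
#' and the saturating branch `1 - knot^2 / x` above the knot. It is
#' continuous and once-differentiable at both knots, monotone increasing,
#' and bounded above by 1, which mimics saturating dose-response behaviour
#' of signaling nodes while keeping gradients alive for negative input.
#'
#' @param x numeric vector/matrix.
#' @param leak negative-branch slope (default 0.01).
#' @param knot end of the identity region (default 0.5).
#' @return transformed values, same shape as `x`.
#' @export
mml_activation <- function(x, leak = 0.01, knot = 0.5) {
  out <- x
  neg <- x < 0
  sat <- x > knot
  out[neg] <- leak * x[neg]
  out[sat] <- 1 - knot^2 / x[sat]
  out
}

#' @rdname mml_activation
#' @details `mml_derivative` evaluates the derivative from the *activation
#'   value* (the function is strictly monotone so the branch is identified
#'   by its output): `leak` below 0, 1 on the identity region, and
#'   `(1 - y)^2 / knot^2` on the saturating branch.
#' @param y activation values (outputs of `mml_activation`).
#' @export
mml_derivative <- function(y, leak = 0.01, knot = 0.5) {
  d <- rep(1, length(y))
  dim(d) <- dim(y)
  d[y < 0] <- leak
  sat <- y > knot
  d[sat] <- (1 - y[sat])^2 / knot^2
  d
}

#' Default spectral-radius target
#'
#' `exp(log(1e-6) / max_steps)`: the contraction rate at which a geometric
#' decay reaches 1e-6 residual within the step budget.
#' @param max_steps iteration cap (default 120).
#' @return scalar in (0, 1).
#' @export
target_rho <- function(max_steps = 120) exp(log(1e-6) / max_steps)

#' Propagate drug signal to the network steady state
#'
#' Iterates `x <- mml(x %*% t(W) + b + U)` from the canonical initial state
#' (1e-3 everywhere, 0.5 on TF nodes) for at most `max_steps` steps, with an
#' early exit when the maximum absolute state change drops below `tol`.
#'
#' @param U input matrix (samples x nodes): drug signal scattered onto the
#'   drug-target nodes, zero elsewhere.
#' @param W dense weight matrix, `W[i, j]` = weight of edge j -> i.
#' @param b node bias vector.
#' @param tf_idx integer indices of TF nodes (for the initial state).
#' @param max_steps,min_steps iteration cap and floor (default 120 / 1).
#' @param tol early-exit tolerance on the max-abs state change (1e-8).
#' @param leak,knot activation parameters, see [mml_activation()].
#' @param keep_trajectory keep all intermediate states (needed for
#'   backpropagation through time).
#' @param x0 optional explicit initial state matrix.
#' @return list of class `state_trajectory`: `state` (samples x nodes),
#'   `steps`, `delta` (final max-abs change), `sample_delta`, `converged`,
#'   and `trajectory` (samples x nodes x steps+1 array) if requested.
#' @export
propagate_steady_state <- function(U, W, b, tf_idx = integer(),
                                   max_steps = 120, min_steps = 1,
                                   tol = 1e-8, leak = 0.01, knot = 0.5,
                                   keep_trajectory = FALSE, x0 = NULL) {
  U <- as.matrix(U)
  if (is.null(x0)) {
    x0 <- matrix(1e-3, nrow(U), ncol(U))
    if (length(tf_idx)) x0[, tf_idx] <- 0.5
  }
  out <- .cpp_forward_rnn(U, W, as.numeric(b), x0,
                          as.integer(max_steps), as.integer(min_steps),
                          tol, leak, knot, keep_trajectory)
  colnames(out$state) <- colnames(U)
  class(out) <- "state_trajectory"
  out
}

#' Project steady states to TF activities
#'
#' Each TF's activity is its steady-state value scaled by its projection
#' weight: `activity_i = wp_i * state_i`.
#'
#' @param steady steady-state matrix (samples x nodes).
#' @param wp projection weights, one per TF node.
#' @param tf_idx indices (or names) of TF nodes in the state columns.
#' @return samples x TFs activity matrix.
#' @export
project_to_tf <- function(steady, wp, tf_idx) {
  act <- steady[, tf_idx, drop = FALSE]
  sweep(act, 2, wp, "*")
}

#' Spectral radius of the steady-state transition Jacobian
#'
#' The Jacobian of one recurrence step at state `x` is
#' `diag(mml'(x)) %*% W`; its largest-magnitude eigenvalue governs whether
#' the iteration contracts. Estimated by power iteration from a fixed
#' deterministic start vector, batched over samples; warns (and returns the
#' last estimate) if the estimate has not stabilized.
#'
#' @param states steady-state matrix (samples x nodes) at which to linearize.
#' @param W weight matrix.
#' @param iters power-iteration steps (default 50).
#' @param tol stabilization tolerance for the warning (1e-6).
#' @inheritParams propagate_steady_state
#' @return list: `rho` (max over samples), `rho_sample` (per sample),
#'   `worst` (index of the sample attaining the max).
#' @export
spectral_radius <- function(states, W, iters = 50, tol = 1e-6,
                            leak = 0.01, knot = 0.5, warn = TRUE) {
  states <- as.matrix(states)
  out <- .cpp_power_radius(states, W, leak, knot, as.integer(iters), tol)
  if (warn && !isTRUE(out$converged)) {
    warning(sprintf("power iteration not stabilized after %d steps (last change %.2e); returning last estimate",
                    iters, out$last_change))
  }
  rho_s <- out$rho
  rho_s[rho_s < 1e-12] <- 0      # below estimator resolution
  list(rho = max(rho_s), rho_sample = rho_s, worst = which.max(rho_s))
}

#' Spectral-radius barrier loss
#'
#' Exponential barrier active only above the target radius:
#' `1e10 * (exp(10 * rho) - 1)` if `rho > target`, else 0. The target
#' `exp(log(1e-6)/120)` is the contraction rate that guarantees a 1e-6
#' steady-state residual within 120 steps.
#'
#' @inheritParams spectral_radius
#' @param target target radius (default [target_rho()]).
#' @return list: `rho`, `loss`, `worst` sample index.
#' @export
spectral_radius_loss <- function(states, W, target = target_rho(),
                                 iters = 50, leak = 0.01, knot = 0.5,
                                 warn = FALSE) {
  sr <- spectral_radius(states, W, iters = iters, leak = leak, knot = knot,
                        warn = warn)
  loss <- if (sr$rho > target) 1e10 * (exp(10 * sr$rho) - 1) else 0
  list(rho = sr$rho, loss = loss, worst = sr$worst, rho_sample = sr$rho_sample)
}

#' Sign-constraint loss on the signaling weights
#'
#' `0.1 * sum(|w|)` over weights whose sign contradicts the prior edge sign.
#' A weight of exactly zero is not a violation.
#'
#' @param w weight values (vector or matrix).
#' @param signs prior signs (+1/-1), same shape.
#' @return scalar loss.
#' @export
sign_constraint_loss <- function(w, signs) {
  viol <- (w != 0) & (sign(w) != signs)
  0.1 * sum(abs(w[viol]))
}

#' Weight regularizer avoiding both extremes and zero
#'
#' `1e-6 * sum(w^2 + 1 / (w^2 + 0.5))`: the L2 part discourages extreme
#' values while the reciprocal part (maximal at w = 0) keeps weights from
#' getting stuck at zero. Applied to both the signaling weights and the
#' drug-target weights.
#'
#' @param w weight vector.
#' @return scalar loss.
#' @export
regularize_weights <- function(w) {
  1e-6 * sum(w^2 + 1 / (w^2 + 0.5))
}

.regularize_weights_grad <- function(w) {
  1e-6 * (2 * w - 2 * w / (w^2 + 0.5)^2)
}

#' Uniform-state regularizer
#'
#' Encourages every node's steady state, viewed across conditions, to look
#' like a uniform draw on `[0, 0.99]`: the squared deviations of the
#' empirical mean, variance, max and min from the uniform ideals (0.495,
#' 0.99^2/12, 0.99, 0) are summed per node. A node whose maximum state is
#' negative has its contribution multiplied by 10. The raw sum enters the
#' composite training loss scaled by 1e-5.
#'
#' @param states steady-state matrix (conditions x nodes).
#' @param upper upper end of the target uniform interval (0.99).
#' @return list: `raw` (unscaled sum), `scaled` (`1e-5 * raw`).
#' @export
state_loss <- function(states, upper = 0.99) {
  states <- as.matrix(states)
  n <- nrow(states)
  mu <- colMeans(states)
  mx <- apply(states, 2, max)
  mn <- apply(states, 2, min)
  dev <- (mu - upper / 2)^2 + (mx - upper)^2 + mn^2
  if (n >= 2) {
    v <- apply(states, 2, stats::var)
    dev <- dev + (v - upper^2 / 12)^2
  } else {
    warning("state_loss: single condition, variance term skipped")
  }
  dev[mx < 0] <- 10 * dev[mx < 0]
  raw <- sum(dev)
  list(raw = raw, scaled = 1e-5 * raw)
}

# gradient of the *scaled* state loss w.r.t. the states
.state_loss_grad <- function(states, upper = 0.99) {
  n <- nrow(states); p <- ncol(states)
  mu <- colMeans(states)
  mx_i <- apply(states, 2, which.max)
  mn_i <- apply(states, 2, which.min)
  mx <- states[cbind(mx_i, seq_len(p))]
  mn <- states[cbind(mn_i, seq_len(p))]
  g <- matrix(0, n, p)
  g <- g + matrix(2 * (mu - upper / 2) / n, n, p, byrow = TRUE)
  if (n >= 2) {
    v <- apply(states, 2, stats::var)
    cen <- sweep(states, 2, mu)
    g <- g + sweep(cen, 2, 2 * (v - upper^2 / 12) * 2 / (n - 1), "*")
  }
  g[cbind(mx_i, seq_len(p))] <- g[cbind(mx_i, seq_len(p))] + 2 * (mx - upper)
  g[cbind(mn_i, seq_len(p))] <- g[cbind(mn_i, seq_len(p))] + 2 * mn
  tenx <- mx < 0
  if (any(tenx)) g[, tenx] <- 10 * g[, tenx]
  1e-5 * g
}

#' L2 penalties on biases and TF projection weights
#'
#' `biasLoss = 1e-6 * sum(b^2)`;
#' `projectionLoss = 1e-6 * sum((wp - 1.2)^2)` (projection weights are
#' softly centered at 1.2).
#'
#' @param b node biases.
#' @param wp TF projection weights.
#' @return list with `biasLoss` and `projectionLoss`.
#' @export
bias_projection_losses <- function(b, wp) {
  list(biasLoss = 1e-6 * sum(b^2),
       projectionLoss = 1e-6 * sum((wp - 1.2)^2))
}
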