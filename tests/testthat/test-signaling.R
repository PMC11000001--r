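test_that("mml activation matches its closed form and is monotone, bounded, continuous", {
  expect_equal(mml_activation(0.5), 0.5)     # continuity at the knot
  expect_equal(mml_activation(1), 0.75)      # 1 - 0.25/1
  expect_equal(mml_activation(-1), -0.01)    # leak branch
  expect_equal(mml_activation(0), 0)
  x <- seq(-3, 50, by = 0.01)
  y <- mml_activation(x)
  expect_true(all(diff(y) > 0))              # strictly monotone
  expect_true(all(y < 1))                    # bounded above by 1
  # continuity at both knots
  eps <- 1e-9
  expect_equal(mml_activation(-eps), mml_activation(eps), tolerance = 1e-6)
  expect_equal(mml_activation(0.5 - eps), mml_activation(0.5 + eps),
               tolerance = 1e-6)
  # derivative-from-output agrees with finite differences
  for (x0 in c(-0.7, 0.2, 0.9, 3)) {
    num <- (mml_activation(x0 + 1e-6) - mml_activation(x0 - 1e-6)) / 2e-6
    expect_equal(mml_derivative(mml_activation(x0)), num, tolerance = 1e-5)
  }
})

test_that("steady-state propagation reaches analytic fixed points", {
  # zero network: state collapses to mml(0) = 0 in one step
  r0 <- propagate_steady_state(matrix(0, 2, 3), matrix(0, 3, 3), rep(0, 3))
  expect_true(all(r0$state == 0))
  expect_true(r0$converged)

  # single self-loop node in the linear regime: x* = u / (1 - w)
  r1 <- propagate_steady_state(matrix(0.1, 1, 1), matrix(0.3, 1, 1), 0)
  expect_equal(r1$state[1, 1], 0.1 / (1 - 0.3), tolerance = 1e-7)

  # two-node chain A -> B: B* = mml(mml(u_A)) with unit weight
  W <- matrix(c(0, 1, 0, 0), 2, 2)   # W[2,1] = 1 (edge A -> B)
  u <- matrix(c(0.8, 0), 1, 2)
  r2 <- propagate_steady_state(u, W, c(0, 0))
  expect_equal(r2$state[1, 2], mml_activation(mml_activation(0.8)),
               tolerance = 1e-7)

  # canonical initial state: 1e-3 everywhere, 0.5 on TFs
  r3 <- propagate_steady_state(matrix(0, 1, 3), matrix(0, 3, 3), rep(0, 3),
                               tf_idx = 2, max_steps = 0,
                               keep_trajectory = TRUE)
  # max_steps = 0 keeps the initial state only
  expect_equal(r3$state[1, ], c(1e-3, 0.5, 1e-3))
})

test_that("spectral radius estimate matches dense eigendecomposition on toys", {
  # diagonal matrices in the linear regime (states inside [0, knot])
  st <- matrix(0.2, 1, 4)
  W <- diag(c(0.5, 0.1, 0.2, 0.05))
  sr <- spectral_radius(st, W, iters = 200)
  expect_equal(sr$rho, 0.5, tolerance = 1e-6)

  set.seed(9)
  # nonnegative matrices: real dominant eigenvalue, geometric convergence
  for (i in 1:5) {
    n <- 20
    W <- matrix(runif(n * n, 0, 0.05), n, n)
    st <- matrix(runif(n, 0, 0.4), 1, n)   # linear regime, derivative = 1
    oracle <- max(Mod(eigen(W)$values))
    est <- suppressWarnings(spectral_radius(st, W, iters = 500))$rho
    expect_equal(est, oracle, tolerance = 1e-6)
  }
  # general matrices (complex dominant pairs): growth-rate averaging still
  # tracks the radius, to within the averaging resolution
  for (i in 1:5) {
    n <- 20
    W <- matrix(rnorm(n * n, 0, 0.08), n, n)
    st <- matrix(runif(n, 0, 0.4), 1, n)
    oracle <- max(Mod(eigen(W)$values))
    est <- suppressWarnings(spectral_radius(st, W, iters = 2000))$rho
    expect_equal(est, oracle, tolerance = 1e-2)
  }
})

test_that("spectral barrier is zero below target and explodes above", {
  st <- matrix(0.2, 1, 3)
  expect_equal(spectral_radius_loss(st, matrix(0, 3, 3))$loss, 0)
  sr <- spectral_radius_loss(st, diag(0.5, 3), iters = 200)
  expect_equal(sr$rho, 0.5, tolerance = 1e-6)
  expect_equal(sr$loss, 0)                      # 0.5 < target
  sr2 <- spectral_radius_loss(st, diag(0.95, 3), iters = 200)
  expect_equal(sr2$rho, 0.95, tolerance = 1e-6)
  expect_equal(sr2$loss, 1e10 * (exp(10 * 0.95) - 1), tolerance = 1e-4)
  # the target radius closed form
  expect_equal(target_rho(), exp(log(1e-6) / 120))
  expect_equal(target_rho(), 0.8912509, tolerance = 1e-6)
})

test_that("auxiliary losses reproduce hand-computed values", {
  # sign constraint: 0.1 * sum |w| over violations; zero is not a violation
  expect_equal(sign_constraint_loss(c(0.5, -0.4), c(1, 1)), 0.04)
  expect_equal(sign_constraint_loss(c(0.5, 0.4), c(1, 1)), 0)
  expect_equal(sign_constraint_loss(c(0, -0.3), c(1, -1)), 0)
  expect_equal(sign_constraint_loss(c(-0.2, 0.3), c(1, -1)), 0.1 * 0.5)

  # weight regularizer: values at 0 and 1, and interior minimum (grid oracle)
  expect_equal(regularize_weights(0), 2e-6)
  expect_equal(regularize_weights(1), 1e-6 * (1 + 1 / 1.5))
  grid <- seq(0, 2, by = 1e-4)
  vals <- 1e-6 * (grid^2 + 1 / (grid^2 + 0.5))
  wmin <- grid[which.min(vals)]
  expect_gt(wmin, 0.1)                         # minimum away from zero
  expect_lt(regularize_weights(wmin), regularize_weights(0))

  # bias / projection losses
  bp <- bias_projection_losses(b = c(0, 0), wp = c(1.2, 1.2))
  expect_equal(bp$biasLoss, 0)
  expect_equal(bp$projectionLoss, 0)
  bp2 <- bias_projection_losses(b = 0.5, wp = c(1.0, 1.4))
  expect_equal(bp2$biasLoss, 1e-6 * 0.25)
  expect_equal(bp2$projectionLoss, 8e-8)
})

test_that("state loss reproduces the uniform-moment deviations", {
  # constant states at the uniform mean: only var/max/min terms deviate
  st <- matrix(0.495, 4, 2)
  sl <- state_loss(st)
  per_node <- (0.99^2 / 12)^2 + (0.495 - 0.99)^2 + 0.495^2
  expect_equal(sl$raw, 2 * per_node, tolerance = 1e-12)
  expect_equal(sl$scaled, 1e-5 * sl$raw)

  # dense uniform grid: deviations vanish as the grid densifies
  g <- matrix(seq(0, 0.99, length.out = 2000), ncol = 1)
  expect_lt(state_loss(g)$raw, 1e-4)

  # all-negative states: factor-10 penalty
  neg <- matrix(-0.1, 4, 1)
  pos <- matrix(0.1, 4, 1)
  raw_pos <- state_loss(pos)$raw
  raw_neg <- state_loss(neg)$raw
  manual_neg <- 10 * ((0.1 + 0.495)^2 + (0.99^2 / 12)^2 + (0.1 + 0.99)^2 + 0.1^2)
  expect_equal(raw_neg, manual_neg, tolerance = 1e-12)
  expect_gt(raw_neg, raw_pos)

  # single condition: variance skipped with a warning
  expect_warning(state_loss(matrix(0.3, 1, 2)), "variance")
})

test_that("TF projection scales steady states elementwise", {
  st <- matrix(c(0.5, 0.2, 0.8, 0.4), 2, 2)
  expect_equal(project_to_tf(st, c(1, 1), 1:2), st)
  expect_equal(project_to_tf(st, c(1.2, 1), 1:2)[1, 1], 0.6)
  expect_true(all(project_to_tf(st, c(0, 0), 1:2) == 0))
})

test_that("converged recurrences satisfy the 120-step residual bound", {
  fx <- fixture_small()
  tm <- fixture_trained()
  m <- tm$model
  fw <- model_forward(m, fx$sim$conditions)
  # contraction: residual at the final step below 1e-6
  tr <- propagate_steady_state(
    moanet:::.scatter_signal(m, fw$S), m$W, m$b, tf_idx = m$tf_idx,
    max_steps = 120, min_steps = 120, tol = 0)
  expect_lt(tr$delta, 1e-6)
  sr <- suppressWarnings(spectral_radius(tr$state, m$W, iters = 200))
  expect_lt(sr$rho, 1)
})
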