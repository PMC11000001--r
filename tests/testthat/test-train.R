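test_that("loss breakdown satisfies the composite-sum identity", {
  fx <- fixture_small()
  m <- build_model(fx$net, fx$prior, fx$gt$Wsim, init_seed = 3)
  fw <- model_forward(m, fx$sim$conditions)
  lb <- total_loss(m, fw$Y, fx$sim$Y, fw$traj$state)
  expect_equal(lb$total,
               lb$fitLoss + lb$signConstraint + lb$biasLoss + lb$NetWeightLoss +
                 lb$DTLoss + lb$DTregularization + 1e-3 * lb$spectralRadiusLoss +
                 lb$stateLoss + lb$projectionLoss,
               tolerance = 1e-12)
  expect_equal(lb$stateLoss, 1e-5 * lb$stateLoss_raw)
  expect_equal(lb$fitLoss, mean((fw$Y - fx$sim$Y)^2))

  # perfect fit with identity similarity scaler: fit and DT terms vanish
  lb2 <- total_loss(m, fx$sim$Y, fx$sim$Y, fw$traj$state)
  expect_equal(lb2$fitLoss, 0)
  expect_equal(lb2$DTregularization, 0)     # Wdrug initialized at identity

  # adding one violated sign raises the total by exactly 0.1 * |w|
  m3 <- m
  ei <- which(m3$W_mask & m3$W_sign == 1)[1]
  m3$W[ei] <- -0.4
  lb3a <- total_loss(m3, fw$Y, fx$sim$Y, fw$traj$state)
  m4 <- m3; m4$W[ei] <- 0.4
  lb4 <- total_loss(m4, fw$Y, fx$sim$Y, fw$traj$state)
  expect_equal(lb3a$signConstraint - lb4$signConstraint, 0.1 * 0.4)
})

test_that("the loss identity holds at every logged epoch", {
  tm <- fixture_trained()
  lg <- tm$log
  lhs <- lg$total
  rhs <- lg$fitLoss + lg$signConstraint + lg$biasLoss + lg$NetWeightLoss +
    lg$DTLoss + lg$DTregularization + 1e-3 * lg$spectralRadiusLoss +
    lg$stateLoss + lg$projectionLoss
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("training reduces the fit loss and is seed-deterministic", {
  fx <- fixture_small()
  cfg <- train_config(epochs = 150, seed = 5)
  tm1 <- train_model(fx$sim$conditions, fx$sim$Y, fx$net, fx$prior, fx$gt$Wsim,
                     config = cfg)
  expect_lt(tail(tm1$log$fitLoss, 1), tm1$log$fitLoss[1])
  tm2 <- train_model(fx$sim$conditions, fx$sim$Y, fx$net, fx$prior, fx$gt$Wsim,
                     config = cfg)
  expect_identical(moanet:::.get_params(tm1$model),
                   moanet:::.get_params(tm2$model))
  expect_identical(predict(tm1, fx$sim$conditions),
                   predict(tm2, fx$sim$conditions))
  # final spectral radius below 1 (stability goal)
  fw <- model_forward(tm1$model, fx$sim$conditions)
  sr <- suppressWarnings(spectral_radius(fw$traj$state, tm1$model$W, iters = 200))
  expect_lt(sr$rho, 1)
})

test_that("checkpoints reload to bit-identical eval predictions", {
  fx <- fixture_small()
  tm <- fixture_trained()
  f <- tempfile(fileext = ".rds")
  write_checkpoint(tm$model, f)
  back <- read_checkpoint(f)
  expect_identical(predict(back, fx$sim$conditions),
                   predict(tm$model, fx$sim$conditions))
  fj <- tempfile(fileext = ".json")
  export_checkpoint_json(tm$model, fj)
  expect_true(jsonlite::validate(paste(readLines(fj), collapse = "")))
  expect_error(read_checkpoint(tempfile()), "")
})

test_that("ensembles average member predictions and tolerate distinct seeds", {
  fx <- fixture_small()
  cfg <- train_config(epochs = 60, ensemble_size = 3, seed = 21)
  ens <- train_ensemble(fx$sim$conditions, fx$sim$Y, fx$net, fx$prior,
                        fx$gt$Wsim, config = cfg)
  expect_length(ens$members, 3)
  preds <- lapply(ens$members, function(m) predict(m$model, fx$sim$conditions))
  expect_equal(predict(ens, fx$sim$conditions), Reduce(`+`, preds) / 3)
  # distinct seeds give distinct members
  expect_gt(max(abs(preds[[1]] - preds[[2]])), 0)
  # an ensemble of one equals its single member
  ens1 <- train_ensemble(fx$sim$conditions, fx$sim$Y, fx$net, fx$prior,
                         fx$gt$Wsim,
                         config = train_config(epochs = 60, seed = 21), size = 1)
  expect_equal(predict(ens1, fx$sim$conditions),
               predict(ens1$members[[1]]$model, fx$sim$conditions))
})

test_that("shuffle nulls permute rows reproducibly and preserve marginals", {
  fx <- fixture_small()
  s1 <- shuffle_null(fx$sim$conditions, fx$sim$Y, "shuffle_X", seed = 4)
  s2 <- shuffle_null(fx$sim$conditions, fx$sim$Y, "shuffle_X", seed = 4)
  expect_identical(s1$permutation, s2$permutation)
  expect_equal(colMeans(s1$conditions$X), colMeans(fx$sim$conditions$X))
  expect_identical(s1$Y, fx$sim$Y)
  sy <- shuffle_null(fx$sim$conditions, fx$sim$Y, "shuffle_Y", seed = 4)
  expect_equal(sort(as.vector(sy$Y)), sort(as.vector(fx$sim$Y)))
  expect_identical(sy$conditions$X, fx$sim$conditions$X)
  # n = 1: nothing to permute
  one <- shuffle_null(list(X = fx$sim$conditions$X[1, , drop = FALSE],
                           drug = fx$sim$conditions$drug[1]),
                      fx$sim$Y[1, , drop = FALSE], "shuffle_Y", seed = 1)
  expect_identical(one$Y, fx$sim$Y[1, , drop = FALSE])
})

test_that("per-TF performance matches the textbook correlation formula", {
  set.seed(31)
  obs <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  pred <- obs + matrix(rnorm(15, 0, 0.3), 5, 3)
  perf <- per_tf_performance(pred, obs)
  for (j in 1:3) {
    x <- pred[, j]; y <- obs[, j]
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(perf$r[j], r_hand, tolerance = 1e-12)
  }
  expect_equal(perf$p_adj, p.adjust(perf$p, "BH"))
  # perfect / anti-perfect predictions
  expect_equal(per_tf_performance(obs, obs)$r, rep(1, 3), tolerance = 1e-12)
  expect_equal(per_tf_performance(-obs, obs)$r, rep(-1, 3), tolerance = 1e-12)
  # zero-variance TF flagged, not dropped
  pred2 <- pred; pred2[, 2] <- 1
  perf2 <- per_tf_performance(pred2, obs)
  expect_true(perf2$undefined[2])
  expect_equal(nrow(perf2), 3)
})

test_that("frozen-drug-module transfer keeps the drug module bit-identical", {
  fx <- fixture_small()
  src <- fixture_trained()
  before <- list(Wdrug = src$model$dm$Wdrug, WDT = src$model$dm$WDT,
                 bn = src$model$dm$bn[c("gamma", "beta", "rmean", "rvar")])
  # second synthetic dataset from the same ground truth (new noise draw)
  sim2 <- simulate_dataset(fx$gt, seed = 99)
  cv <- frozen_drug_module_cv(
    src, list(list(conditions = sim2$conditions, Y = sim2$Y)),
    sim = fx$gt$Wsim, k = 2, test_fraction = 0.4,
    config = train_config(epochs = 60, seed = 31))
  tm2 <- train_model(sim2$conditions$X, sim2$Y,
                     config = train_config(epochs = 60, seed = 77),
                     model = src$model,
                     freeze = c("Wdrug", "WDT", "gamma", "beta"))
  after <- list(Wdrug = tm2$model$dm$Wdrug, WDT = tm2$model$dm$WDT,
                bn = tm2$model$dm$bn[c("gamma", "beta", "rmean", "rvar")])
  expect_identical(before, after)
  # the CV table reports per-TF train and validation correlations
  expect_true(all(c("tf", "train_r", "val_r", "train_rank", "val_rank")
                  %in% names(cv)))
  expect_true(all(cv$achieved_test_fraction > 0))
})

test_that("rescale_tf_activity maps to (0,1) with median near one half", {
  set.seed(12)
  Y <- matrix(rnorm(200, 5, 3), 50, 4)
  Z <- rescale_tf_activity(Y)
  expect_true(all(Z > 0 & Z < 1))
  expect_equal(as.vector(apply(Z, 2, median)), rep(0.5, 4), tolerance = 0.1)
  # monotone per column
  ord <- order(Y[, 1])
  expect_true(all(diff(Z[ord, 1]) >= 0))
})
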