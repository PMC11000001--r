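test_that("integrated gradients are exact for linear maps at any step count", {
  A <- matrix(c(2, -1, 0.5, 3, 0, -2), 2, 3)    # outputs x inputs
  x <- c(1, 0.5, -2)
  for (m in c(2, 4, 64)) {
    attr_mat <- integrated_gradients_fn(function(z) A, x, m = m)
    expect_equal(attr_mat, sweep(A, 2, x, "*"), tolerance = 1e-12)
  }
  # completeness: attributions sum to F(x) - F(0) for the linear map
  expect_equal(rowSums(integrated_gradients_fn(function(z) A, x, m = 8)),
               as.vector(A %*% x))
  expect_error(integrated_gradients_fn(function(z) A, x, m = 1), ">= 2")
})

test_that("integrated gradients converge to a dense trapezoid oracle on a nonlinear head", {
  # F(x) = tanh(A x) elementwise; Jacobian = diag(1 - tanh^2) %*% A
  A <- matrix(c(1.5, -0.7, 0.3, 0.8), 2, 2)
  jac <- function(x) (1 - tanh(as.vector(A %*% x))^2) * A
  x <- c(0.9, -1.4)
  # dense trapezoid quadrature of the path integral
  K <- 20001
  al <- seq(0, 1, length.out = K)
  J <- matrix(0, 2, 2)
  for (k in seq_len(K)) {
    w <- if (k == 1 || k == K) 0.5 else 1
    J <- J + w * jac(al[k] * x)
  }
  oracle <- sweep(J / (K - 1), 2, x, "*")
  coarse <- integrated_gradients_fn(jac, x, m = 4)
  fine <- integrated_gradients_fn(jac, x, m = 4096)
  expect_equal(fine, oracle, tolerance = 1e-4)
  expect_gt(max(abs(coarse - oracle)), max(abs(fine - oracle)))
})

test_that("drug-module attribution equals effective weights times dose", {
  fx <- fixture_small()
  m <- build_model(fx$net, fx$prior, fx$gt$Wsim)
  m$dm$bn$rmean <- runif(length(m$dm$drug_ids))
  m$dm$bn$rvar <- runif(length(m$dm$drug_ids), 0.5, 2)
  drug <- m$dm$drug_ids[1]
  sc <- integrated_gradients(m, drug, dose = 0.7, m = 16)
  eff <- moanet:::.drug_module_jacobian(m$dm)
  expect_equal(unname(sc), unname(0.7 * eff[1, ]), tolerance = 1e-12)
  # zero dose: all scores vanish
  expect_true(all(integrated_gradients(m, drug, dose = 0) == 0))
  # invariance to m for the affine module
  expect_equal(integrated_gradients(m, drug, dose = 0.7, m = 2), sc)
  expect_error(integrated_gradients(m, "nope"), "unknown drug")
})

test_that("error curve is flat for drug-blind models and steps up for planted effects", {
  fx <- fixture_small()
  # a model that ignores drugs: zero drug-target weights
  m <- build_model(fx$net, fx$prior, fx$gt$Wsim)
  m$dm$WDT[] <- 0
  ec <- error_curve_cutoff(m, NULL, fx$sim$conditions, fx$sim$Y)
  expect_true(all(is.na(ec$cutoff)))
  expect_false(any(ec$inferred))
  expect_true(all(abs(ec$curve$rel_increase) < 1e-8))

  # trained model: removing the dominant channel raises the per-drug MAE by >= 25%
  tm <- fixture_trained()
  ec2 <- error_curve_cutoff(tm, NULL, fx$sim$conditions, fx$sim$Y)
  expect_true(any(ec2$inferred))
  # inferred entries all have |score| >= their drug cutoff
  sc <- ec2$scores
  for (d in rownames(sc)) {
    if (!is.na(ec2$cutoff[d])) {
      expect_true(all(abs(sc[d, ec2$inferred[d, ]]) >= ec2$cutoff[d]))
    } else {
      expect_false(any(ec2$inferred[d, ]))
    }
  }
})

test_that("ensemble frequency is the fraction of models inferring each pair", {
  m1 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  f <- ensemble_frequency(list(m1, m2))
  expect_equal(f, (m1 + m2) / 2)
  expect_true(all(f %in% c(0, 0.5, 1)))
  expect_equal(ensemble_frequency(list(m1)), m1 * 1)
  # 44 of 50 models
  sets <- c(replicate(44, matrix(TRUE, 1, 1), simplify = FALSE),
            replicate(6, matrix(FALSE, 1, 1), simplify = FALSE))
  expect_equal(as.vector(ensemble_frequency(sets)), 0.88)
})

test_that("interaction metrics match brute-force set arithmetic on random instances", {
  set.seed(123)
  for (rep in 1:100) {
    d <- 20; t <- 10
    uni <- expand.grid(drug = paste0("d", 1:d), target = paste0("t", 1:t),
                       stringsAsFactors = FALSE)
    truth <- matrix(runif(d * t) < 0.08, d, t,
                    dimnames = list(paste0("d", 1:d), paste0("t", 1:t)))
    inferred <- matrix(runif(d * t) < 0.1, d, t, dimnames = dimnames(truth))
    pri_idx <- which(truth & (runif(d * t) < 0.5))
    prior <- data.frame(drug = rownames(truth)[row(truth)[pri_idx]],
                        target = colnames(truth)[col(truth)[pri_idx]])
    mt <- interaction_metrics(inferred, truth, prior)
    # independent oracle via raw set operations on pair keys
    key <- function(m) paste(rownames(m)[row(m)[m]], colnames(m)[col(m)[m]])
    ti <- key(truth); ii <- key(inferred)
    all_keys <- paste(uni$drug, uni$target)
    tp <- length(intersect(ii, ti))
    fp <- length(setdiff(ii, ti))
    fn <- length(setdiff(ti, ii))
    tn <- length(all_keys) - tp - fp - fn
    expect_equal(c(mt$TP, mt$FP, mt$FN, mt$TN), c(tp, fp, fn, tn))
    expect_equal(mt$accuracy, (tp + tn) / length(all_keys))
    nir <- max(length(ti), length(all_keys) - length(ti)) / length(all_keys)
    expect_equal(mt$NIR, nir)
    expect_equal(mt$p_accuracy_vs_NIR,
                 binom.test(tp + tn, length(all_keys), nir,
                            alternative = "greater")$p.value)
    if (length(ii) > 0) {
      expect_equal(mt$precision, tp / length(ii))
      pk <- paste(prior$drug, prior$target)
      expect_equal(mt$NDR, length(setdiff(ii, pk)) / length(ii))
    }
    if (length(ti) > 0) expect_equal(mt$recall, tp / length(ti))
    if (!is.na(mt$F1)) {
      expect_equal(mt$F1, 2 * mt$precision * mt$recall / (mt$precision + mt$recall))
    }
    if (!is.na(mt$G_mean)) {
      expect_equal(mt$G_mean, sqrt(mt$recall * (tn / (tn + fp))))
    }
  }
})

test_that("F1 of precision 1 and recall 0.5 is 2/3", {
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  inferred <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2,
                     dimnames = dimnames(truth))
  mt <- interaction_metrics(inferred, truth)
  expect_equal(mt$precision, 1)
  expect_equal(mt$recall, 0.5)
  expect_equal(mt$F1, 2 / 3)
  # perfect recovery: accuracy 1, NDR 0, TPR 1, F1 1
  prior <- data.frame(drug = c("a", "b"), target = c("x", "x"))
  mt2 <- interaction_metrics(truth, truth, prior)
  expect_equal(mt2$accuracy, 1)
  expect_equal(mt2$F1, 1)
  expect_equal(mt2$NDR, 0)
  expect_equal(mt2$TPR_prior, 1)
  # empty truth flags recall as undefined
  expect_warning(
    mt3 <- interaction_metrics(inferred, truth & FALSE), "empty truth")
  expect_true(is.na(mt3$recall))
})
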