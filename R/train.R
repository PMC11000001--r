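#' Training configuration
#'
#' Defaults follow the reference training protocol: 5000 epochs of Adam on
#' minibatches of 25 with a one-cycle learning rate between `lr_min` and
#' `lr_max` (linear warm-up over the first 40% of epochs, cosine decay back
#' to `lr_min`); spectral-radius term weighted 1e-3 and state term 1e-5 in
#' the composite loss (fixed inside the loss formulas).
#'
#' @param epochs,batch_size,lr_min,lr_max,ensemble_size,seed training knobs.
#' @param lambda_DT drug-target inference regularization (see
#'   [dt_regularization()]).
#' @param warmup_frac fraction of epochs spent warming the learning rate up.
#' @param ... further entries stored verbatim.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 5000, batch_size = 25, lr_min = 1e-8,
                         lr_max = 2e-3, lambda_DT = 5e-3, ensemble_size = 50,
                         seed = 1, warmup_frac = 0.4, ...) {
  stopifnot(epochs >= 1, batch_size >= 1, ensemble_size >= 1, lr_min < lr_max)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_min = lr_min, lr_max = lr_max, lambda_DT = lambda_DT,
                 ensemble_size = as.integer(ensemble_size), seed = seed,
                 warmup_frac = warmup_frac, ...), class = "train_config")
}

.onecycle_lr <- function(epoch, epochs, lr_min, lr_max, warmup_frac = 0.4) {
  warm <- max(1, round(warmup_frac * epochs))
  if (epoch <= warm) {
    lr_min + (lr_max - lr_min) * epoch / warm
  } else {
    frac <- (epoch - warm) / max(1, epochs - warm)
    lr_min + (lr_max - lr_min) * (1 + cos(pi * frac)) / 2
  }
}

#' Composite loss breakdown
#'
#' Evaluates every term of the training loss for given predictions and model
#' state:
#' `total = fitLoss + signConstraint + biasLoss + NetWeightLoss + DTLoss +
#'  DTregularization + 1e-3 * spectralRadiusLoss + stateLoss +
#'  projectionLoss`,
#' where `fitLoss` is the MSE across TFs averaged over the batch,
#' `spectralRadiusLoss` is stored unweighted (the 1e-3 coefficient is applied
#' in the sum) and `stateLoss` is stored with its 1e-5 scaling already
#' applied (`stateLoss_raw` keeps the unscaled value).
#'
#' @param model a `dtn_model`.
#' @param pred predicted TF activities (samples x TFs).
#' @param obs observed TF activities, same shape.
#' @param states steady-state matrix of the same forward pass.
#' @return list of class `loss_breakdown`.
#' @export
total_loss <- function(model, pred, obs, states) {
  fit <- mean((pred - obs)^2)
  wv <- model$W[model$W_mask]
  sgn <- sign_constraint_loss(wv, model$W_sign[model$W_mask])
  bp <- bias_projection_losses(model$b, model$wp)
  nwl <- regularize_weights(wv)
  dtl <- regularize_weights(model$dm$WDT[model$dm$WDT_mask])
  dtr <- dt_regularization(model$dm$Wdrug, model$dm$lambda_DT)
  sp <- spectral_radius_loss(states, model$W, target = model$config$target_rho,
                             iters = model$config$power_iters,
                             leak = model$config$leak, knot = model$config$knot)
  st <- state_loss(states)
  terms <- list(fitLoss = fit, signConstraint = sgn, biasLoss = bp$biasLoss,
                NetWeightLoss = nwl, DTLoss = dtl, DTregularization = dtr,
                spectralRadiusLoss = sp$loss, stateLoss = st$scaled,
                projectionLoss = bp$projectionLoss)
  bad <- names(terms)[!vapply(terms, is.finite, TRUE)]
  if (length(bad)) stop("non-finite loss term(s): ", paste(bad, collapse = ", "))
  terms$stateLoss_raw <- st$raw
  terms$rho <- sp$rho
  terms$total <- fit + sgn + bp$biasLoss + nwl + dtl + dtr +
    1e-3 * sp$loss + st$scaled + bp$projectionLoss
  structure(terms, class = "loss_breakdown")
}

# Full loss + gradients on one batch. Returns list(loss = breakdown,
# grads = list(Wdrug, WDT, gamma, beta, W, b, wp), model (bn state updated)).
.loss_and_grads <- function(model, X, Y, training = TRUE) {
  fwd <- model_forward(model, X, training = training, cache = TRUE)
  model <- fwd$model
  states <- fwd$traj$state
  n <- nrow(states)
  loss <- total_loss(model, fwd$Y, Y, states)

  # --- fit + state loss gradient w.r.t. final state
  dY <- 2 * (fwd$Y - Y) / length(Y)
  dwp <- colSums(dY * states[, model$tf_idx, drop = FALSE])
  dxT <- matrix(0, n, length(model$nodes))
  dxT[, model$tf_idx] <- sweep(dY, 2, model$wp, "*")
  dxT <- dxT + .state_loss_grad(states)

  bk <- .cpp_backward_rnn(fwd$traj$trajectory, model$W, dxT,
                          model$config$leak, model$config$knot)
  dW <- bk$dW
  dW[!model$W_mask] <- 0
  db <- bk$db
  dS <- bk$dU[, model$target_idx, drop = FALSE]
  dg <- .drug_backward(model$dm, fwd$drug_fw, dS)

  # --- regularizer gradients
  wv_mask <- model$W_mask
  viol <- wv_mask & (model$W != 0) & (sign(model$W) != model$W_sign)
  dW[viol] <- dW[viol] + 0.1 * sign(model$W[viol])
  dW[wv_mask] <- dW[wv_mask] + .regularize_weights_grad(model$W[wv_mask])
  db <- db + 2e-6 * model$b
  dwp <- dwp + 2e-6 * (model$wp - 1.2)
  dWDT <- dg$dWDT
  dWDT[model$dm$WDT_mask] <- dWDT[model$dm$WDT_mask] +
    .regularize_weights_grad(model$dm$WDT[model$dm$WDT_mask])
  dWdrug <- dg$dWdrug
  if (is.infinite(model$dm$lambda_DT)) {
    dWdrug[] <- 0
  } else {
    dWdrug <- dWdrug + 2 * model$dm$lambda_DT *
      (model$dm$Wdrug - diag(1, nrow(model$dm$Wdrug)))
  }

  # --- spectral barrier gradient (only when the barrier is active)
  if (loss$spectralRadiusLoss > 0) {
    worst <- which.max(spectral_radius(states, model$W,
                                       iters = model$config$power_iters,
                                       leak = model$config$leak,
                                       knot = model$config$knot,
                                       warn = FALSE)$rho_sample)
    d <- mml_derivative(states[worst, ], leak = model$config$leak,
                        knot = model$config$knot)
    J <- d * model$W
    eg <- eigen(J)
    k <- which.max(Mod(eg$values))
    lam <- eg$values[k]
    v <- eg$vectors[, k]
    ul <- eigen(t(J))
    ku <- which.max(Mod(ul$values))
    uvec <- ul$vectors[, ku]
    denom <- sum(Conj(uvec) * v)
    if (Mod(denom) > 1e-12 && Mod(lam) > 1e-12) {
      dlam_dJ <- outer(Conj(uvec), v) / denom        # d lambda / dJ[i,j]
      drho_dJ <- Re(Conj(lam) / Mod(lam) * dlam_dJ)
      dloss_drho <- 1e-3 * 1e10 * 10 * exp(10 * Mod(lam))
      dW_sp <- dloss_drho * drho_dJ * d              # chain through J = d * W
      dW_sp[!model$W_mask] <- 0
      dW <- dW + dW_sp
    }
  }

  list(loss = loss,
       grads = list(Wdrug = dWdrug, WDT = dWDT, dgamma = dg$dgamma,
                    dbeta = dg$dbeta, W = dW, b = db, wp = dwp),
       model = model, pred = fwd$Y, states = states)
}

.adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       skip = character()) {
  st$t <- st$t + 1L
  for (nm in names(p)) {
    if (nm %in% skip) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, st = st)
}

#' Train a single model
#'
#' Minibatch Adam on the composite loss, deterministic for a given seed.
#' Batches are sampled without replacement and reshuffled every epoch. On a
#' non-finite loss the run aborts and returns the last finite-loss
#' checkpoint.
#'
#' @param conditions a [condition_table()] (or plain dose matrix).
#' @param Y observed TF-activity matrix (samples x TFs), on the `[0, 1]`
#'   scale (see [rescale_tf_activity()]).
#' @param net trimmed [signaling_network()].
#' @param prior drug-target prior data.frame.
#' @param sim similarity matrix.
#' @param config a [train_config()].
#' @param seed integer seed controlling initialization, batching and dropout.
#' @param model optional pre-built / pre-trained `dtn_model` to continue
#'   from (then `net`, `prior`, `sim` are ignored).
#' @param freeze parameter names excluded from updates (e.g.
#'   `c("Wdrug", "WDT", "gamma", "beta")` to freeze the drug module).
#' @param verbose print progress every `verbose` epochs (0 = silent).
#' @return list of class `trained_model`: `model`, `log` (per-epoch loss
#'   breakdown data.frame), `seed`, `config`.
#' @export
train_model <- function(conditions, Y, net = NULL, prior = NULL, sim = NULL,
                        config = train_config(), seed = config$seed,
                        model = NULL, freeze = character(), verbose = 0) {
  X <- if (inherits(conditions, "condition_table")) conditions$X else as.matrix(conditions)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.null(model)) {
    model <- build_model(net, prior, sim, lambda_DT = config$lambda_DT,
                         init_seed = seed)
  }
  if (is.infinite(model$dm$lambda_DT)) freeze <- union(freeze, "Wdrug")
  drug_frozen <- all(c("Wdrug", "WDT", "gamma", "beta") %in% freeze)
  p <- .get_params(model)
  ad <- .adam_init(p)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  log <- vector("list", config$epochs)
  last_good <- model
  for (epoch in seq_len(config$epochs)) {
    lr <- .onecycle_lr(epoch, config$epochs, config$lr_min, config$lr_max,
                       config$warmup_frac)
    ord <- sample.int(n)
    nb <- ceiling(n / bs)
    acc <- NULL
    failed <- FALSE
    for (bi in seq_len(nb)) {
      idx <- ord[seq((bi - 1) * bs + 1, min(bi * bs, n))]
      res <- tryCatch(
        .loss_and_grads(model, X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                        training = !drug_frozen),
        error = function(e) e)
      if (inherits(res, "error") || !is.finite(res$loss$total)) {
        warning(sprintf("training diverged at epoch %d; returning last finite checkpoint", epoch))
        failed <- TRUE
        break
      }
      model <- res$model
      g <- res$grads
      names(g) <- c("Wdrug", "WDT", "gamma", "beta", "W", "b", "wp")
      upd <- .adam_step(p, g, ad, lr, skip = freeze)
      p <- upd$p; ad <- upd$st
      model <- .set_params(model, p)
      bb <- unclass(res$loss)
      acc <- if (is.null(bb)) acc else if (is.null(acc)) {
        lapply(bb, function(x) x / nb)
      } else mapply(function(a, x) a + x / nb, acc, bb, SIMPLIFY = FALSE)
    }
    if (failed) { model <- last_good; break }
    last_good <- model
    log[[epoch]] <- c(epoch = epoch, lr = lr, unlist(acc))
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %4d  loss %.5g  fit %.5g  rho %.3f",
                      epoch, acc$total, acc$fitLoss, acc$rho))
    }
  }
  log <- as.data.frame(do.call(rbind, log[!vapply(log, is.null, TRUE)]))
  structure(list(model = model, log = log, seed = seed, config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model (seed %s): %d epochs, final fitLoss %.4g\n",
              format(x$seed), nrow(x$log),
              if (nrow(x$log)) x$log$fitLoss[nrow(x$log)] else NA))
  invisible(x)
}

#' @export
predict.trained_model <- function(object, newdata, ...) {
  predict(object$model, newdata)
}

#' Train an ensemble of models
#'
#' Members are trained with consecutive distinct seeds; the ensemble
#' prediction is the mean of member predictions. A member whose training
#' fails is recorded; the ensemble proceeds if at least 80% of members
#' succeed.
#'
#' @inheritParams train_model
#' @param size number of members (defaults to `config$ensemble_size`).
#' @return list of class `dtn_ensemble`: `members` (trained models),
#'   `failed` (seeds of failed members), `config`.
#' @export
train_ensemble <- function(conditions, Y, net = NULL, prior = NULL, sim = NULL,
                           config = train_config(), size = config$ensemble_size,
                           model = NULL, freeze = character(), verbose = 0) {
  seeds <- config$seed + seq_len(size) - 1
  members <- list(); failed <- integer()
  for (s in seeds) {
    tm <- tryCatch(
      train_model(conditions, Y, net, prior, sim, config = config, seed = s,
                  model = model, freeze = freeze, verbose = verbose),
      error = function(e) e)
    if (inherits(tm, "error")) failed <- c(failed, s) else members <- c(members, list(tm))
  }
  if (length(members) < 0.8 * size) {
    stop(sprintf("only %d of %d ensemble members trained successfully", length(members), size))
  }
  structure(list(members = members, failed = failed, config = config),
            class = "dtn_ensemble")
}

#' @export
print.dtn_ensemble <- function(x, ...) {
  cat(sprintf("dtn_ensemble: %d members (%d failed seeds)\n",
              length(x$members), length(x$failed)))
  invisible(x)
}

#' Ensemble-mean prediction
#' @param object a `dtn_ensemble`.
#' @param newdata dose matrix or condition table.
#' @param ... unused.
#' @return samples x TFs matrix (mean over members).
#' @export
predict.dtn_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, function(m) predict(m$model, newdata))
  Reduce(`+`, preds) / length(preds)
}

#' Shuffle-null datasets
#'
#' `shuffle_X` permutes the rows of the dose matrix (drug labels decoupled
#' from responses); `shuffle_Y` permutes the rows of the TF-activity matrix.
#' Marginals are preserved exactly.
#'
#' @param conditions a [condition_table()].
#' @param Y TF-activity matrix.
#' @param mode `"shuffle_X"` or `"shuffle_Y"`.
#' @param seed seed for the permutation.
#' @return list with permuted `conditions` / `Y` and the `permutation`.
#' @export
shuffle_null <- function(conditions, Y, mode = c("shuffle_X", "shuffle_Y"),
                         seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(Y)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample.int(n)
  if (mode == "shuffle_X") {
    conditions$X <- conditions$X[perm, , drop = FALSE]
    conditions$drug <- conditions$drug[perm]
  } else {
    Y <- Y[perm, , drop = FALSE]
  }
  list(conditions = conditions, Y = Y, permutation = perm)
}

#' Per-TF prediction performance
#'
#' Pearson correlation between predicted and observed activity per TF, with
#' two-sided p values, Benjamini-Hochberg adjustment and rank percentiles.
#' Zero-variance TFs are flagged (`undefined = TRUE`), never dropped
#' silently.
#'
#' @param pred,obs samples x TFs matrices (>= 3 samples).
#' @return data.frame: `tf`, `r`, `p`, `p_adj`, `rank_percentile`,
#'   `undefined`.
#' @export
per_tf_performance <- function(pred, obs) {
  stopifnot(nrow(pred) >= 3, all(dim(pred) == dim(obs)))
  tfs <- colnames(obs)
  if (is.null(tfs)) tfs <- paste0("TF", seq_len(ncol(obs)))
  res <- lapply(seq_len(ncol(obs)), function(j) {
    if (stats::sd(pred[, j]) == 0 || stats::sd(obs[, j]) == 0) {
      return(data.frame(tf = tfs[j], r = NA_real_, p = NA_real_, undefined = TRUE))
    }
    ct <- stats::cor.test(pred[, j], obs[, j])
    data.frame(tf = tfs[j], r = unname(ct$estimate), p = ct$p.value,
               undefined = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  ok <- !out$undefined
  out$rank_percentile <- NA_real_
  out$rank_percentile[ok] <- rank(out$r[ok]) / sum(ok)
  out[, c("tf", "r", "p", "p_adj", "rank_percentile", "undefined")]
}

#' Rescale TF activities to the unit interval
#'
#' Logistic transform of per-TF z-scores: `1 / (1 + exp(-z))`. Puts
#' enrichment-score style activities on the `[0, 1]` scale the model fits,
#' with the per-TF median near 0.5.
#'
#' @param Y samples x TFs activity matrix.
#' @return rescaled matrix.
#' @export
rescale_tf_activity <- function(Y) {
  Z <- scale(Y)
  Z[is.nan(Z)] <- 0
  out <- 1 / (1 + exp(-Z))
  attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  out
}

#' Frozen-drug-module cross-validation
#'
#' Transfers a trained drug module to other datasets: for each dataset, the
#' drug module (similarity scaler, drug-target weights, batch-norm state) is
#' frozen and only the signaling network is retrained on ~80% of drugs; the
#' held-out ~20% are chosen chemically dissimilar from the training drugs
#' (see [dissimilar_split()]). Per-TF Pearson r on held-out drugs is
#' reported per fold, together with train-rank vs validation-rank
#' percentiles for the well-fitted-TF analysis.
#'
#' @param source a `trained_model` providing the frozen drug module.
#' @param datasets list of `list(conditions = , Y = )` entries.
#' @param sim similarity matrix of the common drug space.
#' @param k number of folds (distinct seeded splits; default 5).
#' @param threshold dissimilarity threshold (default 0.5).
#' @param test_fraction held-out drug fraction per fold (default 0.2).
#' @param config retraining configuration.
#' @return data.frame with one row per (dataset, fold, TF): validation `r`,
#'   training `r`, and both rank percentiles. Skipped folds are reported via
#'   warnings.
#' @export
frozen_drug_module_cv <- function(source, datasets, sim, k = 5,
                                  threshold = 0.5, test_fraction = 0.2,
                                  config = train_config()) {
  stopifnot(inherits(source, "trained_model"))
  out <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    for (fold in seq_len(k)) {
      sp <- tryCatch(
        dissimilar_split(sim, test_fraction = test_fraction, threshold = threshold,
                         seed = 1000 * di + fold),
        error = function(e) e)
      if (inherits(sp, "error")) {
        warning(sprintf("dataset %d fold %d: infeasible dissimilar split, skipped", di, fold))
        next
      }
      in_test <- ds$conditions$drug %in% sp$test
      Xtr <- ds$conditions$X[!in_test, , drop = FALSE]
      Ytr <- ds$Y[!in_test, , drop = FALSE]
      Xte <- ds$conditions$X[in_test, , drop = FALSE]
      Yte <- ds$Y[in_test, , drop = FALSE]
      tm <- train_model(Xtr, Ytr, config = config,
                        seed = config$seed + fold, model = source$model,
                        freeze = c("Wdrug", "WDT", "gamma", "beta"))
      tr_perf <- per_tf_performance(predict(tm$model, Xtr), Ytr)
      va_perf <- per_tf_performance(predict(tm$model, Xte), Yte)
      out[[length(out) + 1]] <- data.frame(
        dataset = di, fold = fold, tf = tr_perf$tf,
        train_r = tr_perf$r, train_rank = tr_perf$rank_percentile,
        val_r = va_perf$r, val_rank = va_perf$rank_percentile,
        achieved_test_fraction = sp$achieved_fraction)
    }
  }
  do.call(rbind, out)
}
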