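#' Integrated-gradient attribution along a straight path
#'
#' Generic Riemann-sum approximation of integrated gradients for a
#' differentiable map `F`: attribution of input coordinate `i` on every
#' output is `(x_i - x'_i) * mean_a dF(x' + a (x - x'))/dx_i`, with the path
#' coefficient `a` on a midpoint grid of `m` steps and baseline `x' = 0` by
#' default. Exact for affine maps at any `m`.
#'
#' @param jac function of the input vector returning the Jacobian matrix
#'   (outputs x inputs).
#' @param x input vector.
#' @param m number of integration steps (>= 2).
#' @param baseline baseline vector (default zeros).
#' @return attribution matrix (outputs x inputs).
#' @export
integrated_gradients_fn <- function(jac, x, m = 64, baseline = NULL) {
  if (m < 2) stop("integration steps m must be >= 2")
  if (is.null(baseline)) baseline <- rep(0, length(x))
  alphas <- (seq_len(m) - 0.5) / m
  J <- NULL
  for (a in alphas) {
    Ja <- jac(baseline + a * (x - baseline))
    J <- if (is.null(J)) Ja / m else J + Ja / m
  }
  sweep(J, 2, x - baseline, "*")
}

# effective eval-mode Jacobian of the drug module: dS/dX (t x d transposed
# as d x t here). Eval-mode batch norm is affine, so this is constant in X.
.drug_module_jacobian <- function(dm, bn_bypass = FALSE) {
  scale <- if (bn_bypass) rep(1, length(dm$bn$gamma)) else {
    dm$bn$gamma / sqrt(dm$bn$rvar + dm$bn$eps)
  }
  (dm$Wsim * dm$Wdrug) %*% (scale * dm$WDT)
}

#' Integrated-gradient drug-target scores
#'
#' Attribution of one drug's dose input onto every target node's signal,
#' through the drug module in eval mode (deterministic). The eval-mode
#' module is affine in the dose, so the Riemann sum is exact for any number
#' of steps; the signed score is positive for activation-like and negative
#' for inhibition-like influence.
#'
#' @param model a `dtn_model` (or `trained_model`).
#' @param drug drug identifier.
#' @param dose input dose on the scaled axis (default 1).
#' @param m integration steps (default 64).
#' @param bn_bypass bypass batch normalization.
#' @return named numeric vector of per-target scores.
#' @export
integrated_gradients <- function(model, drug, dose = 1, m = 64,
                                 bn_bypass = FALSE) {
  if (inherits(model, "trained_model")) model <- model$model
  dm <- model$dm
  di <- match(drug, dm$drug_ids)
  if (is.na(di)) stop("unknown drug: ", drug)
  A <- .drug_module_jacobian(dm, bn_bypass)     # d x t, constant Jacobian
  x <- rep(0, length(dm$drug_ids)); x[di] <- dose
  attr_mat <- integrated_gradients_fn(function(z) t(A), x, m = m)
  scores <- attr_mat[, di]
  names(scores) <- dm$target_ids
  scores
}

# Predict with a per-drug target mask applied to the drug signal:
# for samples of drug `drug`, the signal entering the masked targets is
# zeroed before propagation.
.predict_masked <- function(model, X, sample_drugs, masked,
                            min_steps = 1) {
  fw <- drug_forward(model$dm, X, training = FALSE)
  S <- fw$S
  if (length(masked)) {
    basal <- .basal_signal(model$dm)
    for (d in names(masked)) {
      rows <- which(sample_drugs == d)
      cols <- match(masked[[d]], model$target_ids)
      cols <- cols[!is.na(cols)]
      if (length(rows) && length(cols)) {
        S[rows, cols] <- rep(basal[cols], each = length(rows))
      }
    }
  }
  U <- .scatter_signal(model, S)
  traj <- propagate_steady_state(U, model$W, model$b, tf_idx = model$tf_idx,
                                 max_steps = model$config$max_steps,
                                 min_steps = min_steps,
                                 tol = model$config$tol,
                                 leak = model$config$leak,
                                 knot = model$config$knot)
  Y <- project_to_tf(traj$state, model$wp, model$tf_idx)
  colnames(Y) <- model$tf_ids
  Y
}

#' Error-curve cutoff for inferred drug-target interactions
#'
#' Candidate interactions are sorted by ascending absolute attribution score
#' and progressively masked (their drug signal zeroed); after each removal
#' the model's MAE against the observed TF activities is recomputed. The
#' cutoff is the smallest absolute score whose cumulative removal first
#' produces a relative MAE increase of at least `increase` (default 25%)
#' over the unmasked model; interactions scoring at or above the cutoff are
#' inferred. With `scope = "per_drug"` the curve and cutoff are computed per
#' drug over that drug's samples; `scope = "global"` pools all candidates on
#' one curve over all samples. A flat curve yields an empty inferred set.
#'
#' @param model a `dtn_model` / `trained_model`.
#' @param scores drugs x targets score matrix (see
#'   [drug_target_scores()]), or NULL to compute it.
#' @param conditions a [condition_table()].
#' @param Y observed TF activities.
#' @param increase relative MAE increase defining the cutoff (0.25).
#' @param scope `"per_drug"` or `"global"`.
#' @return list: `inferred` (logical drugs x targets matrix), `cutoff`
#'   (per drug, or scalar for global), `curve` (data.frame of the error
#'   curve), `scores`.
#' @export
error_curve_cutoff <- function(model, scores = NULL, conditions, Y,
                               increase = 0.25,
                               scope = c("per_drug", "global")) {
  scope <- match.arg(scope)
  if (inherits(model, "trained_model")) model <- model$model
  if (is.null(scores)) scores <- drug_target_scores(model, conditions)
  X <- conditions$X
  sample_drugs <- conditions$drug
  Y <- as.matrix(Y)
  drug_ids <- model$dm$drug_ids
  target_ids <- model$target_ids
  inferred <- matrix(FALSE, length(drug_ids), length(target_ids),
                     dimnames = list(drug_ids, target_ids))
  mae <- function(rows, masked) {
    pred <- .predict_masked(model, X[rows, , drop = FALSE],
                            sample_drugs[rows], masked)
    mean(abs(pred - Y[rows, , drop = FALSE]))
  }
  curve <- list()
  if (scope == "per_drug") {
    cutoffs <- stats::setNames(rep(NA_real_, length(drug_ids)), drug_ids)
    for (d in drug_ids) {
      rows <- which(sample_drugs == d)
      if (!length(rows)) next
      sc <- scores[d, ]
      ord <- order(abs(sc), target_ids)     # ascending |score|, lexical ties
      base <- mae(rows, NULL)
      if (base == 0) base <- .Machine$double.eps
      masked <- character()
      for (k in seq_along(ord)) {
        masked <- c(masked, target_ids[ord[k]])
        m_k <- mae(rows, stats::setNames(list(masked), d))
        curve[[length(curve) + 1]] <- data.frame(
          drug = d, n_removed = k, abs_score = abs(sc[ord[k]]),
          mae = m_k, rel_increase = m_k / base - 1)
        if (m_k / base - 1 >= increase) {
          cutoffs[d] <- abs(sc[ord[k]])
          inferred[d, abs(sc) >= cutoffs[d]] <- TRUE
          break
        }
      }
    }
  } else {
    cand <- expand.grid(drug = drug_ids, target = target_ids,
                        stringsAsFactors = FALSE)
    cand$score <- scores[cbind(cand$drug, cand$target)]
    cand <- cand[order(abs(cand$score), cand$drug, cand$target), ]
    rows <- seq_len(nrow(X))
    base <- mae(rows, NULL)
    if (base == 0) base <- .Machine$double.eps
    masked <- stats::setNames(vector("list", length(drug_ids)), drug_ids)
    cutoffs <- NA_real_
    for (k in seq_len(nrow(cand))) {
      d <- cand$drug[k]
      masked[[d]] <- c(masked[[d]], cand$target[k])
      m_k <- mae(rows, masked)
      curve[[length(curve) + 1]] <- data.frame(
        drug = NA_character_, n_removed = k, abs_score = abs(cand$score[k]),
        mae = m_k, rel_increase = m_k / base - 1)
      if (m_k / base - 1 >= increase) {
        cutoffs <- abs(cand$score[k])
        inferred <- abs(scores) >= cutoffs
        break
      }
    }
  }
  list(inferred = inferred, cutoff = cutoffs,
       curve = do.call(rbind, curve), scores = scores)
}

#' Score every drug against every target
#'
#' Integrated-gradient scores for each drug at its reference dose (the
#' maximum scaled dose at which the drug appears in `conditions`, or
#' `dose = 1` if no conditions are given).
#'
#' @param model a `dtn_model` / `trained_model`.
#' @param conditions optional [condition_table()] supplying reference doses.
#' @param m integration steps.
#' @return drugs x targets numeric matrix of signed scores.
#' @export
drug_target_scores <- function(model, conditions = NULL, m = 64) {
  if (inherits(model, "trained_model")) model <- model$model
  drug_ids <- model$dm$drug_ids
  doses <- rep(1, length(drug_ids))
  if (!is.null(conditions)) {
    mx <- apply(conditions$X, 2, max)
    doses <- ifelse(mx > 0, mx, 1)[match(drug_ids, conditions$drug_ids)]
    doses[is.na(doses)] <- 1
  }
  out <- t(vapply(seq_along(drug_ids),
                  function(i) integrated_gradients(model, drug_ids[i],
                                                   dose = doses[i], m = m),
                  numeric(length(model$target_ids))))
  dimnames(out) <- list(drug_ids, model$target_ids)
  out
}

#' Infer drug-target interactions from an ensemble
#'
#' Runs attribution scoring and the error-curve cutoff for every ensemble
#' member and aggregates inferred interactions into ensemble frequencies.
#'
#' @param ensemble a `dtn_ensemble` (or list of `trained_model`s).
#' @param conditions a [condition_table()].
#' @param Y observed TF activities.
#' @param increase relative MAE increase for the cutoff.
#' @param scope see [error_curve_cutoff()].
#' @return list: `frequency` (drugs x targets in `[0, 1]`), `mean_score`,
#'   `per_model` (list of logical inferred matrices), `n_models`, and
#'   `table` (long data.frame of nonzero-frequency interactions with
#'   `in_prior` flags).
#' @export
infer_interactions <- function(ensemble, conditions, Y, increase = 0.25,
                               scope = "per_drug") {
  members <- if (inherits(ensemble, "dtn_ensemble")) ensemble$members else ensemble
  per_model <- list(); score_sum <- NULL
  for (m in members) {
    mod <- if (inherits(m, "trained_model")) m$model else m
    sc <- drug_target_scores(mod, conditions)
    ec <- error_curve_cutoff(mod, sc, conditions, Y, increase = increase,
                             scope = scope)
    per_model[[length(per_model) + 1]] <- ec$inferred
    score_sum <- if (is.null(score_sum)) sc else score_sum + sc
  }
  freq <- ensemble_frequency(per_model)
  mean_score <- score_sum / length(members)
  mod1 <- if (inherits(members[[1]], "trained_model")) members[[1]]$model else members[[1]]
  prior <- mod1$dm$prior
  idx <- which(freq > 0, arr.ind = TRUE)
  tab <- data.frame(drug = rownames(freq)[idx[, 1]],
                    target = colnames(freq)[idx[, 2]],
                    frequency = freq[idx],
                    mean_score = mean_score[idx])
  tab$in_prior <- paste(tab$drug, tab$target) %in% paste(prior$drug, prior$target)
  tab <- tab[order(-tab$frequency, tab$drug, tab$target), ]
  rownames(tab) <- NULL
  list(frequency = freq, mean_score = mean_score, per_model = per_model,
       n_models = length(members), table = tab)
}

#' Ensemble frequency of inferred interactions
#'
#' @param inferred_sets list of logical drugs x targets matrices (one per
#'   model).
#' @return drugs x targets matrix of frequencies in `[0, 1]` (fraction of
#'   models inferring each interaction).
#' @export
ensemble_frequency <- function(inferred_sets) {
  stopifnot(length(inferred_sets) >= 1)
  Reduce(`+`, lapply(inferred_sets, function(m) m * 1)) / length(inferred_sets)
}

#' Classification metrics for inferred interactions
#'
#' Confusion counts and derived metrics of an inferred interaction set
#' against a truth set over the full drug x target universe. The negative
#' class is every universe pair absent from the truth set. Reports accuracy
#' with the no-information rate (NIR, the majority-class proportion) and a
#' one-tailed exact binomial test of accuracy > NIR; precision, recall, F1;
#' the G-mean of sensitivity and specificity; the new discovery rate (NDR:
#' inferred interactions outside the prior divided by all inferred); and the
#' TPR over prior interactions.
#'
#' @param inferred logical drugs x targets matrix, or a frequency matrix
#'   with `freq_threshold` applied.
#' @param truth logical matrix (or data.frame with `drug`, `target`) of true
#'   interactions.
#' @param prior data.frame of known (prior) interactions.
#' @param freq_threshold frequency cutoff when `inferred` is numeric
#'   (interactions with frequency >= threshold count as inferred).
#' @return list of class `interaction_metrics`.
#' @export
interaction_metrics <- function(inferred, truth, prior = NULL,
                                freq_threshold = 0.5) {
  if (is.numeric(inferred)) inferred <- inferred >= freq_threshold
  if (is.data.frame(truth)) {
    tm <- matrix(FALSE, nrow(inferred), ncol(inferred), dimnames = dimnames(inferred))
    tm[cbind(match(truth$drug, rownames(tm)), match(truth$target, colnames(tm)))] <- TRUE
    truth <- tm
  }
  stopifnot(all(dim(inferred) == dim(truth)))
  if (!any(truth)) warning("empty truth set: recall undefined")
  tp <- sum(inferred & truth); fp <- sum(inferred & !truth)
  fn <- sum(!inferred & truth); tn <- sum(!inferred & !truth)
  n <- tp + fp + fn + tn
  acc <- (tp + tn) / n
  nir <- max(sum(truth), n - sum(truth)) / n
  p_acc <- stats::binom.test(tp + tn, n, p = nir, alternative = "greater")$p.value
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  sens <- rec
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  gmean <- if (!is.na(sens) && !is.na(spec)) sqrt(sens * spec) else NA_real_
  ndr <- NA_real_; tpr_prior <- NA_real_
  if (!is.null(prior)) {
    pm <- matrix(FALSE, nrow(inferred), ncol(inferred), dimnames = dimnames(inferred))
    pm[cbind(match(prior$drug, rownames(pm)), match(prior$target, colnames(pm)))] <- TRUE
    n_inf <- sum(inferred)
    ndr <- if (n_inf > 0) sum(inferred & !pm) / n_inf else 0
    tpr_prior <- if (any(pm)) sum(inferred & pm) / sum(pm) else NA_real_
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, accuracy = acc,
                 NIR = nir, p_accuracy_vs_NIR = p_acc, precision = prec,
                 recall = rec, F1 = f1, G_mean = gmean, NDR = ndr,
                 TPR_prior = tpr_prior), class = "interaction_metrics")
}

#' @export
print.interaction_metrics <- function(x, ...) {
  cat(sprintf("TP %d FP %d TN %d FN %d | acc %.4f (NIR %.4f, p %.3g) | P %.3f R %.3f F1 %.3f | G %.3f NDR %.3f TPRprior %.3f\n",
              x$TP, x$FP, x$TN, x$FN, x$accuracy, x$NIR, x$p_accuracy_vs_NIR,
              x$precision, x$recall, x$F1, x$G_mean, x$NDR, x$TPR_prior))
  invisible(x)
}
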