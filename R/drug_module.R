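#' Build a condition table from sample annotations
#'
#' Converts a long table of samples (one perturbing drug per sample, dose in
#' micromolar) into the dose-input matrix `X` (samples x drugs) on the
#' log scale `log10(dose + 1)`. Control compounds (e.g. DMSO) are treated as
#' drugs like any other.
#'
#' @param samples data.frame with columns `sample`, `drug`, `dose_uM` and
#'   optionally `group` (replicate group / cell line).
#' @param drug_ids ordered drug universe; defaults to order of appearance.
#' @return object of class `condition_table`: list with `X`, `sample_ids`,
#'   `drug_ids`, `drug` (per-sample perturbing drug), `group`.
#' @export
condition_table <- function(samples, drug_ids = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "drug", "dose_uM") %in% names(samples)))
  if (is.null(drug_ids)) drug_ids <- unique(samples$drug)
  if (!all(samples$drug %in% drug_ids)) stop("sample drug not in drug_ids")
  X <- matrix(0, nrow(samples), length(drug_ids),
              dimnames = list(samples$sample, drug_ids))
  X[cbind(seq_len(nrow(samples)), match(samples$drug, drug_ids))] <-
    scale_dose(samples$dose_uM)
  structure(list(X = X, sample_ids = samples$sample, drug_ids = drug_ids,
                 drug = samples$drug,
                 group = if ("group" %in% names(samples)) samples$group else samples$sample),
            class = "condition_table")
}

#' Log-scale a micromolar dose
#'
#' `log10(dose + 1)`; maps 0 to 0 and compresses the usual 0.01-10 uM range
#' to roughly the unit interval.
#' @param dose_uM nonnegative dose(s) in micromolar.
#' @return scaled dose(s).
#' @export
scale_dose <- function(dose_uM) {
  if (any(dose_uM < 0)) stop("dose must be nonnegative")
  log10(dose_uM + 1)
}

#' Initialize drug-module parameters
#'
#' The module computes `S = bn(X %*% (Wsim * Wdrug)) %*% WDT`:
#' the dose matrix is mixed across drugs by the chemical similarity `Wsim`
#' element-wise scaled by the trainable `Wdrug` (initialized at the identity,
#' so the module starts from prior knowledge only), passed through batch
#' normalization (momentum 0.6) and, during training, dropout (rate 0.1),
#' then mapped onto target nodes by the sparse trainable `WDT` whose support
#' is exactly the known drug-target prior. Known interactions are
#' initialized at `sign * 0.1`.
#'
#' @param Wsim similarity matrix (drugs x drugs), frozen during training.
#' @param prior data.frame of known interactions: `drug`, `target`, `sign`.
#' @param target_ids ordered target-node universe (columns of the output).
#' @param lambda_DT regularization strength pulling `Wdrug` to the identity;
#'   `Inf` freezes `Wdrug` at the identity (prior knowledge only).
#' @param dropout_rate training-time dropout rate (0.1).
#' @param bn_momentum batch-norm running-statistics momentum (0.6).
#' @return list of class `drug_module` with trainable parameters and masks.
#' @export
drug_module <- function(Wsim, prior, target_ids, lambda_DT = 5e-3,
                        dropout_rate = 0.1, bn_momentum = 0.6) {
  drug_ids <- rownames(Wsim)
  stopifnot(!is.null(drug_ids), identical(drug_ids, colnames(Wsim)))
  d <- length(drug_ids); t <- length(target_ids)
  if (!all(prior$drug %in% drug_ids)) {
    stop("prior drug(s) not in similarity matrix: ",
         paste(setdiff(prior$drug, drug_ids), collapse = ", "))
  }
  if (!all(prior$target %in% target_ids)) {
    stop("prior target(s) not in target universe: ",
         paste(setdiff(prior$target, target_ids), collapse = ", "))
  }
  WDT <- matrix(0, d, t, dimnames = list(drug_ids, target_ids))
  mask <- matrix(FALSE, d, t, dimnames = dimnames(WDT))
  idx <- cbind(match(prior$drug, drug_ids), match(prior$target, target_ids))
  mask[idx] <- TRUE
  WDT[idx] <- 0.1 * prior$sign
  structure(list(
    drug_ids = drug_ids, target_ids = target_ids,
    Wsim = Wsim,
    Wdrug = diag(1, d, d),
    WDT = WDT, WDT_mask = mask,
    prior = prior,
    bn = list(gamma = rep(1, d), beta = rep(0, d),
              rmean = rep(0, d), rvar = rep(1, d),
              momentum = bn_momentum, eps = 1e-5),
    dropout_rate = dropout_rate,
    lambda_DT = lambda_DT), class = "drug_module")
}

#' Drug-module forward pass
#'
#' @param dm a [drug_module()].
#' @param X dose matrix (samples x drugs) or a [condition_table()].
#' @param training logical; batch statistics + running-stat update + dropout
#'   are only used in training mode. Inference is deterministic.
#' @param bn_bypass replace batch normalization by the identity (useful for
#'   analytic checks of the degenerate limit `S = X %*% WDT`).
#' @param cache return intermediate quantities needed for the backward pass.
#' @return list of class `drug_signal`: `S` (samples x targets),
#'   `target_ids`, updated `dm` (running statistics), plus cached
#'   intermediates when requested.
#' @export
drug_forward <- function(dm, X, training = FALSE, bn_bypass = FALSE,
                         cache = FALSE) {
  if (inherits(X, "condition_table")) X <- X$X
  X <- as.matrix(X)
  if (ncol(X) != length(dm$drug_ids)) {
    stop(sprintf("dose matrix has %d columns but module has %d drugs",
                 ncol(X), length(dm$drug_ids)))
  }
  M <- X %*% (dm$Wsim * dm$Wdrug)
  bn <- dm$bn
  if (bn_bypass) {
    xhat <- M; B <- M; mu <- rep(0, ncol(M)); ivstd <- rep(1, ncol(M))
  } else if (training) {
    n <- nrow(M)
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2          # population variance
    ivstd <- 1 / sqrt(v + bn$eps)
    xhat <- sweep(sweep(M, 2, mu), 2, ivstd, "*")
    B <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    ub <- if (n > 1) v * n / (n - 1) else v
    bn$rmean <- (1 - bn$momentum) * bn$rmean + bn$momentum * mu
    bn$rvar <- (1 - bn$momentum) * bn$rvar + bn$momentum * ub
    dm$bn <- bn
  } else {
    mu <- bn$rmean
    ivstd <- 1 / sqrt(bn$rvar + bn$eps)
    xhat <- sweep(sweep(M, 2, mu), 2, ivstd, "*")
    B <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  }
  drop_mask <- NULL
  D <- B
  if (training && dm$dropout_rate > 0) {
    keep <- 1 - dm$dropout_rate
    drop_mask <- matrix(stats::rbinom(length(B), 1, keep) / keep,
                        nrow(B), ncol(B))
    D <- B * drop_mask
  }
  S <- D %*% dm$WDT
  if (!all(is.finite(S))) stop("non-finite drug-module output")
  out <- list(S = S, target_ids = dm$target_ids, dm = dm)
  if (cache) {
    out$M <- M; out$xhat <- xhat; out$ivstd <- ivstd; out$D <- D
    out$drop_mask <- drop_mask; out$bn_bypass <- bn_bypass
    out$training <- training; out$X <- X
  }
  class(out) <- "drug_signal"
  out
}

# Backward through the drug module. dS is dLoss/dS; fw is the cached forward.
# Returns grads for Wdrug, WDT, gamma, beta (NULL entries when frozen).
.drug_backward <- function(dm, fw, dS) {
  dD <- dS %*% t(dm$WDT)
  dWDT <- t(fw$D) %*% dS
  dWDT[!dm$WDT_mask] <- 0
  if (!is.null(fw$drop_mask)) dB <- dD * fw$drop_mask else dB <- dD
  if (fw$bn_bypass) {
    dM <- dB
    dgamma <- rep(0, ncol(dB)); dbeta <- rep(0, ncol(dB))
  } else {
    dgamma <- colSums(dB * fw$xhat)
    dbeta <- colSums(dB)
    dxhat <- sweep(dB, 2, dm$bn$gamma, "*")
    if (fw$training) {
      n <- nrow(dB)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * fw$xhat)
      dM <- sweep(dxhat * n - matrix(s1, n, length(s1), byrow = TRUE) -
                    fw$xhat * matrix(s2, n, length(s2), byrow = TRUE),
                  2, fw$ivstd / n, "*")
    } else {
      dM <- sweep(dxhat, 2, fw$ivstd, "*")
    }
  }
  dWdrug <- (t(fw$X) %*% dM) * dm$Wsim
  list(dWdrug = dWdrug, dWDT = dWDT, dgamma = dgamma, dbeta = dbeta)
}

#' Regularization of similarity-mediated target inference
#'
#' `lambda_DT * sum((Wdrug - I)^2)`: pulls the similarity scaler toward the
#' identity, throttling how much chemical similarity may route one drug's
#' dose through another drug's target channels (and hence how many new
#' drug-target interactions can be inferred). `lambda_DT = Inf` is
#' represented by freezing `Wdrug` at the identity, in which case the term
#' is 0 and contributes no gradient.
#'
#' @param Wdrug d x d trainable similarity scaler.
#' @param lambda_DT regularization strength (>= 0 or `Inf`).
#' @return scalar loss.
#' @export
dt_regularization <- function(Wdrug, lambda_DT) {
  if (is.infinite(lambda_DT)) return(0)
  if (lambda_DT < 0) stop("lambda_DT must be >= 0")
  dev <- Wdrug - diag(1, nrow(Wdrug), ncol(Wdrug))
  lambda_DT * sum(dev^2)
}

#' Mask a drug signal down to known targets
#'
#' Per sample, removes the drug-attributable signal on every target node
#' that is not in the perturbing drug's known (prior) target set; signal on
#' known targets is left unchanged. "Removing" means resetting the masked
#' entries to the module's basal signal `basal` — the output the sample
#' would have received at zero dose. With the default `basal = 0` masked
#' columns are zeroed outright (appropriate when batch normalization is
#' bypassed, in which case zero dose produces zero signal); model-level
#' wrappers pass the eval-mode zero-dose output so that batch-norm offsets,
#' which are not drug-attributable, are preserved. Used to quantify
#' off-target effects by difference.
#'
#' @param S drug-signal matrix (samples x targets) or a `drug_signal`.
#' @param prior data.frame of known interactions (`drug`, `target`).
#' @param sample_drugs perturbing drug per sample (length `nrow(S)`).
#' @param basal basal signal: scalar, per-target vector, or matrix shaped
#'   like `S` (default 0).
#' @return masked signal matrix, same shape as `S`.
#' @export
mask_offtarget_signal <- function(S, prior, sample_drugs, basal = 0) {
  if (inherits(S, "drug_signal")) S <- S$S
  target_ids <- colnames(S)
  if (is.null(target_ids)) stop("S must have target column names")
  unknown <- setdiff(unique(sample_drugs), unique(prior$drug))
  if (length(unknown)) {
    stop("drug(s) absent from the prior table: ", paste(unknown, collapse = ", "))
  }
  if (!is.matrix(basal)) {
    basal <- matrix(basal, nrow(S), ncol(S), byrow = length(basal) > 1)
  }
  known <- split(prior$target, prior$drug)
  out <- S
  for (s in seq_len(nrow(S))) {
    keep <- target_ids %in% known[[sample_drugs[s]]]
    out[s, !keep] <- basal[s, !keep]
  }
  out
}

# eval-mode module output at zero dose: the basal (non-drug-attributable)
# signal row implied by the batch-norm offsets
.basal_signal <- function(dm) {
  X0 <- matrix(0, 1, length(dm$drug_ids))
  drug_forward(dm, X0, training = FALSE)$S[1, ]
}
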