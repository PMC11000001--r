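#' Assemble a drug-to-TF signaling model
#'
#' Combines the drug module with the recurrent prior-knowledge signaling
#' network. Signaling weights live on the network's edge support (dense
#' storage, masked), carry the prior sign, and feed the Michaelis-Menten-like
#' recurrence; TF activities are read out from the steady state through
#' per-TF projection weights.
#'
#' @param net a (trimmed) [signaling_network()].
#' @param prior drug-target prior data.frame (`drug`, `target`, `sign`).
#' @param Wsim chemical-similarity matrix with drug-id dimnames.
#' @param lambda_DT see [drug_module()].
#' @param config optional overrides: `max_steps` (120), `tol` (1e-8),
#'   `leak` (0.01), `knot` (0.5), `dropout_rate` (0.1), `bn_momentum` (0.6).
#' @param init_seed seed for the signaling weight initialization.
#' @return object of class `dtn_model`.
#' @export
build_model <- function(net, prior, Wsim, lambda_DT = 5e-3, config = list(),
                        init_seed = 1) {
  stopifnot(inherits(net, "signaling_network"))
  cfg <- utils::modifyList(
    list(max_steps = 120, tol = 1e-8, leak = 0.01, knot = 0.5,
         dropout_rate = 0.1, bn_momentum = 0.6, target_rho = target_rho(120),
         power_iters = 50), config)
  nodes <- net$nodes
  n <- length(nodes)
  target_ids <- net$target_nodes
  tf_ids <- net$tf_nodes
  if (length(target_ids) == 0 || length(tf_ids) == 0) {
    stop("network must designate drug-target and TF nodes")
  }
  dm <- drug_module(Wsim, prior, target_ids, lambda_DT = lambda_DT,
                    dropout_rate = cfg$dropout_rate,
                    bn_momentum = cfg$bn_momentum)
  W_mask <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  W_sign <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ei <- cbind(match(net$edges$target, nodes), match(net$edges$source, nodes))
  W_mask[ei] <- TRUE
  W_sign[ei] <- net$edges$sign
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  old <- .save_rng(); set.seed(init_seed)
  W[ei] <- net$edges$sign * abs(stats::rnorm(nrow(ei), 0, 0.1))
  .restore_rng(old)
  structure(list(
    net = net, dm = dm,
    nodes = nodes, target_ids = target_ids, tf_ids = tf_ids,
    target_idx = match(target_ids, nodes), tf_idx = match(tf_ids, nodes),
    W = W, W_mask = W_mask, W_sign = W_sign,
    b = rep(0.01, n), wp = rep(1.2, length(tf_ids)),
    config = cfg), class = "dtn_model")
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv())
}

#' @export
print.dtn_model <- function(x, ...) {
  cat(sprintf("dtn_model: %d nodes, %d edges, %d drugs, %d targets, %d TFs (lambda_DT = %s)\n",
              length(x$nodes), sum(x$W_mask), length(x$dm$drug_ids),
              length(x$target_ids), length(x$tf_ids),
              format(x$dm$lambda_DT)))
  invisible(x)
}

# scatter a (samples x targets) drug signal into node space
.scatter_signal <- function(model, S) {
  U <- matrix(0, nrow(S), length(model$nodes),
              dimnames = list(rownames(S), model$nodes))
  U[, model$target_idx] <- S
  U
}

#' Full model forward pass
#'
#' Dose matrix -> drug module -> signal scattered onto target nodes ->
#' steady-state recurrence -> TF projection.
#'
#' @param model a `dtn_model`.
#' @param X dose matrix (samples x drugs) or [condition_table()].
#' @param training training mode (batch-norm batch statistics + dropout).
#' @param bn_bypass bypass batch normalization (analytic checks).
#' @param cache keep intermediates for backpropagation.
#' @param min_steps minimum recurrence steps (default 1).
#' @param U_extra optional matrix added to the node-space input (e.g.
#'   knockout signal).
#' @return list: `Y` (samples x TFs activity), `S` (drug signal), `traj`
#'   (state trajectory), `model` (with updated batch-norm state), caches.
#' @export
model_forward <- function(model, X, training = FALSE, bn_bypass = FALSE,
                          cache = FALSE, min_steps = 1, U_extra = NULL) {
  fw <- drug_forward(model$dm, X, training = training, bn_bypass = bn_bypass,
                     cache = cache)
  model$dm <- fw$dm
  U <- .scatter_signal(model, fw$S)
  if (!is.null(U_extra)) U <- U + U_extra
  traj <- propagate_steady_state(
    U, model$W, model$b, tf_idx = model$tf_idx,
    max_steps = model$config$max_steps, min_steps = min_steps,
    tol = model$config$tol, leak = model$config$leak, knot = model$config$knot,
    keep_trajectory = cache)
  Y <- project_to_tf(traj$state, model$wp, model$tf_idx)
  colnames(Y) <- model$tf_ids
  rownames(Y) <- rownames(as.matrix(if (inherits(X, "condition_table")) X$X else X))
  list(Y = Y, S = fw$S, traj = traj, model = model, drug_fw = fw, U = U)
}

#' Predict TF activities (deterministic, eval mode)
#'
#' @param object a `dtn_model`.
#' @param newdata dose matrix or [condition_table()].
#' @param ... unused.
#' @return samples x TFs matrix of predicted activities.
#' @export
predict.dtn_model <- function(object, newdata, ...) {
  model_forward(object, newdata, training = FALSE)$Y
}

# flatten/unflatten the trainable parameters
.param_names <- function(model) {
  c("Wdrug", "WDT", "gamma", "beta", "W", "b", "wp")
}

.get_params <- function(model) {
  list(Wdrug = model$dm$Wdrug, WDT = model$dm$WDT,
       gamma = model$dm$bn$gamma, beta = model$dm$bn$beta,
       W = model$W, b = model$b, wp = model$wp)
}

.set_params <- function(model, p) {
  model$dm$Wdrug <- p$Wdrug; model$dm$WDT <- p$WDT
  model$dm$bn$gamma <- p$gamma; model$dm$bn$beta <- p$beta
  model$W <- p$W; model$b <- p$b; model$wp <- p$wp
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding a versioned metadata
#' header (format version, node order, edge list with signs, configuration)
#' together with every parameter vector and the batch-normalization running
#' statistics. Reloading reproduces eval-mode predictions bit-identically.
#' `export_checkpoint_json()` writes a JSON rendering for interchange with
#' other tools (full decimal precision; not guaranteed bit-identical).
#'
#' @param model a `dtn_model` (or `dtn_ensemble`).
#' @param path file path.
#' @return `read_checkpoint` returns the model; writers return `path`.
#' @export
write_checkpoint <- function(model, path) {
  obj <- list(header = list(format = "moanet-checkpoint", version = 1L,
                            class = class(model)[1],
                            created = "unset"),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$header$format, "moanet-checkpoint")) {
    stop("not a moanet checkpoint: ", path)
  }
  obj$model
}

#' @rdname write_checkpoint
#' @export
export_checkpoint_json <- function(model, path) {
  p <- .get_params(model)
  obj <- list(
    header = list(format = "moanet-checkpoint-json", version = 1L),
    nodes = model$nodes, target_ids = model$target_ids, tf_ids = model$tf_ids,
    edges = model$net$edges, config = model$config,
    lambda_DT = model$dm$lambda_DT,
    params = lapply(p, function(x) unname(as.vector(x))),
    bn = list(rmean = model$dm$bn$rmean, rvar = model$dm$bn$rvar,
              momentum = model$dm$bn$momentum, eps = model$dm$bn$eps))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
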