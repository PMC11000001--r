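#' Off-target effect on TF activities (delta-TF report)
#'
#' For every sample and TF, compares the ensemble-mean prediction using the
#' full drug signal with the prediction where signal outside the perturbing
#' drug's known (prior) targets is masked out
#' (`delta = full - masked`). Samples are flagged as trustworthy large
#' off-target effects when the predicted activity is extreme
#' (`>= act_hi` or `<= act_lo`), `|delta| >= delta_min`, and the TF's
#' fit quality passes (`mean(train r, val r) >= mean_r_min` and
#' `val r > val_r_min`). TFs lacking a performance record are excluded from
#' flagging with a warning.
#'
#' @param ensemble `dtn_ensemble` (or list of trained models).
#' @param conditions a [condition_table()].
#' @param prior drug-target prior data.frame.
#' @param performance optional data.frame with columns `tf`, `train_r`,
#'   `val_r`.
#' @param act_hi,act_lo,delta_min,mean_r_min,val_r_min flag thresholds
#'   (defaults 0.75 / 0.25 / 0.2 / 0.5 / 0.4).
#' @return data.frame: `sample`, `drug`, `tf`, `activity` (full),
#'   `masked_activity`, `delta`, `flagged`.
#' @export
delta_tf <- function(ensemble, conditions, prior, performance = NULL,
                     act_hi = 0.75, act_lo = 0.25, delta_min = 0.2,
                     mean_r_min = 0.5, val_r_min = 0.4) {
  members <- if (inherits(ensemble, "dtn_ensemble")) ensemble$members else ensemble
  X <- conditions$X
  sample_drugs <- conditions$drug
  known <- split(prior$target, prior$drug)
  full_sum <- NULL; mask_sum <- NULL
  for (m in members) {
    mod <- if (inherits(m, "trained_model")) m$model else m
    fw <- drug_forward(mod$dm, X, training = FALSE)
    S <- fw$S
    Sm <- mask_offtarget_signal(S, prior, sample_drugs,
                                basal = .basal_signal(mod$dm))
    pf <- function(Sx) {
      U <- .scatter_signal(mod, Sx)
      traj <- propagate_steady_state(U, mod$W, mod$b, tf_idx = mod$tf_idx,
                                     max_steps = mod$config$max_steps,
                                     tol = mod$config$tol,
                                     leak = mod$config$leak, knot = mod$config$knot)
      project_to_tf(traj$state, mod$wp, mod$tf_idx)
    }
    yf <- pf(S); ym <- pf(Sm)
    full_sum <- if (is.null(full_sum)) yf else full_sum + yf
    mask_sum <- if (is.null(mask_sum)) ym else mask_sum + ym
  }
  full <- full_sum / length(members)
  masked <- mask_sum / length(members)
  mod1 <- if (inherits(members[[1]], "trained_model")) members[[1]]$model else members[[1]]
  tfs <- mod1$tf_ids
  out <- expand.grid(sample = seq_len(nrow(X)), tf = tfs,
                     stringsAsFactors = FALSE)
  out$drug <- sample_drugs[out$sample]
  out$sample <- conditions$sample_ids[out$sample]
  idx <- cbind(match(out$sample, conditions$sample_ids), match(out$tf, tfs))
  out$activity <- full[idx]
  out$masked_activity <- masked[idx]
  out$delta <- out$activity - out$masked_activity
  out$flagged <- FALSE
  extreme <- (out$activity >= act_hi | out$activity <= act_lo) &
    abs(out$delta) >= delta_min
  if (!is.null(performance)) {
    missing_tf <- setdiff(tfs, performance$tf)
    if (length(missing_tf)) {
      warning("TF(s) without performance record excluded from flagging: ",
              paste(missing_tf, collapse = ", "))
    }
    pm <- performance[match(out$tf, performance$tf), ]
    ok <- !is.na(pm$train_r) & !is.na(pm$val_r) &
      (pm$train_r + pm$val_r) / 2 >= mean_r_min & pm$val_r > val_r_min
    ok[is.na(ok)] <- FALSE
    out$flagged <- extreme & ok
  } else {
    out$flagged <- extreme
  }
  out[, c("sample", "drug", "tf", "activity", "masked_activity", "delta", "flagged")]
}

#' Node and edge importance for one drug-TF effect
#'
#' Scales the drug's module-generated signal by `n_fractions` factors
#' spanning `[0, 1]`, propagates each scaled signal, and uses the sum of the
#' focal TF's activity over these artificial conditions as the objective.
#' Backpropagation yields bias gradients `db` (per node) and weight
#' gradients `dw` (per edge); importance is
#' `score_b = |db| * range` (range = max - min node activity across the
#' scaled conditions) and `score_w = |dw| * |weight|`.
#'
#' @param model a `dtn_model` / `trained_model`.
#' @param drug drug identifier.
#' @param tf focal TF node.
#' @param n_fractions number of signal fractions (default 11: 0, 0.1, ..., 1).
#' @param dose scaled dose generating the drug signal (default 1).
#' @return list of class `importance_scores`: `node_scores` (named vector),
#'   `edge_scores` (data.frame `source`, `target`, `score`), `range`,
#'   `objective`.
#' @export
node_edge_importance <- function(model, drug, tf, n_fractions = 11, dose = 1) {
  if (inherits(model, "trained_model")) model <- model$model
  if (!tf %in% model$tf_ids) stop("focal TF not in model: ", tf)
  di <- match(drug, model$dm$drug_ids)
  if (is.na(di)) stop("unknown drug: ", drug)
  X <- matrix(0, 1, length(model$dm$drug_ids)); X[1, di] <- dose
  S1 <- drug_forward(model$dm, X, training = FALSE)$S
  fr <- seq(0, 1, length.out = n_fractions)
  S <- fr %o% S1[1, ]
  colnames(S) <- model$target_ids
  U <- .scatter_signal(model, S)
  traj <- propagate_steady_state(U, model$W, model$b, tf_idx = model$tf_idx,
                                 max_steps = model$config$max_steps,
                                 tol = model$config$tol,
                                 leak = model$config$leak, knot = model$config$knot,
                                 keep_trajectory = TRUE)
  states <- traj$state
  tfj <- match(tf, model$tf_ids)
  obj <- sum(states[, model$tf_idx[tfj]] * model$wp[tfj])
  dxT <- matrix(0, nrow(states), ncol(states))
  dxT[, model$tf_idx[tfj]] <- model$wp[tfj]
  bk <- .cpp_backward_rnn(traj$trajectory, model$W, dxT,
                          model$config$leak, model$config$knot)
  rng <- apply(states, 2, max) - apply(states, 2, min)
  node_scores <- abs(bk$db) * rng
  names(node_scores) <- model$nodes
  dW <- bk$dW
  ei <- cbind(match(model$net$edges$target, model$nodes),
              match(model$net$edges$source, model$nodes))
  edge_scores <- data.frame(source = model$net$edges$source,
                            target = model$net$edges$target,
                            sign = model$net$edges$sign,
                            weight = model$W[ei],
                            score = abs(dW[ei]) * abs(model$W[ei]))
  structure(list(node_scores = node_scores, edge_scores = edge_scores,
                 range = rng, objective = obj),
            class = "importance_scores")
}

# helper: does g retain a directed path from >= 1 of `targets` to `tf`?
.connected_targets <- function(g, targets, tf) {
  vs <- igraph::V(g)$name
  targets <- intersect(targets, vs)
  if (!tf %in% vs || length(targets) == 0) return(character())
  reach_tf <- names(igraph::subcomponent(g, tf, mode = "in"))
  intersect(targets, reach_tf)
}

# cleaning pass: keep only nodes on a directed path from a connected target
# to the focal TF (removes disconnected parts, undruggable nodes, dead ends)
.clean_moa_graph <- function(g, targets, tf) {
  ct <- .connected_targets(g, targets, tf)
  if (length(ct) == 0) return(NULL)
  fwd <- unique(unlist(lapply(ct, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))))
  bwd <- names(igraph::subcomponent(g, tf, mode = "in"))
  keep <- union(intersect(fwd, bwd), c(ct, tf))
  igraph::induced_subgraph(g, keep)
}

.moa_to_network <- function(g, net, targets, tf) {
  vs <- igraph::V(g)$name
  el <- igraph::as_data_frame(g, what = "edges")
  key_all <- paste(net$edges$source, net$edges$target)
  sg <- net$edges[key_all %in% paste(el$from, el$to), , drop = FALSE]
  keep_order <- intersect(net$nodes, vs)
  signaling_network(sg, target_nodes = intersect(targets, vs),
                    tf_nodes = tf, nodes = keep_order)
}

#' Prune a network to a mechanism-of-action subnetwork
#'
#' Starting from the model's full network, nodes and then edges are removed
#' in ascending importance order; after each removal the graph is cleaned
#' (disconnected parts, nodes the drug cannot reach, nodes that cannot
#' reach the TF). The phase stops as soon as the next removal would
#' disconnect every target from the focal TF (or remove all targets). The
#' result is a minimal signed subgraph explaining the drug's effect on the
#' TF.
#'
#' @param model a `dtn_model` / `trained_model`.
#' @param drug drug identifier.
#' @param tf focal TF node.
#' @param targets entry nodes for the drug (e.g. its inferred targets);
#'   default: the drug's prior targets.
#' @param scores optional [node_edge_importance()] result (computed if
#'   missing).
#' @return list of class `moa_subnetwork`: `net` (a
#'   [signaling_network()]), `targets`, `tf`, `drug`, `node_scores`,
#'   `edge_scores`.
#' @export
prune_moa_subnetwork <- function(model, drug, tf, targets = NULL,
                                 scores = NULL) {
  if (inherits(model, "trained_model")) model <- model$model
  if (is.null(targets)) {
    targets <- model$dm$prior$target[model$dm$prior$drug == drug]
  }
  if (is.null(scores)) scores <- node_edge_importance(model, drug, tf)
  g <- .net_igraph(model$net)
  g <- .clean_moa_graph(g, targets, tf)
  if (is.null(g)) stop("no target of ", drug, " connects to ", tf, " (empty mechanism)")
  # --- node removal phase
  ns <- sort(scores$node_scores[setdiff(names(scores$node_scores), tf)])
  for (v in names(ns)) {
    if (!v %in% igraph::V(g)$name) next
    g2 <- igraph::delete_vertices(g, v)
    g2 <- .clean_moa_graph(g2, targets, tf)
    if (is.null(g2)) break                   # further removal kills the MoA
    g <- g2
  }
  # --- edge removal phase
  es <- scores$edge_scores
  es$key <- paste(es$source, es$target)
  es <- es[order(es$score, es$key), ]
  for (k in seq_len(nrow(es))) {
    eid <- tryCatch(igraph::get_edge_ids(g, c(es$source[k], es$target[k])),
                    error = function(e) 0)
    if (length(eid) == 0 || eid == 0) next
    g2 <- igraph::delete_edges(g, eid)
    g2 <- .clean_moa_graph(g2, targets, tf)
    if (is.null(g2)) break
    g <- g2
  }
  net <- .moa_to_network(g, model$net, targets, tf)
  structure(list(net = net, targets = net$target_nodes, tf = tf, drug = drug,
                 node_scores = scores$node_scores,
                 edge_scores = scores$edge_scores),
            class = "moa_subnetwork")
}

#' @export
print.moa_subnetwork <- function(x, ...) {
  cat(sprintf("moa_subnetwork: %s -> %s, %d nodes, %d edges (entry: %s)\n",
              if (is.null(x$drug)) "?" else x$drug, x$tf,
              length(x$net$nodes), nrow(x$net$edges),
              paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Merge per-model MoA subnetworks by ensemble consensus
#'
#' Keeps nodes and edges present in at least `threshold` (default 50%) of
#' the member subnetworks. If no target survives, the target threshold is
#' lowered to the highest observed target frequency so that at least one
#' target remains. If thresholding disconnects every target from the TF,
#' edges are re-added along the candidate path with the maximal summed edge
#' frequency.
#'
#' @param subnets list of `moa_subnetwork`s for the same drug / TF.
#' @param threshold consensus frequency (default 0.5).
#' @return a `moa_subnetwork` with `node_freq` and `edge_freq` annotations.
#' @export
merge_ensemble_subnetworks <- function(subnets, threshold = 0.5) {
  stopifnot(length(subnets) >= 1)
  tf <- subnets[[1]]$tf
  n_mod <- length(subnets)
  node_tab <- table(unlist(lapply(subnets, function(s) s$net$nodes)))
  node_freq <- as.numeric(node_tab) / n_mod
  names(node_freq) <- names(node_tab)
  ekeys <- lapply(subnets, function(s)
    paste(s$net$edges$source, s$net$edges$target, s$net$edges$sign, sep = "\t"))
  etab <- table(unlist(ekeys))
  edge_freq <- as.numeric(etab) / n_mod
  names(edge_freq) <- names(etab)
  all_edges <- do.call(rbind, strsplit(names(etab), "\t"))
  union_edges <- data.frame(source = all_edges[, 1], target = all_edges[, 2],
                            sign = as.integer(all_edges[, 3]),
                            freq = edge_freq, stringsAsFactors = FALSE)
  tgt_tab <- table(unlist(lapply(subnets, function(s) s$targets)))
  tgt_freq <- as.numeric(tgt_tab) / n_mod
  names(tgt_freq) <- names(tgt_tab)
  # targets at the consensus threshold, relaxed if necessary
  t_thr <- threshold
  targets <- names(tgt_freq)[tgt_freq >= t_thr]
  if (length(targets) == 0) {
    t_thr <- max(tgt_freq)
    targets <- names(tgt_freq)[tgt_freq >= t_thr]
  }
  keep_edges <- union_edges[union_edges$freq >= threshold, , drop = FALSE]
  keep_nodes <- names(node_freq)[node_freq >= threshold]
  keep_nodes <- union(keep_nodes, c(targets, tf))
  keep_edges <- keep_edges[keep_edges$source %in% keep_nodes &
                             keep_edges$target %in% keep_nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep_edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = keep_nodes))
  if (length(.connected_targets(g, targets, tf)) == 0) {
    # reconnect through the union graph along the max-frequency-sum path
    gu <- igraph::graph_from_data_frame(
      union_edges[, c("source", "target")], directed = TRUE,
      vertices = data.frame(name = unique(c(union_edges$source,
                                            union_edges$target, targets, tf))))
    best <- NULL; best_sum <- -Inf
    for (t in sort(targets)) {
      if (!t %in% igraph::V(gu)$name) next
      paths <- tryCatch(igraph::all_simple_paths(gu, t, tf, mode = "out"),
                        error = function(e) list())
      for (p in paths) {
        nm <- names(p)
        ek <- paste(nm[-length(nm)], nm[-1])
        fsum <- sum(union_edges$freq[match(ek, paste(union_edges$source, union_edges$target))])
        if (fsum > best_sum) { best_sum <- fsum; best <- nm }
      }
    }
    if (!is.null(best)) {
      add <- union_edges[paste(union_edges$source, union_edges$target) %in%
                           paste(best[-length(best)], best[-1]), , drop = FALSE]
      keep_edges <- unique(rbind(keep_edges, add))
      keep_nodes <- union(keep_nodes, best)
    }
  }
  net <- signaling_network(keep_edges[, c("source", "sign", "target")],
                           target_nodes = targets, tf_nodes = tf,
                           nodes = keep_nodes)
  gg <- .net_igraph(net)
  gg <- .clean_moa_graph(gg, targets, tf)
  if (is.null(gg)) {
    net <- signaling_network(NULL, nodes = character())
    targets <- character()
  } else {
    net <- .moa_to_network(gg, net, targets, tf)
    targets <- net$target_nodes
  }
  structure(list(net = net, targets = targets, tf = tf,
                 drug = subnets[[1]]$drug,
                 node_freq = node_freq[names(node_freq) %in% net$nodes],
                 edge_freq = edge_freq,
                 target_threshold = t_thr),
            class = "moa_subnetwork")
}

#' Reduce a MoA subnetwork to its simplest paths
#'
#' Union over targets of the shortest directed path (by edge count) from
#' each target to the TF. Ties are broken by the maximal summed edge
#' frequency (when available), then lexically by the node sequence.
#' Unreachable targets are omitted with a warning.
#'
#' @param subnet a `moa_subnetwork`.
#' @param targets,tf defaults taken from `subnet`.
#' @return a `moa_subnetwork` containing only the selected paths.
#' @export
simplest_paths <- function(subnet, targets = subnet$targets, tf = subnet$tf) {
  g <- .net_igraph(subnet$net)
  ef <- subnet$edge_freq
  keep_nodes <- character(); keep_keys <- character()
  for (t in targets) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = t, to = tf, mode = "out"))
    if (length(sp$vpaths) == 0) {
      warning("target ", t, " cannot reach ", tf, "; omitted")
      next
    }
    cand <- lapply(sp$vpaths, names)
    if (length(cand) > 1) {
      fsum <- vapply(cand, function(nm) {
        ek <- paste(nm[-length(nm)], nm[-1],
                    subnet$net$edges$sign[match(paste(nm[-length(nm)], nm[-1]),
                                                paste(subnet$net$edges$source,
                                                      subnet$net$edges$target))],
                    sep = "\t")
        if (is.null(ef)) 0 else sum(ef[ek], na.rm = TRUE)
      }, numeric(1))
      lex <- vapply(cand, function(nm) paste(nm, collapse = "\r"), character(1))
      best <- order(-fsum, lex)[1]
    } else best <- 1
    nm <- cand[[best]]
    keep_nodes <- union(keep_nodes, nm)
    keep_keys <- union(keep_keys, paste(nm[-length(nm)], nm[-1]))
  }
  e <- subnet$net$edges
  e <- e[paste(e$source, e$target) %in% keep_keys, , drop = FALSE]
  net <- signaling_network(e, target_nodes = intersect(targets, keep_nodes),
                           tf_nodes = tf,
                           nodes = intersect(subnet$net$nodes, keep_nodes))
  structure(list(net = net, targets = net$target_nodes, tf = tf,
                 drug = subnet$drug, edge_freq = ef),
            class = "moa_subnetwork")
}

#' In-silico knockout of signaling nodes
#'
#' Adds a strongly negative value (default -10) to the node-space input of
#' the listed nodes, optionally on top of a drug's signal (full,
#' known-targets-only, or off-target-only), and propagates for at least 120
#' steps. With `level = 0` the run is identical to the no-knockout run.
#'
#' @param model a `dtn_model`, `trained_model` or `dtn_ensemble`.
#' @param nodes nodes to knock out.
#' @param level input offset applied to those nodes (default -10).
#' @param drug optional drug whose signal to combine with the knockout.
#' @param dose scaled dose for the drug signal (default 1).
#' @param signal `"none"`, `"full"`, `"on_target"` (prior targets only) or
#'   `"off_target"` (complement).
#' @param min_steps minimum propagation steps (default 120).
#' @return for an ensemble: list with `mean` (TF activities) and
#'   `per_model`; otherwise the TF-activity matrix (1 x TFs).
#' @export
insilico_knockout <- function(model, nodes, level = -10, drug = NULL,
                              dose = 1, signal = c("none", "full", "on_target",
                                                   "off_target"),
                              min_steps = 120) {
  signal <- match.arg(signal)
  if (inherits(model, "dtn_ensemble")) {
    per <- lapply(model$members, function(m)
      insilico_knockout(m, nodes, level, drug, dose, signal, min_steps))
    return(list(mean = Reduce(`+`, per) / length(per), per_model = per))
  }
  if (inherits(model, "trained_model")) model <- model$model
  bad <- setdiff(nodes, model$nodes)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  d <- length(model$dm$drug_ids)
  if (!is.null(drug) && signal != "none") {
    di <- match(drug, model$dm$drug_ids)
    if (is.na(di)) stop("unknown drug: ", drug)
    X <- matrix(0, 1, d); X[1, di] <- dose
    S <- drug_forward(model$dm, X, training = FALSE)$S
    if (signal != "full") {
      basal <- .basal_signal(model$dm)
      Sm <- mask_offtarget_signal(S, model$dm$prior, drug, basal = basal)
      S <- if (signal == "on_target") Sm else S - Sm + rep(basal, each = nrow(S))
    }
  } else {
    S <- matrix(0, 1, length(model$target_ids),
                dimnames = list(NULL, model$target_ids))
  }
  U <- .scatter_signal(model, S)
  U[, match(nodes, model$nodes)] <- U[, match(nodes, model$nodes)] + level
  traj <- propagate_steady_state(U, model$W, model$b, tf_idx = model$tf_idx,
                                 max_steps = max(model$config$max_steps, min_steps),
                                 min_steps = min_steps,
                                 tol = model$config$tol,
                                 leak = model$config$leak, knot = model$config$knot)
  Y <- project_to_tf(traj$state, model$wp, model$tf_idx)
  colnames(Y) <- model$tf_ids
  Y
}

#' Write a MoA subnetwork as SIF + node attributes
#'
#' Writes the signed edge list via [write_network()] and, alongside it, a
#' `<path>.nodes.tsv` attribute table with node roles and consensus
#' frequencies, suitable for graph viewers.
#'
#' @param subnet a `moa_subnetwork`.
#' @param path output SIF/TSV path.
#' @return invisibly, `path`.
#' @export
write_moa <- function(subnet, path) {
  write_network(subnet$net, path)
  nf <- if (is.null(subnet$node_freq)) rep(NA_real_, length(subnet$net$nodes)) else
    subnet$node_freq[match(subnet$net$nodes, names(subnet$node_freq))]
  attrs <- data.frame(node = subnet$net$nodes,
                      role = ifelse(subnet$net$nodes %in% subnet$targets, "target",
                                    ifelse(subnet$net$nodes == subnet$tf, "tf", "intermediate")),
                      frequency = nf)
  utils::write.table(attrs, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
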