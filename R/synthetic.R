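#' Generate a toy signaling network
#'
#' Random signed directed graph with the pathway-modular structure of real
#' signaling: each drug-target node roots its own cascade (a short chain of
#' intermediate kinase-like nodes ending in that module's TFs), and modules
#' exchange sparse forward crosstalk edges, so distinct targets drive
#' largely distinct transcriptional programs. Every target reaches at least
#' one TF and every TF is reachable, hence the network survives
#' [trim_network()] unchanged. A fraction of backward (feedback) edges is
#' added on top — `feedback_fraction = 0` yields an acyclic graph. About
#' 70% of edges are activating, mimicking the activation bias of curated
#' signaling networks.
#'
#' @param n_nodes,n_targets,n_tfs network size (targets + TFs <= nodes).
#' @param edge_density probability of each potential forward crosstalk edge
#'   between modules (default 0.04).
#' @param feedback_fraction feedback edges as a fraction of total edges.
#' @param seed integer seed.
#' @param p_activation probability of a +1 edge sign (default 0.7).
#' @return a [signaling_network()] with `target_nodes` and `tf_nodes` set.
#' @export
generate_toy_network <- function(n_nodes = 40, n_targets = 8, n_tfs = 12,
                                 edge_density = 0.04, feedback_fraction = 0.1,
                                 seed = 1, p_activation = 0.7) {
  if (n_targets + n_tfs > n_nodes) stop("n_targets + n_tfs must be <= n_nodes")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  targets <- nodes[seq_len(n_targets)]
  tfs <- nodes[seq(n_nodes - n_tfs + 1, n_nodes)]
  middles <- setdiff(nodes, c(targets, tfs))
  # round-robin assignment of intermediates and TFs to target-rooted modules
  mod_mid <- split(middles, rep_len(seq_len(n_targets), length(middles)))
  mod_tf <- split(tfs, rep_len(seq_len(n_targets), length(tfs)))
  el <- list()
  add <- function(from, to) el[[length(el) + 1]] <<- c(from, to)
  for (k in seq_len(n_targets)) {
    chain <- c(targets[k], mod_mid[[min(k, length(mod_mid))]])
    for (i in seq_len(length(chain) - 1)) add(chain[i], chain[i + 1])
    ends <- if (length(chain) > 1) chain[-1] else chain
    for (f in mod_tf[[min(k, length(mod_tf))]]) {
      add(ends[length(ends)], f)
      if (length(ends) > 1 && stats::runif(1) < 0.5) add(ends[1], f)
    }
  }
  # sparse forward crosstalk between modules (node order = forward order)
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i < j && stats::runif(1) < edge_density) add(nodes[i], nodes[j])
    }
  }
  el <- unique(do.call(rbind, el))
  # feedback edges (backward in node order) between on-path nodes
  n_fb <- round(feedback_fraction * nrow(el))
  if (n_fb > 0) {
    src <- sample(seq(2, n_nodes), n_fb, replace = TRUE)
    fb <- cbind(nodes[src],
                nodes[vapply(src, function(j) sample.int(j - 1, 1), 0L)])
    el <- unique(rbind(el, fb))
  }
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  edges <- data.frame(source = el[, 1],
                      sign = ifelse(stats::runif(nrow(el)) < p_activation, 1L, -1L),
                      target = el[, 2], stringsAsFactors = FALSE)
  net <- signaling_network(edges, target_nodes = targets, tf_nodes = tfs,
                           nodes = nodes)
  trimmed <- trim_network(net)
  if (length(trimmed$nodes) != n_nodes) {
    stop("toy network generation failed to produce a trim-stable graph")
  }
  net
}

#' Generate a ground-truth model with planted off-target interactions
#'
#' Samples true signaling weights consistent with the prior signs (rescaled
#' so the linear-regime spectral radius is at most 80% of the convergence
#' target), a true drug-target table in which drugs come in chemical
#' clusters sharing a common target, and clustered synthetic fingerprints
#' (cluster members share most of their set bits and so are chemically
#' similar, like parent compounds and their analogs — the mechanism that
#' lets similarity-mediated inference recover withheld interactions).
#' `n_planted` cluster-shared interactions are withheld from the disclosed
#' prior: they are real in the generative model but unknown to the fitted
#' one, and are chosen among the plantable candidates as those whose
#' counterfactual footprint on TFs unreachable from the drug's other
#' targets is largest (recovery must be possible in principle).
#'
#' @param net a [signaling_network()] from [generate_toy_network()].
#' @param n_drugs number of drugs (clustered in pairs).
#' @param n_planted number of withheld (planted off-target) interactions.
#' @param weight_scale typical magnitude of true drug-target weights.
#' @param seed integer seed.
#' @param n_bits fingerprint length (default 2048).
#' @param bits_per_drug set bits per fingerprint (default 120).
#' @param cluster_bit_share fraction of set bits shared within a chemical
#'   cluster (default 0.85, Tanimoto ~0.74 between cluster members).
#' @return list of class `ground_truth`: `net`, `W_true`, `b_true`,
#'   `wp_true`, `truth` (full true drug-target table), `prior` (disclosed
#'   part), `planted` (withheld rows), `fingerprints`, `Wsim`, `seed`.
#' @export
generate_ground_truth <- function(net, n_drugs = 10, n_planted = 1,
                                  weight_scale = 1.0, seed = 1,
                                  n_bits = 2048, bits_per_drug = 120,
                                  cluster_bit_share = 0.85) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nodes <- net$nodes
  n <- length(nodes)
  ei <- cbind(match(net$edges$target, nodes), match(net$edges$source, nodes))
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[ei] <- net$edges$sign * abs(stats::rnorm(nrow(ei), 1, 0.2))
  rho0 <- max(Mod(eigen(W, only.values = TRUE)$values))
  cap <- 0.8 * target_rho()
  if (rho0 > cap) W <- W * cap / rho0
  # basal bias: a small constitutive term plus compensation of incoming
  # inhibition, so repressed nodes sit mid-range instead of pinned at zero
  # and both activating and inhibitory drug effects stay visible
  b <- stats::runif(n, 0.05, 0.15) + 0.4 * rowSums(pmax(-W, 0))
  # drug-target nodes idle at mid-range activity so that both activating
  # and inhibitory perturbations produce visible downstream swings
  ti <- match(net$target_nodes, nodes)
  b[ti] <- stats::runif(length(ti), 0.4, 0.6)
  wp <- rep(1, length(net$tf_nodes))

  drugs <- sprintf("D%02d", seq_len(n_drugs))
  # chemical clusters of two; a leftover drug forms a singleton
  cl <- rep(seq_len(ceiling(n_drugs / 2)), each = 2)[seq_len(n_drugs)]
  tpool <- net$target_nodes
  n_cl <- max(cl)
  if (n_cl > length(tpool)) stop("not enough target nodes for the requested drug clusters")
  shared <- sample(tpool, n_cl)
  # Each cluster is a parent compound plus a selective analog: the parent
  # hits the cluster's shared target and one other cluster's shared target
  # (promiscuity, as in real kinase pharmacology - every target in play is
  # hit by several drugs, so no drug's response can be absorbed by a pathway
  # private to it); the analog hits only the shared target. Planting
  # withholds a parent's shared-target interaction: its effect remains in
  # the data, and the chemically similar analog's channel is the clean
  # similarity-mediated route through which it can be recovered.
  truth <- list()
  for (i in seq_len(n_drugs)) {
    first <- i == which(cl == cl[i])[1]
    tg <- shared[cl[i]]
    sgn <- if (first) sample(c(-1L, 1L), 1) else truth[[which(cl == cl[i])[1]]]$sign[1]
    extra <- if (first) sample(setdiff(shared, tg), 1) else character()
    truth[[i]] <- data.frame(
      drug = drugs[i],
      target = c(tg, extra),
      sign = c(sgn, sample(c(-1L, 1L), length(extra), replace = TRUE)),
      weight = stats::runif(1 + length(extra), 0.8 * weight_scale,
                            1.3 * weight_scale),
      shared = c(TRUE, rep(FALSE, length(extra))))
  }
  truth <- do.call(rbind, truth)
  # Effect-size repair: every true interaction must leave a measurable
  # footprint on the TF readout (relative to the per-TF spread across all
  # conditions), otherwise neither this nor any other method could recover
  # it. Interactions with a weak counterfactual effect get their weight
  # bumped, up to a cap.
  tf_idx0 <- match(net$tf_nodes, nodes)
  sim_tf <- function(rows, dose) {
    u <- rep(0, n)
    u[match(rows$target, nodes)] <- u[match(rows$target, nodes)] +
      scale_dose(dose) * rows$sign * rows$weight
    propagate_steady_state(matrix(u, 1), W, b, tf_idx = tf_idx0)$state[1, tf_idx0]
  }
  dose_grid <- c(0.3, 1, 3)
  for (round in 1:4) {
    resp <- do.call(rbind, lapply(unique(truth$drug), function(d) {
      t(vapply(dose_grid, function(dd) sim_tf(truth[truth$drug == d, ], dd),
               numeric(length(tf_idx0))))
    }))
    sd_tf <- pmax(apply(resp, 2, stats::sd), 1e-3)
    bumped <- FALSE
    for (i in seq_len(nrow(truth))) {
      rows <- truth[truth$drug == truth$drug[i], , drop = FALSE]
      delta <- sim_tf(rows, 3) -
        sim_tf(rows[rows$target != truth$target[i], , drop = FALSE], 3)
      if (mean(abs(delta) / sd_tf) < 0.3 &&
          truth$weight[i] < 3 * weight_scale) {
        truth$weight[i] <- truth$weight[i] * 1.6
        bumped <- TRUE
      }
    }
    if (!bumped) break
  }
  # plant: withhold a parent's shared interaction (its analog keeps it).
  # Among the plantable candidates, prefer the interaction whose target
  # drives TFs that none of the drug's remaining targets can reach: an
  # off-target is only recoverable in principle if its transcriptional
  # footprint is not reproducible through the drug's known targets.
  cl2 <- cl[match(truth$drug, drugs)]
  in_pair <- truth$shared & cl2 %in% which(tabulate(cl) == 2)
  first_member <- !duplicated(paste(cl2, truth$target)) # parent's copy
  cand <- which(in_pair & truth$shared & first_member)
  if (n_planted > length(cand)) stop("n_planted exceeds plantable interactions")
  g <- .net_igraph(net)
  tf_idx <- match(net$tf_nodes, nodes)
  reach_tfs <- function(from) {
    intersect(names(igraph::subcomponent(g, from, mode = "out")), net$tf_nodes)
  }
  sim_drug <- function(rows) {
    u <- rep(0, n)
    u[match(rows$target, nodes)] <- u[match(rows$target, nodes)] +
      scale_dose(10) * rows$sign * rows$weight
    propagate_steady_state(matrix(u, 1), W, b, tf_idx = tf_idx)$state[1, tf_idx]
  }
  plant_score <- vapply(cand, function(i) {
    rows <- truth[truth$drug == truth$drug[i], , drop = FALSE]
    others <- setdiff(rows$target, truth$target[i])
    priv <- setdiff(reach_tfs(truth$target[i]),
                    unique(unlist(lapply(others, reach_tfs))))
    if (length(priv) == 0) return(0)
    delta <- sim_drug(rows) - sim_drug(rows[rows$target != truth$target[i], , drop = FALSE])
    sum(abs(delta[match(priv, net$tf_nodes)]))
  }, numeric(1))
  cand <- cand[order(-plant_score, cand)]
  planted_ix <- if (n_planted > 0) cand[seq_len(n_planted)] else integer()
  planted <- truth[planted_ix, , drop = FALSE]
  prior <- truth[setdiff(seq_len(nrow(truth)), planted_ix), , drop = FALSE]
  rownames(planted) <- rownames(prior) <- NULL

  # clustered fingerprints: cluster members share most of their set bits
  # (85% by default, Tanimoto ~0.74 - typical of close structural analogs,
  # comfortably above the 0.5-0.6 similarity threshold that separates
  # "similar" from "dissimilar" compounds)
  bits <- matrix(0L, n_drugs, n_bits, dimnames = list(drugs, NULL))
  n_shared <- round(cluster_bit_share * bits_per_drug)
  for (c_i in seq_len(n_cl)) {
    members <- which(cl == c_i)
    core <- sample.int(n_bits, n_shared)
    for (m in members) {
      own <- sample(setdiff(seq_len(n_bits), core), bits_per_drug - n_shared)
      bits[m, c(core, own)] <- 1L
    }
  }
  fps <- fingerprint_set(bits, drugs)
  structure(list(net = net, W_true = W, b_true = b, wp_true = wp,
                 truth = truth, prior = prior, planted = planted,
                 fingerprints = fps, Wsim = similarity_matrix(fps),
                 clusters = stats::setNames(cl, drugs), seed = seed),
            class = "ground_truth")
}

#' Simulate a TF-activity dataset from a ground truth
#'
#' For each (drug, dose) condition the true drug signal is built from the
#' full truth table (`dose_scaled * weight * sign` on each true target),
#' propagated through the true signaling parameters to steady state, and
#' projected to TF activities; iid Gaussian noise is added and values are
#' clipped to `[0, 1]`. The returned activity matrix is then standardized
#' per TF to the unit interval with [rescale_tf_activity()] — the same
#' scaling applied to real enrichment-score activities before fitting — so
#' that every TF's dynamic range, and hence the fitting loss, lives on the
#' scale the model's fixed loss coefficients were designed for. The
#' unscaled matrices are kept as `Y_raw` / `Y_clean`. Optional replicates
#' share the noiseless mean and differ only in noise.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param doses dose grid in micromolar (default 0.3, 1, 3; scaled
#'   inputs stay in the activation function's sensitive range).
#' @param noise_sd Gaussian noise standard deviation (default 0.01).
#' @param replicates replicate signatures per condition (default 1).
#' @param seed integer seed.
#' @return list: `conditions` (a [condition_table()]), `Y` (samples x TFs),
#'   `replicates` (a [replicate_set()] when `replicates > 1`), `Y_clean`.
#' @export
simulate_dataset <- function(gt, doses = c(0.3, 1, 3), noise_sd = 0.01,
                             replicates = 1, seed = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  net <- gt$net
  drugs <- unique(gt$truth$drug)
  grid <- expand.grid(drug = drugs, dose_uM = doses, stringsAsFactors = FALSE)
  grid <- grid[order(grid$drug, grid$dose_uM), ]
  samples <- data.frame(sample = sprintf("%s_%guM", grid$drug, grid$dose_uM),
                        drug = grid$drug, dose_uM = grid$dose_uM,
                        group = sprintf("%s_%guM", grid$drug, grid$dose_uM))
  cond <- condition_table(samples, drug_ids = drugs)
  # true drug signal on target nodes
  S <- matrix(0, nrow(samples), length(net$target_nodes),
              dimnames = list(samples$sample, net$target_nodes))
  for (i in seq_len(nrow(samples))) {
    rows <- gt$truth[gt$truth$drug == samples$drug[i], , drop = FALSE]
    S[i, rows$target] <- scale_dose(samples$dose_uM[i]) * rows$sign * rows$weight
  }
  U <- matrix(0, nrow(S), length(net$nodes), dimnames = list(rownames(S), net$nodes))
  U[, net$target_nodes] <- S
  tf_idx <- match(net$tf_nodes, net$nodes)
  traj <- propagate_steady_state(U, gt$W_true, gt$b_true, tf_idx = tf_idx)
  if (!traj$converged) stop("ground-truth model did not converge")
  Yc <- project_to_tf(traj$state, gt$wp_true, tf_idx)
  dimnames(Yc) <- list(samples$sample, net$tf_nodes)
  clip01 <- function(m) pmin(pmax(m, 0), 1)
  if (replicates > 1) {
    rep_rows <- Yc[rep(seq_len(nrow(Yc)), each = replicates), , drop = FALSE]
    noise <- matrix(stats::rnorm(length(rep_rows), 0, noise_sd),
                    nrow(rep_rows), ncol(rep_rows))
    R <- clip01(rep_rows + noise)
    rg <- rep(samples$sample, each = replicates)
    rownames(R) <- paste0(rg, "_r", seq_len(replicates))
    reps <- replicate_set(R, rg)
    Yr <- merge_replicates(reps)[samples$sample, , drop = FALSE]
    list(conditions = cond, Y = rescale_tf_activity(Yr), Y_raw = Yr,
         Y_clean = clip01(Yc), replicates = reps)
  } else {
    noise <- matrix(stats::rnorm(length(Yc), 0, noise_sd), nrow(Yc), ncol(Yc))
    Yr <- clip01(Yc + noise)
    list(conditions = cond, Y = rescale_tf_activity(Yr), Y_raw = Yr,
         Y_clean = clip01(Yc), replicates = NULL)
  }
}
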