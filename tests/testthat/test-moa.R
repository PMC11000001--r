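# a small hand-built model with fully controlled weights, used by several
# interpretation tests: two targets feeding separate branches into one TF
#   T1 -> M1 -> F1 ;  T2 -> M2 -> F1 ;  T1 -> F2
hand_model <- function(w_m1 = 0.8, w_m2 = 0.2) {
  edges <- data.frame(
    source = c("T1", "M1", "T2", "M2", "T1"),
    sign = 1L,
    target = c("M1", "F1", "M2", "F1", "F2"))
  net <- signaling_network(edges, target_nodes = c("T1", "T2"),
                           tf_nodes = c("F1", "F2"))
  drugs <- c("a", "b")
  Wsim <- diag(1, 2); dimnames(Wsim) <- list(drugs, drugs)
  prior <- data.frame(drug = c("a", "b"), target = c("T1", "T2"),
                      sign = c(1L, 1L))
  m <- build_model(net, prior, Wsim, config = list(dropout_rate = 0))
  m$W[] <- 0
  m$W["M1", "T1"] <- 0.6; m$W["F1", "M1"] <- w_m1
  m$W["M2", "T2"] <- 0.6; m$W["F1", "M2"] <- w_m2
  m$W["F2", "T1"] <- 0.5
  m$b[] <- 0
  m$wp[] <- 1
  # neutral batch norm
  m$dm$bn$gamma[] <- 1; m$dm$bn$beta[] <- 0
  m$dm$bn$rmean[] <- 0; m$dm$bn$rvar[] <- 1 - m$dm$bn$eps
  m$dm$WDT[] <- 0; m$dm$WDT["a", "T1"] <- 1; m$dm$WDT["b", "T2"] <- 1
  m
}

test_that("delta-TF is zero without off-target signal and flags planted effects", {
  m <- hand_model()
  ct <- condition_table(data.frame(sample = c("s1", "s2"), drug = c("a", "b"),
                                   dose_uM = c(9, 9)),
                        drug_ids = c("a", "b"))
  tm <- structure(list(model = m), class = "trained_model")
  rep_ <- delta_tf(list(tm), ct, m$dm$prior)
  expect_true(all(rep_$delta == 0))       # signal confined to prior targets
  expect_false(any(rep_$flagged))

  # inject an off-target route: drug a also signals T2
  m2 <- m; m2$dm$WDT["a", "T2"] <- 1
  tm2 <- structure(list(model = m2), class = "trained_model")
  rep2 <- delta_tf(list(tm2), ct, m$dm$prior)
  d_a_f1 <- rep2$delta[rep2$drug == "a" & rep2$tf == "F1"]
  expect_gt(abs(d_a_f1), 0)
  # drug b is untouched
  expect_true(all(rep2$delta[rep2$drug == "b"] == 0))

  # activity gate: mid-range activity is never flagged even with large delta
  perf <- data.frame(tf = c("F1", "F2"), train_r = 1, val_r = 1)
  rep3 <- delta_tf(list(tm2), ct, m$dm$prior, performance = perf,
                   act_hi = 0.999, act_lo = 0.001)
  expect_false(any(rep3$flagged))
})

test_that("node and edge importance track the active branch", {
  m <- hand_model(w_m1 = 0.8, w_m2 = 0.2)
  sc <- node_edge_importance(m, "a", "F1", dose = 1)
  # nodes on drug a's path to F1 score higher than the unused branch
  expect_gt(sc$node_scores[["M1"]], sc$node_scores[["M2"]])
  # disconnected-from-drug node M2 has zero range under drug a's signal
  expect_equal(sc$range[[match("M2", names(sc$node_scores))]], 0)
  expect_equal(sc$node_scores[["M2"]], 0)
  expect_true(all(sc$node_scores >= 0))
  expect_true(all(sc$edge_scores$score >= 0))
  # edge on the path has positive importance; unused branch edge zero
  es <- sc$edge_scores
  expect_gt(es$score[es$source == "M1" & es$target == "F1"], 0)
  expect_equal(es$score[es$source == "M2" & es$target == "F1"], 0)
  # score ordering agrees with a perturb-and-measure oracle on the two branches
  base <- insilico_knockout(m, "M1", level = 0, drug = "a", signal = "full")
  ko1 <- insilico_knockout(m, "M1", level = -10, drug = "a", signal = "full")
  ko2 <- insilico_knockout(m, "M2", level = -10, drug = "a", signal = "full")
  eff1 <- abs(ko1[1, "F1"] - base[1, "F1"])
  eff2 <- abs(ko2[1, "F1"] - base[1, "F1"])
  expect_gt(eff1, eff2)
  expect_error(node_edge_importance(m, "a", "nope"), "not in model")
})

test_that("MoA pruning keeps target-to-TF connectivity and drops weak branches", {
  m <- hand_model(w_m1 = 0.8, w_m2 = 0.05)
  # drug a, focal TF F1: only the T1 -> M1 -> F1 branch matters
  sub <- prune_moa_subnetwork(m, "a", "F1")
  expect_s3_class(sub, "moa_subnetwork")
  expect_true("T1" %in% sub$net$nodes)
  expect_true("F1" %in% sub$net$nodes)
  g <- moanet:::.net_igraph(sub$net)
  expect_gt(length(moanet:::.connected_targets(g, sub$targets, "F1")), 0)
  # the unused branch is pruned away
  expect_false("M2" %in% sub$net$nodes)
  # a pure single-path network survives pruning unchanged
  expect_error(prune_moa_subnetwork(m, "b", "F2"), "empty mechanism")
})

test_that("MoA pruning preserves connectivity on random toys", {
  for (seed in 1:10) {
    net <- generate_toy_network(n_nodes = 16, n_targets = 3, n_tfs = 4,
                                seed = seed)
    gt <- generate_ground_truth(net, n_drugs = 4, n_planted = 0, seed = seed)
    m <- build_model(net, gt$prior[, c("drug", "target", "sign")], gt$Wsim,
                     init_seed = seed)
    drug <- gt$prior$drug[1]
    tf <- net$tf_nodes[1]
    sc <- node_edge_importance(m, drug, tf)
    sub <- tryCatch(prune_moa_subnetwork(m, drug, tf, scores = sc),
                    error = function(e) NULL)
    if (is.null(sub)) next   # no path from this drug's targets to this TF
    g <- moanet:::.net_igraph(sub$net)
    expect_gt(length(moanet:::.connected_targets(g, sub$targets, tf)), 0)
    expect_true(all(sub$net$nodes %in% net$nodes))
  }
})

test_that("ensemble subnetwork merging applies the 50% consensus rule", {
  mk <- function(extra_edge = FALSE) {
    e <- data.frame(source = c("T", "M"), sign = 1L, target = c("M", "F"))
    if (extra_edge) e <- rbind(e, data.frame(source = "T", sign = 1L, target = "F"))
    structure(list(net = signaling_network(e, "T", "F"),
                   targets = "T", tf = "F", drug = "a"),
              class = "moa_subnetwork")
  }
  subs <- c(replicate(9, mk(FALSE), simplify = FALSE), list(mk(TRUE)))
  merged <- merge_ensemble_subnetworks(subs)
  # identical backbone kept; 1-of-10 shortcut edge dropped
  expect_true(all(c("T", "M", "F") %in% merged$net$nodes))
  expect_equal(nrow(merged$net$edges), 2)
  # identical subnets merge to any member
  same <- merge_ensemble_subnetworks(replicate(4, mk(FALSE), simplify = FALSE))
  key <- function(e) sort(paste(e$source, e$sign, e$target))
  expect_equal(key(same$net$edges), key(mk(FALSE)$net$edges))
  expect_equal(unname(merged$edge_freq[["T\tM\t1"]]), 1)
})

test_that("simplest paths equal BFS distances and break ties by frequency", {
  # diamond with a long and a short branch
  e <- data.frame(source = c("T", "A", "B", "T", "C"), sign = 1L,
                  target = c("A", "B", "F", "C", "F"))
  net <- signaling_network(e, "T", "F")
  sub <- structure(list(net = net, targets = "T", tf = "F", drug = "a",
                        edge_freq = NULL), class = "moa_subnetwork")
  sp <- simplest_paths(sub)
  # short branch T -> C -> F chosen (2 edges vs 3)
  expect_true(all(c("T", "C", "F") %in% sp$net$nodes))
  expect_false("A" %in% sp$net$nodes)

  # equal-length paths: higher summed edge frequency wins
  e2 <- data.frame(source = c("T", "P", "T", "Q"), sign = 1L,
                   target = c("P", "F", "Q", "F"))
  net2 <- signaling_network(e2, "T", "F")
  ef <- c("T\tP\t1" = 0.9, "P\tF\t1" = 0.9, "T\tQ\t1" = 0.3, "Q\tF\t1" = 0.3)
  sub2 <- structure(list(net = net2, targets = "T", tf = "F", drug = "a",
                         edge_freq = ef), class = "moa_subnetwork")
  sp2 <- simplest_paths(sub2)
  expect_true("P" %in% sp2$net$nodes)
  expect_false("Q" %in% sp2$net$nodes)

  # path lengths match a BFS oracle on random DAGs
  for (seed in 1:5) {
    net3 <- generate_toy_network(n_nodes = 14, n_targets = 2, n_tfs = 3,
                                 feedback_fraction = 0, seed = seed)
    sub3 <- structure(list(net = net3, targets = net3$target_nodes,
                           tf = net3$tf_nodes[1], edge_freq = NULL,
                           drug = NA), class = "moa_subnetwork")
    sp3 <- suppressWarnings(simplest_paths(sub3))
    g <- moanet:::.net_igraph(net3)
    gp <- moanet:::.net_igraph(sp3$net)
    for (t in sp3$targets) {
      d_full <- igraph::distances(g, t, sub3$tf, mode = "out")
      d_sub <- igraph::distances(gp, t, sub3$tf, mode = "out")
      expect_equal(as.numeric(d_sub), as.numeric(d_full))
    }
  }
})

test_that("in-silico knockouts behave as signal surgery", {
  m <- hand_model()
  base <- insilico_knockout(m, "M1", level = 0, drug = "a", signal = "full")
  no_ko <- {
    X <- matrix(c(1, 0), 1, 2); colnames(X) <- c("a", "b")
    predict(m, X)
  }
  # level 0 is identical to the unperturbed run
  expect_equal(base[1, ], no_ko[1, ], tolerance = 1e-9)
  # knocking out a node with no path to F2 leaves F2 unchanged
  ko <- insilico_knockout(m, "M2", level = -10, drug = "a", signal = "full")
  expect_equal(ko[1, "F2"], base[1, "F2"], tolerance = 1e-9)
  # stronger negative levels never increase a purely activating downstream TF
  prev <- Inf
  for (lev in c(0, -1, -5, -10)) {
    val <- insilico_knockout(m, "M1", level = lev, drug = "a",
                             signal = "full")[1, "F1"]
    expect_lte(val, prev + 1e-12)
    prev <- val
  }
  expect_error(insilico_knockout(m, "XX"), "unknown node")
})

test_that("knockout of a planted off-target reproduces the masked-signal direction", {
  m <- hand_model()
  m$dm$WDT["a", "T2"] <- 1     # off-target route of drug a onto T2
  ct <- condition_table(data.frame(sample = "s1", drug = "a", dose_uM = 9),
                        drug_ids = c("a", "b"))
  tm <- structure(list(model = m), class = "trained_model")
  rep_ <- delta_tf(list(tm), ct, m$dm$prior)
  d_f1 <- rep_$delta[rep_$tf == "F1"]
  # knocking out the off-target node moves F1 in the same direction as masking
  full <- insilico_knockout(m, "T2", level = 0, drug = "a", signal = "full")
  ko <- insilico_knockout(m, "T2", level = -10, drug = "a", signal = "full")
  expect_equal(unname(sign(full[1, "F1"] - ko[1, "F1"])), unname(sign(d_f1)))
})
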