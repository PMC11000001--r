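# Shared fixtures, built once per test run and cached.
.fx <- new.env()

fixture_small <- function() {
  if (is.null(.fx$small)) {
    net <- generate_toy_network(n_nodes = 18, n_targets = 4, n_tfs = 5,
                                seed = 11)
    gt <- generate_ground_truth(net, n_drugs = 6, n_planted = 1, seed = 11)
    sim <- simulate_dataset(gt, seed = 11)
    .fx$small <- list(net = net, gt = gt, sim = sim,
                      prior = gt$prior[, c("drug", "target", "sign")])
  }
  .fx$small
}

# a quickly trained single model on the small fixture
fixture_trained <- function() {
  if (is.null(.fx$trained)) {
    fx <- fixture_small()
    .fx$trained <- train_model(fx$sim$conditions, fx$sim$Y, fx$net, fx$prior,
                               fx$gt$Wsim,
                               config = train_config(epochs = 400, seed = 2))
  }
  .fx$trained
}

# the flagship fixture + ensemble (shared by the recovery and lambda-sweep
# acceptance checks); sizes documented in the methods vignette
fixture_flagship <- function() {
  if (is.null(.fx$flag)) {
    net <- generate_toy_network(seed = 3)
    gt <- generate_ground_truth(net, seed = 3)
    sim <- simulate_dataset(gt, seed = 3)
    .fx$flag <- list(net = net, gt = gt, sim = sim,
                     prior = gt$prior[, c("drug", "target", "sign")])
  }
  .fx$flag
}

fixture_flagship_ensemble <- function() {
  if (is.null(.fx$flag_ens)) {
    fx <- fixture_flagship()
    .fx$flag_ens <- train_ensemble(
      fx$sim$conditions, fx$sim$Y, fx$net, fx$prior, fx$gt$Wsim,
      config = train_config(epochs = 2500, ensemble_size = 10, seed = 1))
  }
  .fx$flag_ens
}

write_lines_tsv <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}
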