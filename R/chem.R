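#' Fingerprint sets and Tanimoto similarity
#'
#' A `fingerprint_set` stores one fixed-length binary fingerprint per drug
#' (ECFP4-style circular fingerprints, conventionally 2048 bits). The package
#' operates on precomputed bit vectors; computing fingerprints from structures
#' is left to standard cheminformatics toolkits.
#'
#' @param bits numeric/integer matrix (drugs x bits) with entries in {0,1},
#'   or a list of equal-length 0/1 vectors.
#' @param drug_ids drug identifiers; defaults to rownames/list names.
#' @return object of class `fingerprint_set` (list with `drug_ids`, `bits`).
#' @export
fingerprint_set <- function(bits, drug_ids = NULL) {
  if (is.list(bits) && !is.matrix(bits)) {
    if (is.null(drug_ids)) drug_ids <- names(bits)
    bits <- do.call(rbind, bits)
  }
  bits <- as.matrix(bits)
  if (is.null(drug_ids)) drug_ids <- rownames(bits)
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(nrow(bits)))
  if (!all(bits %in% c(0, 1))) stop("fingerprint entries must be 0/1")
  storage.mode(bits) <- "integer"
  rownames(bits) <- drug_ids
  structure(list(drug_ids = drug_ids, bits = bits), class = "fingerprint_set")
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`. Undefined when both vectors are all-zero; this is
#' raised as an error rather than silently mapped to 0, because an empty
#' fingerprint signals an upstream featurization failure.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprints must have equal length")
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0) stop("Tanimoto similarity undefined: both fingerprints are all-zero")
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps a [fingerprint_set()].
#' @return symmetric d x d matrix with unit diagonal, dimnames = drug ids.
#' @export
similarity_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  B <- fps$bits != 0
  storage.mode(B) <- "double"
  common <- B %*% t(B)                     # |a AND b|
  sz <- rowSums(B)
  un <- outer(sz, sz, "+") - common        # |a OR b|
  if (any(diag(un) == 0)) {
    stop("Tanimoto similarity undefined: all-zero fingerprint for drug ",
         fps$drug_ids[which(diag(un) == 0)[1]])
  }
  S <- common / un
  dimnames(S) <- list(fps$drug_ids, fps$drug_ids)
  S
}

#' Split drugs into train / chemically dissimilar test sets
#'
#' Every test drug must have Tanimoto similarity strictly below `threshold`
#' to every train drug. Pairs at or above the threshold therefore always land
#' on the same side, i.e. any feasible test set is a union of connected
#' components of the thresholded similarity graph. The split is found by
#' seeded shuffles of those components with greedy packing up to the requested
#' fraction; the achieved fraction may undershoot when the constraint binds.
#'
#' @param sim square similarity matrix with drug-id dimnames.
#' @param test_fraction requested test proportion in (0, 1).
#' @param threshold similarity cutoff in (0, 1]; default 0.5.
#' @param seed integer seed.
#' @param max_attempts shuffles to try before declaring infeasibility.
#' @return list with `train`, `test` (drug-id vectors) and
#'   `achieved_fraction`.
#' @export
dissimilar_split <- function(sim, test_fraction, threshold = 0.5, seed = 1,
                             max_attempts = 1000) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (!(test_fraction > 0 && test_fraction < 1)) stop("test_fraction must be in (0,1)")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0,1]")
  ids <- rownames(sim)
  if (is.null(ids)) ids <- paste0("drug", seq_len(nrow(sim)))
  d <- length(ids)
  adj <- sim >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  comp_ids <- split(ids, comp)
  target_n <- max(1L, round(test_fraction * d))
  best <- NULL
  rng <- .seeded_rng(seed)
  for (attempt in seq_len(max_attempts)) {
    ord <- .rng_sample(rng, length(comp_ids))
    test <- character()
    for (ci in ord) {
      cand <- comp_ids[[ci]]
      if (length(test) + length(cand) <= target_n) test <- c(test, cand)
      if (length(test) >= target_n) break
    }
    if (length(test) > 0 && length(test) < d &&
        (is.null(best) || length(test) > length(best))) {
      best <- test
    }
    if (!is.null(best) && length(best) == target_n) break
  }
  if (is.null(best)) {
    stop("no feasible nonempty chemically dissimilar test set after ",
         max_attempts, " attempts")
  }
  train <- setdiff(ids, best)
  cross <- sim[best, train, drop = FALSE]
  stopifnot(all(cross < threshold))   # contract
  list(train = train, test = sort(best), achieved_fraction = length(best) / d)
}

# Local RNG stream isolated from the global one, so splitting never perturbs
# training reproducibility.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  env
}

.rng_sample <- function(rng, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample.int(n)
  rng$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  out
}

#' Read / write fingerprint and similarity files
#'
#' Fingerprint CSV: first column `drug_id`, remaining columns the 0/1 bits.
#' Similarity CSV: square matrix, first column and header both drug ids.
#'
#' @param path file path.
#' @return [fingerprint_set()] or similarity matrix.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fingerprint_set(as.matrix(df[, -1, drop = FALSE]), drug_ids = df[[1]])
}

#' @rdname read_fingerprints
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m))) stop("similarity CSV must be square with matching ids")
  m
}

#' @rdname read_fingerprints
#' @param sim similarity matrix to write.
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(drug_id = rownames(sim), sim, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
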