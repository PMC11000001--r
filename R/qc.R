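#' Build a replicate set
#'
#' Pairs a replicate-level TF-activity matrix (replicate signatures x TFs)
#' with the grouping of replicate rows into samples.
#'
#' @param activity numeric matrix, rows = replicate signatures, cols = TFs.
#' @param groups factor/character of length `nrow(activity)` assigning every
#'   row to exactly one sample.
#' @return object of class `replicate_set`.
#' @export
replicate_set <- function(activity, groups) {
  activity <- as.matrix(activity)
  stopifnot(length(groups) == nrow(activity))
  structure(list(activity = activity, groups = as.character(groups)),
            class = "replicate_set")
}

#' Filter TFs by replicate variance against a permutation null
#'
#' For each TF, the variance of its activity within each replicate group is
#' compared to a null built by permuting the rows of the activity matrix
#' `n_perm` times (group sizes preserved) and recomputing the per-group
#' variances. A one-tailed Kolmogorov-Smirnov test asks whether the actual
#' within-replicate variances are stochastically *smaller* than the null;
#' TFs with p > `alpha` (i.e. replicate noise indistinguishable from random
#' profiles) are dropped.
#'
#' @param reps a [replicate_set()].
#' @param n_perm number of row permutations (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed permutation seed.
#' @return list: `kept` (TF names), `dropped`, `p` (named per-TF p values).
#' @export
filter_tfs_by_variance <- function(reps, n_perm = 100, alpha = 0.05, seed = 1) {
  stopifnot(inherits(reps, "replicate_set"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  A <- reps$activity
  gl <- split(seq_len(nrow(A)), reps$groups)
  multi <- gl[lengths(gl) >= 2]
  if (length(multi) < 2) {
    warning("fewer than 2 multi-replicate groups: all TFs kept")
    return(list(kept = colnames(A), dropped = character(),
                p = stats::setNames(rep(NA_real_, ncol(A)), colnames(A))))
  }
  group_vars <- function(M) {
    vapply(multi, function(ix) apply(M[ix, , drop = FALSE], 2, stats::var),
           numeric(ncol(M)))   # TFs x groups
  }
  actual <- group_vars(A)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    null[[i]] <- group_vars(A[sample.int(nrow(A)), , drop = FALSE])
  }
  p <- vapply(seq_len(ncol(A)), function(j) {
    nj <- unlist(lapply(null, function(m) m[j, ]))
    aj <- actual[j, ]
    # alternative "greater": CDF of actual lies above the null's,
    # i.e. actual variances stochastically smaller
    suppressWarnings(stats::ks.test(aj, nj, alternative = "greater")$p.value)
  }, numeric(1))
  names(p) <- colnames(A)
  kept <- colnames(A)[p <= alpha]
  list(kept = kept, dropped = setdiff(colnames(A), kept), p = p)
}

#' Filter samples by replicate correlation against a sampling null
#'
#' For each replicate-group size k, a null distribution of mean pairwise
#' Pearson correlations is built from `n_samples` random k-subsets of all
#' signatures. A sample's p value is the fraction of null values greater
#' than or equal to its observed mean pairwise replicate correlation
#' (no smoothing); samples with p > `alpha` are dropped with all their
#' replicates. Singleton groups are kept unconditionally.
#'
#' @param reps a [replicate_set()].
#' @param n_samples null draws per group size (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed sampling seed.
#' @return list: `kept` (sample names), `dropped`, `p` (per sample).
#' @export
filter_replicates_by_correlation <- function(reps, n_samples = 1000,
                                             alpha = 0.05, seed = 1) {
  stopifnot(inherits(reps, "replicate_set"))
  A <- reps$activity
  if (nrow(A) < 3) stop("need at least 3 signatures")
  gl <- split(seq_len(nrow(A)), reps$groups)
  C <- suppressWarnings(stats::cor(t(A)))
  mean_pair_r <- function(ix) {
    cc <- C[ix, ix, drop = FALSE]
    mean(cc[upper.tri(cc)])
  }
  sizes <- sort(unique(lengths(gl)))
  sizes <- sizes[sizes >= 2]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null_by_size <- lapply(sizes, function(k) {
    vapply(seq_len(n_samples), function(i)
      mean_pair_r(sample.int(nrow(A), k)), numeric(1))
  })
  names(null_by_size) <- as.character(sizes)
  p <- vapply(names(gl), function(g) {
    ix <- gl[[g]]
    if (length(ix) < 2) return(0)        # singleton: kept as-is
    obs <- mean_pair_r(ix)
    nd <- null_by_size[[as.character(length(ix))]]
    mean(nd >= obs)
  }, numeric(1))
  kept <- names(gl)[p <= alpha]
  list(kept = kept, dropped = setdiff(names(gl), kept), p = p)
}

#' Merge replicate signatures by the median
#'
#' Element-wise median of each sample's replicate rows (mean of the two
#' middle values for even counts, the standard median convention).
#'
#' @param reps a [replicate_set()].
#' @return samples x TFs matrix, rows ordered by first appearance of each
#'   group.
#' @export
merge_replicates <- function(reps) {
  stopifnot(inherits(reps, "replicate_set"))
  A <- reps$activity
  groups <- unique(reps$groups)
  out <- t(vapply(groups, function(g) {
    rows <- A[reps$groups == g, , drop = FALSE]
    apply(rows, 2, stats::median)
  }, numeric(ncol(A))))
  rownames(out) <- groups
  colnames(out) <- colnames(A)
  out
}

#' Run the full TF-activity QC pipeline
#'
#' Filters TFs by replicate variance, then samples by replicate correlation,
#' then merges replicates by the median — in that order.
#'
#' @param reps a [replicate_set()].
#' @inheritParams filter_tfs_by_variance
#' @param n_corr_samples null draws for the correlation filter.
#' @return list: `activity` (clean samples x TFs matrix), `tf_filter`,
#'   `sample_filter` (the two filter reports).
#' @export
qc_tf_activity <- function(reps, n_perm = 100, n_corr_samples = 1000,
                           alpha = 0.05, seed = 1) {
  tf_f <- filter_tfs_by_variance(reps, n_perm = n_perm, alpha = alpha, seed = seed)
  A <- reps$activity[, tf_f$kept, drop = FALSE]
  reps2 <- replicate_set(A, reps$groups)
  s_f <- filter_replicates_by_correlation(reps2, n_samples = n_corr_samples,
                                          alpha = alpha, seed = seed)
  keep_rows <- reps2$groups %in% s_f$kept
  reps3 <- replicate_set(A[keep_rows, , drop = FALSE], reps2$groups[keep_rows])
  list(activity = merge_replicates(reps3), tf_filter = tf_f, sample_filter = s_f)
}
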