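#' Read standard input tables
#'
#' Tab-separated readers for the pipeline inputs: the drug-target prior
#' (`drug<TAB>target<TAB>sign`), the condition table
#' (`sample<TAB>drug<TAB>dose_uM<TAB>group`) and the TF-activity matrix
#' (first column = sample id, remaining columns = TFs). All files carry a
#' header row.
#'
#' @param path file path.
#' @return `read_drug_prior`: data.frame with `drug`, `target`, `sign`;
#'   `read_conditions`: a [condition_table()]; `read_tf_activity`: numeric
#'   matrix with sample rownames.
#' @export
read_drug_prior <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "target", "sign") %in% names(df)))
  df$sign <- as.integer(df$sign)
  if (!all(df$sign %in% c(-1L, 1L))) stop("prior signs must be +1/-1")
  df
}

#' @rdname read_drug_prior
#' @param drug_ids optional drug universe passed to [condition_table()].
#' @export
read_conditions <- function(path, drug_ids = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  condition_table(df, drug_ids = drug_ids)
}

#' @rdname read_drug_prior
#' @export
read_tf_activity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write standard tables
#'
#' Counterparts of the readers in [read_drug_prior()].
#'
#' @param x object to write.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_drug_prior <- function(x, path) {
  utils::write.table(x[, c("drug", "target", "sign")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drug_prior
#' @export
write_tf_activity <- function(x, path) {
  df <- data.frame(sample = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drug_prior
#' @export
write_conditions <- function(x, path) {
  stopifnot(inherits(x, "condition_table"))
  dose <- 10^(x$X[cbind(seq_along(x$sample_ids), match(x$drug, x$drug_ids))]) - 1
  df <- data.frame(sample = x$sample_ids, drug = x$drug,
                   dose_uM = dose, group = x$group)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
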