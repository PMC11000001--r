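#' Construct a signed signaling network
#'
#' A `signaling_network` is a signed directed graph of protein nodes with two
#' designated subsets: *drug-target nodes* (nodes that appear in a drug-target
#' prior and can receive drug input) and *TF nodes* (transcription factors,
#' whose steady-state activity the model predicts). Node order is the insertion
#' order of first appearance and is preserved by all operations, so that
#' weight-matrix indices are reproducible.
#'
#' @param edges data.frame with columns `source`, `sign` (+1/-1), `target`,
#'   and optionally `source_db` (provenance, carried along but never used).
#' @param target_nodes character vector of drug-target nodes (subset of nodes).
#' @param tf_nodes character vector of TF nodes (subset of nodes). A node may
#'   be both a drug target and a TF.
#' @param nodes optional explicit node order; defaults to first appearance in
#'   `edges`, then any extra nodes in `target_nodes`/`tf_nodes`.
#' @return An object of class `signaling_network` with elements `nodes`,
#'   `edges`, `target_nodes`, `tf_nodes`.
#' @export
signaling_network <- function(edges, target_nodes = character(),
                              tf_nodes = character(), nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "sign", "target") %in% names(edges)))
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop("edge signs must be exactly +1 or -1")
    }
  } else {
    edges <- data.frame(source = character(), sign = integer(),
                        target = character(), stringsAsFactors = FALSE)
  }
  seen <- unique(c(rbind(edges$source, edges$target)))
  if (is.null(nodes)) {
    nodes <- unique(c(seen, target_nodes, tf_nodes))
  } else {
    if (!all(seen %in% nodes)) stop("every edge endpoint must be in nodes")
  }
  # duplicate (source, target) rows: dedupe, conflicting signs are an error
  if (nrow(edges) > 0) {
    key <- paste(edges$source, edges$target, sep = "\r")
    nsign <- tapply(edges$sign, key, function(s) length(unique(s)))
    if (any(nsign > 1)) {
      bad <- names(nsign)[nsign > 1][1]
      stop("contradictory signs for duplicated edge: ",
           gsub("\r", " -> ", bad))
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  if (!all(target_nodes %in% nodes)) stop("target_nodes must be a subset of nodes")
  if (!all(tf_nodes %in% nodes)) stop("tf_nodes must be a subset of nodes")
  structure(list(nodes = nodes, edges = edges,
                 target_nodes = unique(target_nodes),
                 tf_nodes = unique(tf_nodes)),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("signaling_network: %d nodes, %d signed edges (%d drug-target, %d TF nodes)\n",
              length(x$nodes), nrow(x$edges),
              length(x$target_nodes), length(x$tf_nodes)))
  invisible(x)
}

#' Number of nodes / edges of a signaling network
#' @param net a `signaling_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

.parse_sign <- function(tok, line) {
  s <- switch(tolower(tok),
              "1" = 1L, "+1" = 1L, "activation" = 1L, "stimulation" = 1L,
              "-1" = -1L, "inhibition" = -1L,
              NA_integer_)
  if (is.na(s)) stop(sprintf("line %d: unrecognized sign token '%s'", line, tok))
  s
}

#' Read a signed network from a SIF-like TSV file
#'
#' Expected layout: three tab-separated columns `source<TAB>sign<TAB>target`
#' with an optional fourth `source_db` column. Sign tokens may be `1`/`-1` or
#' `activation`/`inhibition`. A header line starting with `source` is skipped.
#' Duplicate rows are collapsed; duplicated (source, target) pairs with
#' conflicting signs raise an error.
#'
#' @param path file path.
#' @param dialect `"sif3"` (bare 3/4 column, header optional) or `"tsv"`
#'   (identical parsing; kept as an explicit dialect tag).
#' @return a [signaling_network()].
#' @export
read_network <- function(path, dialect = c("sif3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(signaling_network(NULL))
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  start <- if (tolower(first[[1]]) == "source") 2L else 1L
  if (start > length(lines)) return(signaling_network(NULL))
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("line %d: expected >= 3 tab-separated fields, got %d", i, length(f)))
    list(source = f[[1]], sign = .parse_sign(f[[2]], i), target = f[[3]],
         source_db = if (length(f) >= 4) f[[4]] else NA_character_)
  })
  edges <- data.frame(
    source = vapply(rows, `[[`, "", "source"),
    sign = vapply(rows, `[[`, 0L, "sign"),
    target = vapply(rows, `[[`, "", "target"),
    source_db = vapply(rows, `[[`, "", "source_db"),
    stringsAsFactors = FALSE)
  if (all(is.na(edges$source_db))) edges$source_db <- NULL
  signaling_network(edges)
}

#' Write a signed network to a SIF-like TSV file
#'
#' Inverse of [read_network()]: `read_network(write_network(net, p))`
#' reproduces the edge list exactly. A header line is always written, so an
#' empty network yields a header-only file. Node subsets (`target_nodes`,
#' `tf_nodes`) are not part of the SIF format and are not serialized.
#'
#' @param net a `signaling_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "signaling_network"))
  has_db <- "source_db" %in% names(net$edges)
  hdr <- c("source", "sign", "target", if (has_db) "source_db")
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(net$edges) > 0) {
    body <- paste(net$edges$source, net$edges$sign, net$edges$target,
                  sep = "\t")
    if (has_db) body <- paste(body, net$edges$source_db, sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

.net_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = net$nodes))
}

#' Trim a network to drug-to-TF relevant nodes
#'
#' Iteratively removes (a) nodes and edges that do not lie on any directed
#' path from a drug-target node to a TF node, (b) nodes whose only source and
#' only target are the node itself (pure self-loop orphans), and (c) drug
#' targets and TFs that fall out of the network, until a fixed point.
#' Reachability is purely topological; edge signs are ignored.
#'
#' @param net a `signaling_network`.
#' @param drug_targets,tfs node sets; default to the subsets stored in `net`.
#' @return the trimmed `signaling_network`, with attributes
#'   `dropped_targets` and `dropped_tfs` listing removed nodes of each role.
#'   The surviving node order preserves the input order.
#' @export
trim_network <- function(net, drug_targets = net$target_nodes, tfs = net$tf_nodes) {
  stopifnot(inherits(net, "signaling_network"))
  if (length(drug_targets) == 0 || length(tfs) == 0) {
    stop("drug_targets and tfs must be nonempty")
  }
  drug_targets <- intersect(net$nodes, drug_targets)
  tfs <- intersect(net$nodes, tfs)
  edges <- net$edges
  nodes <- net$nodes
  repeat {
    cur_t <- intersect(drug_targets, nodes)
    cur_f <- intersect(tfs, nodes)
    if (length(cur_t) == 0 || length(cur_f) == 0) {
      stop("trimming removed every drug target or every TF (empty model)")
    }
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target"), drop = FALSE],
      directed = TRUE, vertices = data.frame(name = nodes))
    # nodes reachable from a target, and nodes that reach a TF
    fwd <- rep(FALSE, length(nodes)); names(fwd) <- nodes
    for (t in cur_t) {
      r <- igraph::subcomponent(g, t, mode = "out")
      fwd[names(r)] <- TRUE
    }
    bwd <- rep(FALSE, length(nodes)); names(bwd) <- nodes
    for (f in cur_f) {
      r <- igraph::subcomponent(g, f, mode = "in")
      bwd[names(r)] <- TRUE
    }
    on_path <- fwd & bwd
    # a node is on a target->TF path iff reachable from a target AND reaches a TF
    keep_nodes <- nodes[on_path]
    # drop pure self-loop nodes: only in- and out-neighbor is the node itself
    self_only <- vapply(keep_nodes, function(v) {
      inn <- setdiff(edges$source[edges$target == v], v)
      out <- setdiff(edges$target[edges$source == v], v)
      has_self <- any(edges$source == v & edges$target == v)
      has_self && length(inn) == 0 && length(out) == 0
    }, logical(1))
    keep_nodes <- keep_nodes[!self_only]
    keep_edges <- edges$source %in% keep_nodes & edges$target %in% keep_nodes
    # an edge must itself lie on a path: source reachable, target reaching
    new_edges <- edges[keep_edges, , drop = FALSE]
    if (length(keep_nodes) == length(nodes) && nrow(new_edges) == nrow(edges)) break
    nodes <- keep_nodes
    edges <- new_edges
  }
  out <- signaling_network(edges,
                           target_nodes = intersect(drug_targets, nodes),
                           tf_nodes = intersect(tfs, nodes),
                           nodes = nodes)
  attr(out, "dropped_targets") <- setdiff(drug_targets, nodes)
  attr(out, "dropped_tfs") <- setdiff(tfs, nodes)
  out
}
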