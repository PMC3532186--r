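#' Undirected protein-protein interaction network
#'
#' Constructs a simple undirected interaction network from an edge list.
#' Node identifiers are opaque, case-sensitive strings; surrounding
#' whitespace is trimmed. Self-loops are dropped with a warning, and
#' duplicate rows (in either orientation) collapse to a single edge,
#' keeping the maximum weight and the maximum evidence count, so the
#' result is independent of row order.
#'
#' @param node1,node2 character vectors of interaction endpoints.
#' @param weight optional positive numeric evidence weight per row.
#' @param evidence optional non-negative integer publication count per row.
#' @return An object of class `ppi_network`: a list with elements
#'   `edges` (data.frame with columns `node1`, `node2`, and optionally
#'   `weight`, `evidence`; `node1 < node2` and rows sorted
#'   lexicographically) and `nodes` (sorted character vector).
#' @examples
#' net <- ppi_network(c("A", "B", "B"), c("B", "A", "C"))
#' n_edges(net)  # 2: the reversed duplicate collapses
#' @export
ppi_network <- function(node1, node2, weight = NULL, evidence = NULL) {
  node1 <- trimws(as.character(node1))
  node2 <- trimws(as.character(node2))
  if (length(node1) != length(node2))
    stopf("node1 and node2 must have equal length")
  if (any(node1 == "" | node2 == ""))
    stopf("empty node identifier")
  if (!is.null(weight)) {
    weight <- as.numeric(weight)
    if (any(!is.finite(weight) | weight <= 0))
      stopf("edge weights must be positive and finite")
  }
  if (!is.null(evidence)) {
    evidence <- as.integer(evidence)
    if (any(is.na(evidence) | evidence < 0))
      stopf("evidence counts must be non-negative integers")
  }

  loop <- node1 == node2
  if (any(loop)) {
    warnf("dropping %d self-loop row(s)", sum(loop))
    node1 <- node1[!loop]; node2 <- node2[!loop]
    if (!is.null(weight)) weight <- weight[!loop]
    if (!is.null(evidence)) evidence <- evidence[!loop]
  }
  if (length(node1) == 0L) stopf("network has no edges")

  a <- pmin(node1, node2)
  b <- pmax(node1, node2)
  id <- paste(a, b, sep = "\t")
  keep <- !duplicated(id)
  edges <- data.frame(node1 = a[keep], node2 = b[keep],
                      stringsAsFactors = FALSE)
  # conservative, order-independent merge of duplicate rows
  if (!is.null(weight))
    edges$weight <- as.numeric(tapply(weight, id, max)[id[keep]])
  if (!is.null(evidence))
    edges$evidence <- as.integer(tapply(evidence, id, max)[id[keep]])

  o <- order(edges$node1, edges$node2, method = "radix")
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$node1, edges$node2)),
                              method = "radix")),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges%s%s\n",
              length(x$nodes), nrow(x$edges),
              if (!is.null(x$edges$weight)) ", weighted" else "",
              if (!is.null(x$edges$evidence)) ", with evidence counts" else ""))
  invisible(x)
}

#' Network accessors
#'
#' `n_edges()` and `n_nodes()` return the edge and node counts;
#' `edge_ids()` the canonical (tab-joined, sorted-pair) edge identifiers;
#' `node_degrees()` a named integer vector of node degrees.
#'
#' @param network a `ppi_network`.
#' @return See individual descriptions.
#' @export
n_edges <- function(network) nrow(network$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_edges
#' @export
edge_ids <- function(network) edge_id(network$edges$node1, network$edges$node2)

#' @rdname n_edges
#' @export
node_degrees <- function(network) {
  tab <- table(factor(c(network$edges$node1, network$edges$node2),
                      levels = network$nodes))
  stats::setNames(as.integer(tab), names(tab))
}

# adjacency list: node -> character vector of neighbours
adjacency_list <- function(network) {
  nb <- split(c(network$edges$node2, network$edges$node1),
              factor(c(network$edges$node1, network$edges$node2),
                     levels = network$nodes))
  lapply(nb, unlist, use.names = FALSE)
}

#' Read an interaction network from a TSV or SIF edge list
#'
#' TSV rows hold two node identifiers, optionally followed by a numeric
#' weight column and/or an integer evidence-count column (roles set by
#' `weight_col` / `evidence_col`). Lines starting with `#` are comments;
#' a header line is detected when the designated weight field of the
#' first data row is non-numeric. SIF rows are
#' `node1<TAB>relation<TAB>node2`; the relation token is ignored.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @param weight_col,evidence_col optional 1-based column indices of the
#'   weight and evidence columns (TSV only).
#' @return A [ppi_network].
#' @export
read_network <- function(path, format = c("tsv", "sif"),
                         weight_col = NULL, evidence_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("empty network file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)

  if (format == "sif") {
    bad <- which(lengths(fields) != 3L)
    if (length(bad))
      stopf("malformed SIF row at line %d: expected 3 tab-separated fields",
            lineno[bad[1]])
    return(ppi_network(vapply(fields, `[`, character(1), 1L),
                       vapply(fields, `[`, character(1), 3L)))
  }

  ncol_needed <- max(2L, weight_col %||% 0L, evidence_col %||% 0L)
  bad <- which(lengths(fields) < ncol_needed)
  # header detection: a numeric-designated field of the first row (and
  # only the first) is non-numeric -> treat row 1 as header
  num_cols <- c(weight_col, evidence_col)
  if (length(num_cols) && length(fields) > 1L &&
      lengths(fields)[1] >= max(num_cols) &&
      anyNA(suppressWarnings(as.numeric(fields[[1]][num_cols])))) {
    fields <- fields[-1L]; lineno <- lineno[-1L]
    bad <- which(lengths(fields) < ncol_needed)
    if (length(fields) == 0L) stopf("no data rows in %s", path)
  }
  if (length(bad))
    stopf("malformed row at line %d: expected >= %d tab-separated fields",
          lineno[bad[1]], ncol_needed)

  node1 <- vapply(fields, `[`, character(1), 1L)
  node2 <- vapply(fields, `[`, character(1), 2L)
  weight <- evidence <- NULL
  if (!is.null(weight_col)) {
    raw <- vapply(fields, `[`, character(1), weight_col)
    weight <- suppressWarnings(as.numeric(raw))
    if (anyNA(weight))
      stopf("non-numeric weight at line %d", lineno[which(is.na(weight))[1]])
  }
  if (!is.null(evidence_col)) {
    raw <- vapply(fields, `[`, character(1), evidence_col)
    evidence <- suppressWarnings(as.integer(raw))
    if (anyNA(evidence))
      stopf("non-integer evidence count at line %d",
            lineno[which(is.na(evidence))[1]])
  }
  ppi_network(node1, node2, weight = weight, evidence = evidence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scored network as TSV
#'
#' Writes columns `node1`, `node2`, `confidence` with a header, one row
#' per edge in lexicographic order of the sorted endpoint pair.
#'
#' @param network a [ppi_network].
#' @param scores numeric vector of confidence scores named by canonical
#'   edge id (as from [edge_ids]); every edge must be scored.
#' @param path output file path.
#' @param digits decimal places written (default 6).
#' @export
write_scored_network <- function(network, scores, path, digits = 6) {
  ids <- edge_ids(network)
  missing <- setdiff(ids, names(scores))
  if (length(missing))
    stopf("missing score for edge(s): %s",
          paste(gsub("\t", "--", utils::head(missing, 5)), collapse = ", "))
  df <- data.frame(node1 = network$edges$node1,
                   node2 = network$edges$node2,
                   confidence = formatC(unname(scores[ids]),
                                        format = "f", digits = digits),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
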