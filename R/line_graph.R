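#' Line graph of an interaction network
#'
#' Builds the line graph L(G): one node per interaction, and a link
#' between two interactions iff they share a protein (exactly one, since
#' the source network is simple). Each link is labelled with the shared
#' protein. Construction iterates over each protein's incident edges and
#' emits all pairs, so the cost is O(sum of squared degrees) rather than
#' all edge pairs.
#'
#' When `use_weights = TRUE` and the network carries edge weights, a
#' link between interactions e1 and e2 is weighted by the geometric mean
#' sqrt(w(e1) * w(e2)); this symmetric combination rule is this
#' package's choice (see the methods vignette) and is off by default so
#' that unweighted and weighted inputs are clustered identically.
#'
#' @param network a [ppi_network] with at least one edge.
#' @param use_weights combine edge weights into line-graph link weights.
#' @return An object of class `line_graph`: list with `nodes` (canonical
#'   edge ids of the source network), `links` (data.frame with integer
#'   columns `from`, `to` indexing `nodes`, character `shared` protein,
#'   numeric `weight`).
#' @examples
#' tri <- ppi_network(c("A", "B", "C"), c("B", "C", "A"))
#' lg <- build_line_graph(tri)
#' nrow(lg$links)  # 3: L(K3) = K3
#' @export
build_line_graph <- function(network, use_weights = FALSE) {
  if (!inherits(network, "ppi_network")) stopf("not a ppi_network")
  m <- n_edges(network)
  if (m == 0L) stopf("network has no edges")
  ids <- edge_ids(network)

  # incidence: for each node, indices of its edges
  ends <- c(network$edges$node1, network$edges$node2)
  eidx <- rep.int(seq_len(m), 2L)
  by_node <- split(eidx, ends)

  from <- to <- integer(0)
  shared <- character(0)
  for (p in names(by_node)) {
    inc <- by_node[[p]]
    d <- length(inc)
    if (d < 2L) next
    pr <- utils::combn(sort(inc), 2L)
    from <- c(from, pr[1L, ])
    to <- c(to, pr[2L, ])
    shared <- c(shared, rep.int(p, ncol(pr)))
  }
  w <- rep.int(1.0, length(from))
  if (use_weights && !is.null(network$edges$weight) && length(from))
    w <- sqrt(network$edges$weight[from] * network$edges$weight[to])
  links <- data.frame(from = from, to = to, shared = shared, weight = w,
                      stringsAsFactors = FALSE)
  structure(list(nodes = ids, links = links), class = "line_graph")
}

#' @export
print.line_graph <- function(x, ...) {
  cat(sprintf("line_graph: %d interaction nodes, %d shared-protein links\n",
              length(x$nodes), nrow(x$links)))
  invisible(x)
}
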