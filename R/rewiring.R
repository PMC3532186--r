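#' Degree-preserving partial rewiring of a network
#'
#' Generates labelled false interactions by double-edge swaps: two
#' edges (a,b) and (c,d) are replaced by (a,d),(c,b) or (a,c),(b,d)
#' (orientation chosen at random), so every node keeps its degree while
#' two real interactions are destroyed and two false ones created. A
#' candidate swap is rejected and redrawn if it would create a
#' self-loop, a duplicate edge, reconstitute any edge of the original
#' network, touch an edge created by an earlier swap (rewired edges
#' must stay unambiguous negatives), or change the number of connected
#' components.
#'
#' The number of rewired edges follows the two-for-two bookkeeping:
#' `round(fraction * n_edges)` edges rounded to the nearest even count,
#' i.e. `round(fraction * n_edges / 2)` swaps.
#'
#' @param network a [ppi_network] with >= 4 edges.
#' @param fraction fraction of edges to rewire, in (0, 1];
#'   `fraction * n_edges` must be >= 2.
#' @param seed integer RNG seed; results are reproducible given the seed.
#' @return An object of class `rewired_instance`: `network` (the
#'   partially rewired [ppi_network]; surviving edges keep their weight
#'   and evidence, new edges get weight 1 and evidence 0),
#'   `rewired_edges` and `removed_edges` (canonical edge ids), `seed`,
#'   and `n_swaps`.
#' @export
rewire_fraction <- function(network, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  m <- n_edges(network)
  if (m < 4L) stopf("network must have >= 4 edges")
  if (fraction * m < 2) stopf("fraction * n_edges must be >= 2")
  target_swaps <- max(1L, as.integer(round(round(fraction * m) / 2)))
  res <- with_seed(seed, rewire_engine(network, target_swaps,
                                       budget = 100L * target_swaps,
                                       forbid_original = TRUE,
                                       lock_rewired = TRUE))
  if (res$n_swaps < target_swaps)
    stopf("only %d of %d requested swaps possible within the retry budget; the network is too constrained for fraction %g",
          res$n_swaps, target_swaps, fraction)
  structure(c(res, list(seed = seed)), class = "rewired_instance")
}

#' Full degree-preserving randomisation of a network
#'
#' Shuffles the whole network by `attempts_per_edge * n_edges` random
#' double-edge swap attempts (the standard configuration-style null
#' model), preserving every node's degree and the component count.
#' Unlike [rewire_fraction], edges may be swapped repeatedly and the
#' no-original-edge rule is enforced only per swap, so an original edge
#' can reappear later; exact global avoidance is impossible under full
#' randomisation. Failed attempts are skipped, not retried.
#'
#' @param network a [ppi_network] with >= 4 edges.
#' @param seed integer RNG seed.
#' @param attempts_per_edge swap attempts per edge (default 10).
#' @return A `rewired_instance` (see [rewire_fraction]); if no valid
#'   swap exists (e.g. a star network) the original network is returned
#'   with a warning.
#' @export
rewire_full <- function(network, seed, attempts_per_edge = 10) {
  m <- n_edges(network)
  if (m < 4L) stopf("network must have >= 4 edges")
  res <- with_seed(seed, rewire_engine(network, target_swaps = NA,
                                       budget = as.integer(attempts_per_edge * m),
                                       forbid_original = FALSE,
                                       lock_rewired = FALSE))
  if (res$n_swaps == 0L)
    warnf("no valid degree-preserving swap exists; returning the network unchanged")
  structure(c(res, list(seed = seed)), class = "rewired_instance")
}

# Core swap loop. `target_swaps = NA` means "spend the whole budget"
# (full randomisation); otherwise stop after that many successful swaps.
rewire_engine <- function(network, target_swaps, budget,
                          forbid_original, lock_rewired) {
  nodes <- network$nodes
  n <- length(nodes)
  e1 <- match(network$edges$node1, nodes)
  e2 <- match(network$edges$node2, nodes)
  m <- length(e1)
  orig1 <- e1; orig2 <- e2

  pair_key <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  original <- new.env(hash = TRUE, parent = emptyenv())
  for (k in pair_key(e1, e2)) assign(as.character(k), TRUE, original)
  current <- new.env(hash = TRUE, parent = emptyenv())
  for (k in pair_key(e1, e2)) assign(as.character(k), TRUE, current)

  comp0 <- n_components(cbind(e1, e2), n)
  touched <- rep.int(FALSE, m)   # edges created by a swap (slot-wise)
  swaps <- 0L
  draws <- 0L

  while (draws < budget &&
         (is.na(target_swaps) || swaps < target_swaps)) {
    draws <- draws + 1L
    cand <- sample.int(m, 2L)
    i <- cand[1L]; j <- cand[2L]
    if (lock_rewired && (touched[i] || touched[j])) next
    a <- e1[i]; b <- e2[i]; cc <- e1[j]; d <- e2[j]
    if (stats::runif(1) < 0.5) { na1 <- a; nb1 <- d; na2 <- cc; nb2 <- b }
    else                       { na1 <- a; nb1 <- cc; na2 <- b;  nb2 <- d }
    # self-loops
    if (na1 == nb1 || na2 == nb2) next
    k1 <- pair_key(na1, nb1); k2 <- pair_key(na2, nb2)
    if (k1 == k2) next
    # duplicate of an existing edge
    if (exists(as.character(k1), current) ||
        exists(as.character(k2), current)) next
    # reconstitution of a real (original) interaction
    if (forbid_original &&
        (exists(as.character(k1), original) ||
         exists(as.character(k2), original))) next
    # tentative swap; keep component count intact
    old_k1 <- pair_key(a, b); old_k2 <- pair_key(cc, d)
    e1[i] <- na1; e2[i] <- nb1; e1[j] <- na2; e2[j] <- nb2
    if (n_components(cbind(e1, e2), n) != comp0) {
      e1[i] <- a; e2[i] <- b; e1[j] <- cc; e2[j] <- d
      next
    }
    rm(list = as.character(c(old_k1, old_k2)), envir = current)
    assign(as.character(k1), TRUE, current)
    assign(as.character(k2), TRUE, current)
    touched[c(i, j)] <- TRUE
    swaps <- swaps + 1L
  }

  orig_ids <- edge_id(nodes[orig1], nodes[orig2])
  new_ids <- edge_id(nodes[e1], nodes[e2])
  rewired <- setdiff(new_ids, orig_ids)
  removed <- setdiff(orig_ids, new_ids)

  out <- ppi_network(nodes[e1], nodes[e2])
  # carry weights/evidence of surviving original edges; new edges get
  # neutral weight and zero evidence
  if (!is.null(network$edges$weight) || !is.null(network$edges$evidence)) {
    pos <- match(edge_ids(out), orig_ids)
    if (!is.null(network$edges$weight))
      out$edges$weight <- ifelse(is.na(pos), 1, network$edges$weight[pos])
    if (!is.null(network$edges$evidence))
      out$edges$evidence <- ifelse(is.na(pos), 0L,
                                   network$edges$evidence[pos])
  }
  list(network = out, rewired_edges = rewired, removed_edges = removed,
       n_swaps = swaps)
}

#' @export
print.rewired_instance <- function(x, ...) {
  cat(sprintf("rewired_instance: %d swaps, %d rewired / %d removed edges (seed %d)\n",
              x$n_swaps, length(x$rewired_edges), length(x$removed_edges),
              x$seed))
  print(x$network)
  invisible(x)
}

#' Write rewired/original edge labels as TSV
#'
#' @param instance a `rewired_instance`.
#' @param path output file path.
#' @export
write_rewired_labels <- function(instance, path) {
  ids <- edge_ids(instance$network)
  ep <- edge_id_split(ids)
  df <- data.frame(node1 = ep$node1, node2 = ep$node2,
                   label = ifelse(ids %in% instance$rewired_edges,
                                  "rewired", "original"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
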