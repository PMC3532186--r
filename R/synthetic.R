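#' Planted-module synthetic interaction network
#'
#' Samples a planted-partition (stochastic block model) network:
#' `n_modules` modules of `module_size` proteins each, with every
#' within-module pair present with probability `p_in` and every
#' cross-module pair with probability `p_out` (`p_in > p_out`, the
#' modular structure the confidence model assumes). Isolated proteins
#' are discarded. A fraction `evidence_high_fraction` of edges, chosen
#' at random, receives evidence count 3 (the conventional
#' multi-publication threshold) and the rest evidence 1, so the
#' generated network can drive benchmark positive sets directly.
#'
#' @param n_modules number of modules (>= 2).
#' @param module_size proteins per module (>= 3).
#' @param p_in within-module edge probability, in (0, 1].
#' @param p_out cross-module edge probability, in \[0, 1).
#' @param evidence_high_fraction fraction of edges given evidence 3
#'   (default 1).
#' @param seed integer RNG seed; generation is reproducible.
#' @return list with `network` (a [ppi_network] carrying evidence
#'   counts), `truth` (named integer vector: module index per node),
#'   and `within_module` (logical per edge id: both endpoints share a
#'   module - the proxy positive class for synthetic benchmarks).
#' @examples
#' g <- generate_planted_network(4, 10, p_in = 0.9, p_out = 0, seed = 1)
#' g$network
#' @export
generate_planted_network <- function(n_modules, module_size, p_in, p_out,
                                     evidence_high_fraction = 1.0, seed) {
  if (n_modules < 2L) stopf("n_modules must be >= 2")
  if (module_size < 3L) stopf("module_size must be >= 3")
  if (p_in <= 0 || p_in > 1 || p_out < 0 || p_out >= 1)
    stopf("need p_in in (0,1] and p_out in [0,1)")
  if (p_in <= p_out) stopf("p_in must exceed p_out (modular structure)")
  if (evidence_high_fraction < 0 || evidence_high_fraction > 1)
    stopf("evidence_high_fraction must be in [0,1]")

  n <- n_modules * module_size
  node <- sprintf("n%03d", seq_len(n))
  module <- rep(seq_len(n_modules), each = module_size)
  pairs <- utils::combn(n, 2L)
  same <- module[pairs[1L, ]] == module[pairs[2L, ]]

  with_seed(seed, {
    keep <- stats::runif(ncol(pairs)) < ifelse(same, p_in, p_out)
    if (sum(keep) < 4L) stopf("generated network has fewer than 4 edges; increase sizes or p_in")
    i <- pairs[1L, keep]; j <- pairs[2L, keep]
    m <- length(i)
    n_high <- round(evidence_high_fraction * m)
    evid <- rep(1L, m)
    evid[sample.int(m, n_high)] <- 3L
    net <- ppi_network(node[i], node[j], evidence = evid)
    truth <- stats::setNames(module, node)[net$nodes]
    ids <- edge_ids(net)
    ep <- edge_id_split(ids)
    within <- stats::setNames(truth[ep$node1] == truth[ep$node2], ids)
    list(network = net, truth = truth, within_module = within)
  })
}

#' Node-averaged clustering coefficient
#'
#' Watts-Strogatz convention: for each node of degree >= 2, the
#' fraction of its neighbour pairs that are themselves connected;
#' nodes of degree < 2 contribute 0 and are included in the mean.
#'
#' @param network a [ppi_network].
#' @return value in \[0, 1\].
#' @export
clustering_coefficient <- function(network) {
  adj <- adjacency_list(network)
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (id in edge_ids(network)) assign(id, TRUE, have)
  coef_one <- function(nb) {
    d <- length(nb)
    if (d < 2L) return(0)
    pr <- utils::combn(sort(nb), 2L)
    closed <- sum(vapply(seq_len(ncol(pr)), function(k)
      exists(edge_id(pr[1L, k], pr[2L, k]), have), logical(1)))
    closed / choose(d, 2)
  }
  mean(vapply(adj, coef_one, numeric(1)))
}

#' Fraction of interactions embedded in triangles
#'
#' Fraction of edges whose two endpoints share at least one common
#' neighbour; only these can be scored by the common-neighbour
#' baseline ([goldberg_roth_score]).
#'
#' @param network a [ppi_network].
#' @return value in \[0, 1\].
#' @export
fraction_links_in_triangles <- function(network) {
  adj <- adjacency_list(network)
  in_tri <- mapply(function(a, b) length(intersect(adj[[a]], adj[[b]])) > 0L,
                   network$edges$node1, network$edges$node2)
  mean(in_tri)
}
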