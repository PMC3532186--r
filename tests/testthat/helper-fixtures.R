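# Small networks built in code, shared across test files.

triangle_net <- function() ppi_network(c("A", "B", "C"), c("B", "C", "A"))

star_net <- function(k = 3) {
  leaves <- LETTERS[seq_len(k)]
  ppi_network(rep("H", k), leaves)
}

path_net <- function() ppi_network(c("A", "B", "C"), c("B", "C", "D"))

two_triangles_net <- function() {
  ppi_network(c("A", "B", "C", "D", "E", "F"),
              c("B", "C", "A", "E", "F", "D"))
}

# K4 on A-D, triangle on E-G, bridge D-E: 7 nodes, 10 edges, two modules
toy_modular_net <- function() {
  ppi_network(c("A", "A", "A", "B", "B", "C", "D", "E", "E", "F"),
              c("B", "C", "D", "C", "D", "D", "E", "F", "G", "G"))
}

# Erdos-Renyi network on n nodes (conditioned on having >= min_edges)
random_net <- function(n, p, seed, min_edges = 1L) {
  pairs <- utils::combn(n, 2L)
  nodes <- sprintf("v%02d", seq_len(n))
  for (s in seed + 0:50) {
    keep <- withr::with_seed(s, stats::runif(ncol(pairs)) < p)
    if (sum(keep) >= min_edges)
      return(ppi_network(nodes[pairs[1L, keep]], nodes[pairs[2L, keep]]))
  }
  stop("could not generate a network with enough edges")
}

# canonical form of a partition labelling for permutation-invariance
# checks: list of sorted member-id sets, sorted by first member
canonical_partition <- function(assignment) {
  cl <- lapply(split(names(assignment), assignment), sort)
  names(cl) <- NULL
  cl[order(vapply(cl, `[`, character(1), 1L))]
}
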