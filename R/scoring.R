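#' Protein-to-cluster fidelity
#'
#' The fidelity of protein p to interaction cluster c is the lower-tail
#' cumulative hypergeometric probability P(X <= L_pc) of seeing at most
#' L_pc of p's interactions in a random draw of L_c interactions out of
#' the network's L_total, where p has L_p interactions in total. It is
#' near 1 when the cluster is enriched in p's interactions (p is
#' "specific" to c), and equals 1 exactly when L_pc reaches
#' min(L_p, L_c).
#'
#' Vectorised over its arguments. Computation delegates to the stable
#' log-space hypergeometric CDF of [stats::phyper], so it is accurate at
#' interactome scale (L_total in the tens of thousands).
#'
#' @param l_pc interactions of the protein inside the cluster (>= 0).
#' @param l_p degree of the protein (>= 1).
#' @param l_c interactions in the cluster (>= 1).
#' @param l_total interactions in the network (>= 1).
#' @return Fidelity value(s) in \[0, 1\].
#' @examples
#' fidelity(2, 2, 3, 10)  # 1: all of the protein's links are in c
#' fidelity(1, 2, 3, 10)  # 14/15
#' @export
fidelity <- function(l_pc, l_p, l_c, l_total) {
  args <- unname(cbind(l_pc, l_p, l_c, l_total))  # recycles
  l_pc <- as.numeric(args[, 1]); l_p <- as.numeric(args[, 2])
  l_c <- as.numeric(args[, 3]); l_total <- as.numeric(args[, 4])
  if (any(l_pc < 0 | l_p < 1 | l_c < 1 | l_total < 1))
    stopf("invalid fidelity context: counts out of range")
  if (any(l_pc > pmin(l_p, l_c) | l_p > l_total | l_c > l_total))
    stopf("invalid fidelity context: L_pc <= min(L_p, L_c) and L_p, L_c <= L_total required")
  stats::phyper(l_pc, m = l_p, n = l_total - l_p, k = l_c)
}

#' Confidence scores for all interactions of a clustered network
#'
#' For every interaction l = (p1, p2) assigned to cluster c, the
#' confidence is the product of the two endpoint fidelities,
#' `fidelity(p1, c) * fidelity(p2, c)`, with no renormalisation. Scores
#' are high only when both proteins are specific to the cluster holding
#' the interaction. Fidelities are computed once per (protein, cluster)
#' pair.
#'
#' @param network a [ppi_network].
#' @param clustering an `interaction_clustering` whose interactions are
#'   exactly the network's edges (see [cluster_interactions]).
#' @return A list of class `confidence_result`: `scores` (numeric in
#'   \[0, 1\] named by edge id), `fidelity` (data.frame `protein`,
#'   `cluster`, `l_pc`, `l_p`, `l_c`, `fidelity`), plus the `clustering`
#'   used.
#' @export
score_network <- function(network, clustering) {
  ids <- edge_ids(network)
  assign_ids <- names(clustering$assignment)
  extra <- setdiff(assign_ids, ids)
  missing <- setdiff(ids, assign_ids)
  if (length(extra) || length(missing))
    stopf("clustering does not match network (%d missing, %d extra interaction(s)): %s",
          length(missing), length(extra),
          paste(gsub("\t", "--", utils::head(c(missing, extra), 5)),
                collapse = ", "))

  cl <- unname(clustering$assignment[ids])
  l_total <- length(ids)
  deg <- node_degrees(network)
  cl_size <- tabulate(cl)

  # links of each protein per cluster, over both endpoint roles
  prot <- c(network$edges$node1, network$edges$node2)
  cc <- c(cl, cl)
  key <- paste(prot, cc, sep = "\t")
  l_pc_tab <- table(key)

  uk <- !duplicated(key)
  fid_tab <- data.frame(protein = prot[uk], cluster = cc[uk],
                        l_pc = as.integer(l_pc_tab[key[uk]]),
                        stringsAsFactors = FALSE)
  fid_tab$l_p <- as.integer(deg[fid_tab$protein])
  fid_tab$l_c <- cl_size[fid_tab$cluster]
  # internal consistency: an interaction in c puts >= 1 link of each
  # endpoint in c
  stopifnot(all(fid_tab$l_pc >= 1L))
  fid_tab$fidelity <- fidelity(fid_tab$l_pc, fid_tab$l_p, fid_tab$l_c, l_total)

  fkey <- paste(fid_tab$protein, fid_tab$cluster, sep = "\t")
  f1 <- fid_tab$fidelity[match(paste(network$edges$node1, cl, sep = "\t"), fkey)]
  f2 <- fid_tab$fidelity[match(paste(network$edges$node2, cl, sep = "\t"), fkey)]
  scores <- stats::setNames(f1 * f2, ids)

  o <- order(fid_tab$cluster, fid_tab$protein, method = "radix")
  structure(list(scores = scores,
                 fidelity = `rownames<-`(fid_tab[o, ], NULL),
                 clustering = clustering),
            class = "confidence_result")
}

#' @export
print.confidence_result <- function(x, ...) {
  q <- stats::quantile(x$scores, c(0, .25, .5, .75, 1))
  cat(sprintf("confidence_result: %d interactions, %d cluster(s)\n",
              length(x$scores), x$clustering$n_clusters))
  cat("score quantiles:\n")
  print(signif(q, 4))
  invisible(x)
}

#' Write the per-(protein, cluster) fidelity table as TSV
#'
#' @param result a `confidence_result` from [score_network].
#' @param path output file path.
#' @export
write_fidelity_table <- function(result, path) {
  utils::write.table(result$fidelity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
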