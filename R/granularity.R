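#' One-sided Wilcoxon rank-sum P-value
#'
#' P-value of the Mann-Whitney/Wilcoxon rank-sum test under the
#' alternative that `greater_sample` is stochastically larger than
#' `lesser_sample`. The exact null distribution is used when both
#' samples have at most 20 observations and there are no ties; for
#' larger samples (or tied data) the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param greater_sample,lesser_sample non-empty numeric vectors.
#' @param exact force the exact (`TRUE`, untied data only) or
#'   approximate (`FALSE`) mode; the default `NULL` selects
#'   automatically as described above.
#' @return P-value in (0, 1].
#' @examples
#' wilcoxon_one_sided(c(10, 11, 12), c(1, 2, 3))  # 1/choose(6,3) = 0.05
#' @export
wilcoxon_one_sided <- function(greater_sample, lesser_sample, exact = NULL) {
  if (length(greater_sample) == 0L || length(lesser_sample) == 0L)
    stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(greater_sample, lesser_sample)) > 0L
  if (is.null(exact))
    exact <- !ties && length(greater_sample) <= 20L &&
      length(lesser_sample) <= 20L
  if (exact && ties) stopf("exact mode requires untied data")
  stats::wilcox.test(greater_sample, lesser_sample,
                     alternative = "greater", exact = exact,
                     correct = TRUE)$p.value
}

# round inflation values so grid membership tests are exact
round_inf <- function(x) round(x, 3)

# coarse grid {1.1, 1.2, ..., 2.0}; fine grid step 0.025 within +/- 0.1
# of the coarse optimum, clipped to stay > 1.0 by one step and <= 30
coarse_grid <- function() round_inf(seq(1.1, 2.0, by = 0.1))
fine_grid <- function(best) {
  g <- round_inf(seq(best - 0.1, best + 0.1, by = 0.025))
  g[g >= 1.025 & g <= 30]
}

# minimal P-value; ties broken to the smallest inflation (coarsest
# clustering)
select_optimal <- function(evaluations) {
  p <- evaluations$p_value
  cand <- which(p == min(p))
  evaluations$inflation[cand[which.min(evaluations$inflation[cand])]]
}

#' Inflation scan: self-tuning of clustering granularity
#'
#' Selects the Markov-clustering inflation for a network by partial
#' degree-preserving rewiring: a single rewired instance (default 3% of
#' the edges) is clustered and scored at every inflation of a coarse
#' grid (1.1 to 2.0, step 0.1), recording the one-sided Wilcoxon
#' rank-sum P-value that separates the scores of surviving original
#' links from the rewired (known-false) links; a fine scan at step
#' 0.025 within +/- 0.1 of the coarse optimum follows. The inflation
#' minimising the P-value is optimal; ties go to the smallest
#' inflation. A single rewired instance is shared by all inflations so
#' that the P-values are comparable on the same negative set.
#'
#' @param network a [ppi_network].
#' @param fraction fraction of edges to rewire (default 0.03).
#' @param seed integer RNG seed.
#' @param use_weights pass edge weights into the clustering.
#' @param params optional [mcl_params] template.
#' @return An object of class `inflation_scan`: `evaluations`
#'   (data.frame `inflation`, `p_value`, `n_clusters`, ordered by
#'   inflation), `optimal_inflation`, `rewire_fraction`, `seed`, and
#'   `instance` (the `rewired_instance` used).
#' @export
scan_inflation <- function(network, fraction = 0.03, seed,
                           use_weights = FALSE, params = NULL) {
  instance <- rewire_fraction(network, fraction, seed)
  lg <- build_line_graph(instance$network, use_weights = use_weights)
  ids <- edge_ids(instance$network)
  is_rewired <- ids %in% instance$rewired_edges

  eval_one <- function(inflation) {
    p <- if (is.null(params)) mcl_params(inflation = inflation)
    else { params$inflation <- inflation; params }
    clus <- mcl_cluster(lg, p)
    if (clus$n_clusters == 1L) {
      # every score is 1: no separation is measurable at this inflation
      return(c(p_value = 1, n_clusters = 1))
    }
    sc <- score_network(instance$network, clus)$scores
    c(p_value = wilcoxon_one_sided(unname(sc[!is_rewired]),
                                   unname(sc[is_rewired])),
      n_clusters = clus$n_clusters)
  }

  grid <- coarse_grid()
  res <- vapply(grid, eval_one, numeric(2))
  ev <- data.frame(inflation = grid, p_value = res["p_value", ],
                   n_clusters = as.integer(res["n_clusters", ]))
  best <- select_optimal(ev)
  fg <- setdiff(fine_grid(best), ev$inflation)
  if (length(fg)) {
    res2 <- vapply(fg, eval_one, numeric(2))
    ev <- rbind(ev, data.frame(inflation = fg, p_value = res2["p_value", ],
                               n_clusters = as.integer(res2["n_clusters", ])))
  }
  ev <- ev[order(ev$inflation), ]
  rownames(ev) <- NULL
  structure(list(evaluations = ev, optimal_inflation = select_optimal(ev),
                 rewire_fraction = fraction, seed = seed,
                 instance = instance),
            class = "inflation_scan")
}

#' @export
print.inflation_scan <- function(x, ...) {
  cat(sprintf("inflation_scan: %d inflations evaluated, %g%% of edges rewired (seed %d)\n",
              nrow(x$evaluations), 100 * x$rewire_fraction, x$seed))
  cat(sprintf("optimal inflation %.3f (Wilcoxon P = %.3g)\n",
              x$optimal_inflation,
              min(x$evaluations$p_value)))
  invisible(x)
}

#' Write the inflation scan report as TSV
#'
#' @param scan an `inflation_scan`.
#' @param path output file path.
#' @export
write_scan_report <- function(scan, path) {
  utils::write.table(scan$evaluations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cluster-based interaction confidence scoring
#'
#' Fits the full confidence model to a network: the clustering
#' granularity (MCL inflation) is first selected by [scan_inflation] on
#' a partially rewired copy of the network (the optimum transfers to
#' the intact network), then the original, intact network is clustered
#' at that inflation via [cluster_interactions] and every interaction
#' is scored by [score_network] as the product of its endpoint
#' fidelities. No reference sets or manual parameters are required;
#' `inflation` may be given to skip the scan.
#'
#' @param network a [ppi_network].
#' @param fraction fraction of edges rewired during granularity tuning
#'   (default 0.03).
#' @param seed integer RNG seed (used by the rewiring only; clustering
#'   and scoring are deterministic).
#' @param inflation optional fixed inflation; skips the scan.
#' @param use_weights exploit edge evidence weights in the clustering
#'   (off by default; see [build_line_graph]).
#' @param params optional [mcl_params] template.
#' @return An object of class `cappic`: `scores` (confidence per
#'   interaction, named by edge id), `fidelity` (per-(protein, cluster)
#'   table), `clustering`, `inflation`, `scan` (the `inflation_scan`,
#'   or NULL when `inflation` was given), `network`, and `call`.
#'   Methods: [print.cappic], [summary.cappic], [coef.cappic],
#'   [plot.cappic], [as.data.frame.cappic].
#' @examples
#' net <- generate_planted_network(n_modules = 3, module_size = 8,
#'                                 p_in = 0.8, p_out = 0.02, seed = 1)$network
#' fit <- cappic(net, seed = 1)
#' fit
#' head(coef(fit))
#' @export
cappic <- function(network, fraction = 0.03, seed = 1L, inflation = NULL,
                   use_weights = FALSE, params = NULL) {
  cl <- match.call()
  scan <- NULL
  if (is.null(inflation)) {
    scan <- scan_inflation(network, fraction = fraction, seed = seed,
                           use_weights = use_weights, params = params)
    inflation <- scan$optimal_inflation
  }
  clus <- cluster_interactions(network, inflation = inflation,
                               use_weights = use_weights, params = params)
  res <- score_network(network, clus)
  structure(list(scores = res$scores, fidelity = res$fidelity,
                 clustering = clus, inflation = inflation, scan = scan,
                 network = network, call = cl),
            class = "cappic")
}

#' @export
print.cappic <- function(x, ...) {
  cat("Cluster-based interaction confidence (CAPPIC)\n")
  cat(sprintf("  network: %d proteins, %d interactions\n",
              n_nodes(x$network), n_edges(x$network)))
  cat(sprintf("  inflation: %.3f%s\n", x$inflation,
              if (is.null(x$scan)) " (fixed)" else
                sprintf(" (tuned; Wilcoxon P = %.3g)",
                        min(x$scan$evaluations$p_value))))
  cat(sprintf("  clusters: %d\n", x$clustering$n_clusters))
  cat("  confidence quantiles:\n")
  print(signif(stats::quantile(x$scores, c(0, .25, .5, .75, 1)), 4))
  invisible(x)
}

#' Summary of a fitted CAPPIC model
#'
#' @param object a `cappic` fit.
#' @param ... unused.
#' @return A list of class `summary.cappic` with cluster sizes, score
#'   quantiles, and the inflation-scan table when a scan was run.
#' @export
summary.cappic <- function(object, ...) {
  structure(list(
    n_nodes = n_nodes(object$network), n_edges = n_edges(object$network),
    inflation = object$inflation,
    cluster_sizes = sort(lengths(object$clustering$clusters),
                         decreasing = TRUE),
    score_quantiles = stats::quantile(object$scores,
                                      c(0, .1, .25, .5, .75, .9, 1)),
    scan = if (!is.null(object$scan)) object$scan$evaluations),
    class = "summary.cappic")
}

#' @export
print.summary.cappic <- function(x, ...) {
  cat(sprintf("CAPPIC fit: %d proteins, %d interactions, inflation %.3f\n",
              x$n_nodes, x$n_edges, x$inflation))
  cat(sprintf("interaction clusters (%d): sizes %s\n",
              length(x$cluster_sizes),
              paste(x$cluster_sizes, collapse = " ")))
  cat("confidence quantiles:\n"); print(signif(x$score_quantiles, 4))
  if (!is.null(x$scan)) {
    cat("inflation scan:\n")
    print(x$scan, digits = 4)
  }
  invisible(x)
}

#' @rdname summary.cappic
#' @param object,... see above.
#' @export
coef.cappic <- function(object, ...) object$scores

#' Histogram of interaction confidence scores
#'
#' @param x a `cappic` fit.
#' @param ... passed to [graphics::hist].
#' @export
plot.cappic <- function(x, ...) {
  graphics::hist(x$scores, breaks = seq(0, 1, by = 0.05),
                 main = "Interaction confidence", xlab = "CAPPIC score",
                 col = "grey80", border = "white", ...)
  invisible(x)
}

#' @export
as.data.frame.cappic <- function(x, ...) {
  ids <- edge_ids(x$network)
  data.frame(node1 = x$network$edges$node1, node2 = x$network$edges$node2,
             confidence = unname(x$scores[ids]),
             cluster = unname(x$clustering$assignment[ids]),
             stringsAsFactors = FALSE)
}
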