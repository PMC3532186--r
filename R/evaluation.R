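#' Positive and negative reference sets from a rewired instance
#'
#' Positives are the surviving original edges whose evidence count
#' (number of supporting publications) reaches `min_evidence`; edges
#' destroyed by the rewiring are absent from the instance and therefore
#' excluded. Negatives are the rewired (known-false) edges. The two
#' sets are disjoint by construction.
#'
#' @param instance a `rewired_instance` whose network carries evidence
#'   counts (see [rewire_fraction]).
#' @param min_evidence minimal evidence count for the positive set
#'   (default 3).
#' @return list with character vectors `positives` and `negatives`
#'   (canonical edge ids).
#' @export
build_reference_sets <- function(instance, min_evidence = 3L) {
  net <- instance$network
  if (is.null(net$edges$evidence))
    stopf("instance network carries no evidence counts")
  ids <- edge_ids(net)
  rewired <- ids %in% instance$rewired_edges
  positives <- ids[!rewired & net$edges$evidence >= min_evidence]
  negatives <- ids[rewired]
  if (length(positives) == 0L)
    stopf("empty positive set: no surviving edge has evidence >= %d",
          min_evidence)
  if (length(negatives) == 0L) stopf("empty negative set")
  list(positives = positives, negatives = negatives)
}

# ROC curve of a score vector against labels, with tied scores drawn as
# single diagonal segments (fractional contribution; the implied AUC is
# the rank-average Mann-Whitney statistic). Returns curve vertices.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(y, grp, sum))
  fp <- unname(tapply(!y, grp, sum))
  list(fpr = c(0, cumsum(fp) / sum(!labels)),
       tpr = c(0, cumsum(tp) / sum(labels)))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Evaluate the piecewise-linear ROC curve at grid points. At a vertical
# jump (repeated fpr) the achieved (upper) tpr is taken; strictly
# between two distinct fpr vertices the segment runs from the top of
# the left vertical to the bottom of the right one, so horizontal runs
# stay horizontal and tie diagonals stay diagonal.
roc_interpolate <- function(fpr, tpr, grid) {
  i <- findInterval(grid, fpr)  # last vertex with fpr <= grid point
  at_vertex <- fpr[i] == grid
  out <- numeric(length(grid))
  out[at_vertex] <- tpr[i[at_vertex]]
  j <- which(!at_vertex)
  if (length(j)) {
    x0 <- fpr[i[j]]; y0 <- tpr[i[j]]
    x1 <- fpr[i[j] + 1L]; y1 <- tpr[i[j] + 1L]
    out[j] <- y0 + (grid[j] - x0) / (x1 - x0) * (y1 - y0)
  }
  out
}

#' Repeated, averaged ROC analysis of a confidence scorer
#'
#' Benchmarks a scorer by repeatedly (default 100 times) rewiring a
#' small fraction of the network's edges, scoring the partially rewired
#' instance, and ranking the union of the positive reference set
#' (surviving multi-publication edges) and the negative set (the
#' rewired edges) by decreasing confidence. Each run's ROC curve is
#' linearly interpolated onto a common false-positive-rate grid and
#' curves are averaged vertically; the mean AUC is the mean of the
#' per-run trapezoidal areas on that grid (and hence equals the
#' trapezoidal area under the mean curve).
#'
#' @param network a [ppi_network] carrying evidence counts.
#' @param scorer `"cappic"`, `"goldberg_roth"`, or a function
#'   `function(network, instance)` returning scores named by edge id
#'   (useful for oracle/constant baselines).
#' @param n_runs number of rewiring repetitions (default 100).
#' @param fraction fraction rewired per run (default 0.03).
#' @param min_evidence positive-set evidence threshold (default 3).
#' @param seed base RNG seed; run r uses `seed + r`.
#' @param inflation inflation at which the CAPPIC scorer clusters each
#'   instance. The default (NULL) tunes it once on the input network
#'   via [scan_inflation] with seed `seed` and reuses it across runs.
#' @param n_genes universe size for the Goldberg-Roth scorer.
#' @return An object of class `roc_result`: `fpr_grid` (101 points),
#'   `mean_tpr`, `stderr_tpr`, `mean_auc`, `auc_runs`, `n_runs`,
#'   `scorer`, `fraction`.
#' @export
roc_analysis <- function(network, scorer = "cappic", n_runs = 100L,
                         fraction = 0.03, min_evidence = 3L, seed = 1L,
                         inflation = NULL, n_genes = 6000L) {
  scorer_name <- if (is.function(scorer)) "custom" else match.arg(
    scorer, c("cappic", "goldberg_roth", "constant"))
  if (identical(scorer_name, "cappic") && is.null(inflation))
    inflation <- scan_inflation(network, fraction = fraction,
                                seed = seed)$optimal_inflation
  score_fun <- if (is.function(scorer)) scorer
  else switch(scorer_name,
    cappic = function(net, inst)
      score_network(net, cluster_interactions(net, inflation = inflation))$scores,
    goldberg_roth = function(net, inst) goldberg_roth_score(net, n_genes = n_genes),
    constant = function(net, inst)
      stats::setNames(rep(1, n_edges(net)), edge_ids(net)))

  grid <- seq(0, 1, by = 0.01)
  tpr_mat <- matrix(NA_real_, n_runs, length(grid))
  aucs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    inst <- rewire_fraction(network, fraction, seed = seed + r)
    refs <- build_reference_sets(inst, min_evidence = min_evidence)
    sc <- score_fun(inst$network, inst)
    ids <- c(refs$positives, refs$negatives)
    missing <- setdiff(ids, names(sc))
    if (length(missing)) stopf("scorer left %d edge(s) unscored", length(missing))
    pts <- roc_points(unname(sc[ids]),
                      c(rep(TRUE, length(refs$positives)),
                        rep(FALSE, length(refs$negatives))))
    tpr <- roc_interpolate(pts$fpr, pts$tpr, grid)
    tpr_mat[r, ] <- tpr
    aucs[r] <- trapz(grid, tpr)
  }
  structure(list(fpr_grid = grid,
                 mean_tpr = colMeans(tpr_mat),
                 stderr_tpr = apply(tpr_mat, 2, stats::sd) / sqrt(n_runs),
                 mean_auc = mean(aucs), auc_runs = aucs,
                 n_runs = n_runs, scorer = scorer_name,
                 fraction = fraction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: scorer %s, %d runs, %g%% rewired; mean AUC %.3f\n",
              x$scorer, x$n_runs, 100 * x$fraction, x$mean_auc))
  invisible(x)
}

#' Plot an averaged ROC curve
#'
#' Mean true-positive rate against false-positive rate with standard
#' error bands.
#'
#' @param x a `roc_result`.
#' @param ... passed to [graphics::plot].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (mean AUC %.2f, %d runs)",
                                x$scorer, x$mean_auc, x$n_runs), ...)
  graphics::lines(x$fpr_grid, pmin(1, x$mean_tpr + x$stderr_tpr), lty = 3)
  graphics::lines(x$fpr_grid, pmax(0, x$mean_tpr - x$stderr_tpr), lty = 3)
  graphics::abline(0, 1, col = "grey70")
  invisible(x)
}

#' Common-neighbour hypergeometric baseline scorer
#'
#' Classic connectivity-based confidence: for an interaction (u, v)
#' with k common neighbours, the score is -log10 of the upper-tail
#' hypergeometric P-value of observing at least k common neighbours
#' when deg(u) and deg(v) neighbours are drawn from a universe of
#' `n_genes` genes. Interactions whose endpoints share no neighbour are
#' left unscored (score 0) - the method's characteristic limitation.
#'
#' @param network a [ppi_network].
#' @param n_genes universe size (default 6000, a standard figure for
#'   the yeast genome); must be at least the node count.
#' @return numeric scores named by canonical edge id.
#' @export
goldberg_roth_score <- function(network, n_genes = 6000L) {
  if (n_genes < n_nodes(network))
    stopf("n_genes (%d) must be >= the node count (%d)",
          n_genes, n_nodes(network))
  adj <- adjacency_list(network)
  u <- network$edges$node1; v <- network$edges$node2
  k <- mapply(function(a, b) length(intersect(adj[[a]], adj[[b]])), u, v)
  deg <- node_degrees(network)
  p <- stats::phyper(k - 1L, m = deg[u], n = n_genes - deg[u], k = deg[v],
                     lower.tail = FALSE)
  score <- ifelse(k == 0L, 0, -log10(p))
  stats::setNames(as.numeric(score), edge_id(u, v))
}

#' Bin per-interaction values by increasing confidence score
#'
#' Interactions are ranked by increasing score (ties broken
#' lexicographically by edge id) and split into `n_bins` contiguous
#' bins whose sizes differ by at most one (any remainder goes to the
#' first bins); the mean of `values` is reported per bin. Used to
#' relate confidence to an external per-interaction quantity such as
#' annotation semantic similarity.
#'
#' @param scores,values numeric vectors named by the same edge ids.
#' @param n_bins number of bins (default 5).
#' @return data.frame with `bin`, `n`, `mean_value`.
#' @export
bin_scores <- function(scores, values, n_bins = 5L) {
  if (length(scores) < n_bins) stopf("fewer edges than bins")
  if (!setequal(names(scores), names(values)))
    stopf("scores and values must cover the same edges")
  values <- values[names(scores)]
  o <- order(scores, names(scores), method = "radix")
  n <- length(scores)
  base <- n %/% n_bins; extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  data.frame(bin = seq_len(n_bins), n = sizes,
             mean_value = as.numeric(tapply(values[o], bin, mean)))
}

#' Spearman rank correlation between confidence and external evidence
#'
#' Convenience wrapper with rank-average tie handling, used to relate
#' CAPPIC scores to experimental interaction weights.
#'
#' @param scores,values numeric vectors named by the same edge ids.
#' @return Spearman's rho.
#' @export
score_evidence_correlation <- function(scores, values) {
  if (!setequal(names(scores), names(values)))
    stopf("scores and values must cover the same edges")
  stats::cor(scores, values[names(scores)], method = "spearman")
}
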