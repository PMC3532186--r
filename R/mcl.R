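#' Markov clustering parameters
#'
#' Defaults mirror the canonical MCL tool: expansion 2, self-loop weight
#' 1, pruning threshold 1e-5, convergence tolerance 1e-6, at most 200
#' iterations. Inflation must exceed 1 (at inflation 1 the walk never
#' sharpens); values up to 30 are accepted, with higher values giving
#' finer granularity.
#'
#' @param inflation entrywise power applied each iteration; in (1, 30].
#' @param expansion matrix power applied each iteration (integer >= 2).
#' @param max_iterations iteration cap; hitting it returns the current
#'   clustering with a warning rather than failing.
#' @param convergence_tol stop when the largest absolute entry change
#'   between successive iterations falls to this value or below.
#' @param prune_threshold entries below this are zeroed (columns are
#'   renormalised afterwards); the per-column maximum is always kept.
#' @param self_loop_weight weight added to each diagonal entry before
#'   normalisation.
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2.0, expansion = 2L,
                       max_iterations = 200L, convergence_tol = 1e-6,
                       prune_threshold = 1e-5, self_loop_weight = 1.0) {
  if (!is.numeric(inflation) || length(inflation) != 1L || inflation <= 1.0)
    stopf("inflation must be a single value > 1.0")
  if (inflation > 30.0) stopf("inflation must be <= 30.0")
  expansion <- as.integer(expansion)
  if (expansion < 2L) stopf("expansion must be an integer >= 2")
  if (self_loop_weight <= 0) stopf("self_loop_weight must be positive")
  if (convergence_tol < 0 || prune_threshold < 0)
    stopf("tolerances must be non-negative")
  structure(list(inflation = inflation, expansion = expansion,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 prune_threshold = prune_threshold,
                 self_loop_weight = self_loop_weight),
            class = "mcl_params")
}

# Dense matrices up to this many line-graph nodes; sparse beyond.
.mcl_dense_limit <- 2000L

#' Markov clustering of a line graph
#'
#' Deterministic random-walk clustering: the column-stochastic
#' transition matrix (link weights plus a diagonal self-loop) is
#' alternately expanded (matrix power) and inflated (entrywise power
#' followed by column renormalisation), with sub-threshold entries
#' pruned, until the largest entry change falls below the tolerance.
#' Clusters are the connected components of the non-zero structure of
#' the limit matrix: every column's non-zero rows join it to its
#' attractor system.
#'
#' @param graph a [build_line_graph] result (or any object with `nodes`
#'   and a `links` data.frame of `from`/`to`/`weight`).
#' @param params an [mcl_params] object.
#' @return An `interaction_clustering`: list with `assignment` (integer
#'   cluster index named by interaction id), `clusters` (list of
#'   character vectors), `n_clusters`, `iterations`, `converged`, and
#'   `max_colsum_dev` (largest deviation of any column sum from 1 seen
#'   after any normalisation; a numerical self-check).
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  if (!inherits(params, "mcl_params")) stopf("params must be mcl_params")
  n <- length(graph$nodes)
  if (n == 0L) stopf("empty graph")
  lk <- graph$links
  sparse <- n > .mcl_dense_limit

  if (sparse) {
    M <- Matrix::sparseMatrix(
      i = c(lk$from, lk$to, seq_len(n)),
      j = c(lk$to, lk$from, seq_len(n)),
      x = c(lk$weight, lk$weight, rep.int(params$self_loop_weight, n)),
      dims = c(n, n))
  } else {
    M <- matrix(0, n, n)
    if (nrow(lk)) {
      M[cbind(lk$from, lk$to)] <- lk$weight
      M[cbind(lk$to, lk$from)] <- lk$weight
    }
    diag(M) <- diag(M) + params$self_loop_weight
  }

  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    if (sparse) M %*% Matrix::Diagonal(x = 1 / cs)
    else M * rep(1 / cs, each = n)
  }
  prune <- function(M) {
    if (sparse) {
      keep <- apply_colmax(M)
      M@x[M@x < params$prune_threshold] <- 0
      M <- Matrix::drop0(M)
      restore_colmax(M, keep)
    } else {
      cm <- apply(M, 2L, max)
      sel <- M < params$prune_threshold & M < rep(cm, each = n)
      M[sel] <- 0
      M
    }
  }

  M <- normalize(M)
  max_dev <- max(abs(Matrix::colSums(M) - 1))
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- E^params$inflation
    E <- normalize(prune(E))
    E <- normalize(E)   # renormalise after pruning exactly once more
    max_dev <- max(max_dev, abs(Matrix::colSums(E) - 1))
    delta <- max(abs(E - M))
    M <- E
    if (delta <= params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge within %d iterations (last delta above tolerance); returning current clustering",
          params$max_iterations)

  # components of the non-zero structure
  nz <- if (sparse) {
    s <- Matrix::summary(Matrix::drop0(M, tol = params$prune_threshold / 10))
    cbind(s$i, s$j)
  } else {
    which(M > params$prune_threshold / 10, arr.ind = TRUE)
  }
  comp <- components_from_pairs(nz, n)
  as_clustering(comp, graph$nodes, iterations = iter, converged = converged,
                max_colsum_dev = max_dev)
}

# component labels (1..k, relabelled by first appearance) from index pairs
components_from_pairs <- function(pairs, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  if (length(pairs))
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

as_clustering <- function(labels, ids, ...) {
  assignment <- stats::setNames(labels, ids)
  clusters <- split(ids, labels)
  names(clusters) <- NULL
  structure(c(list(assignment = assignment, clusters = clusters,
                   n_clusters = length(clusters)), list(...)),
            class = "interaction_clustering")
}

#' @export
print.interaction_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("interaction_clustering: %d interactions in %d cluster(s); sizes %s\n",
              length(x$assignment), x$n_clusters,
              paste(sort(sizes, decreasing = TRUE), collapse = " ")))
  invisible(x)
}

# sparse helpers: remember / restore each column's maximal entry so
# pruning can never empty a column
apply_colmax <- function(M) {
  n <- ncol(M)
  p <- M@p
  i <- integer(n); x <- numeric(n)
  for (j in seq_len(n)) {
    rng <- seq.int(p[j] + 1L, p[j + 1L])
    if (p[j + 1L] == p[j]) { i[j] <- NA_integer_; next }
    k <- rng[which.max(M@x[rng])]
    i[j] <- M@i[k] + 1L
    x[j] <- M@x[k]
  }
  list(i = i, x = x)
}

restore_colmax <- function(M, keep) {
  j <- which(!is.na(keep$i))
  if (!length(j)) return(M)
  cur <- M[cbind(keep$i[j], j)]
  miss <- cur == 0
  if (any(miss))
    M[cbind(keep$i[j][miss], j[miss])] <- keep$x[j][miss]
  M
}

#' Cluster the interactions of a network
#'
#' Convenience composition: build the line graph of `network` and run
#' Markov clustering on it, so that every interaction is assigned to
#' exactly one interaction cluster (proteins may span clusters).
#'
#' @param network a [ppi_network].
#' @param inflation MCL inflation (granularity) parameter.
#' @param use_weights pass edge weights into the line graph (see
#'   [build_line_graph]).
#' @param params optional [mcl_params]; its inflation is overridden by
#'   `inflation`.
#' @return An `interaction_clustering` (see [mcl_cluster]).
#' @export
cluster_interactions <- function(network, inflation = 2.0,
                                 use_weights = FALSE, params = NULL) {
  if (is.null(params)) params <- mcl_params(inflation = inflation)
  else params$inflation <- inflation
  mcl_cluster(build_line_graph(network, use_weights = use_weights), params)
}
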