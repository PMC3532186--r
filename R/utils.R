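# Internal helpers shared across the package.

#' Canonical identifier of an undirected edge
#'
#' Tab-joined, sorted endpoint pair, so that (u, v) and (v, u) map to
#' the same id. Node identifiers are whitespace-trimmed on input and
#' thus cannot contain a tab. Score maps passed to
#' [write_scored_network] and friends are named by these ids.
#'
#' @param u,v character vectors of endpoints (recycled).
#' @return character vector of edge ids.
#' @export
edge_id <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\t")
}

edge_id_split <- function(id) {
  parts <- strsplit(id, "\t", fixed = TRUE)
  list(node1 = vapply(parts, `[`, character(1), 1L),
       node2 = vapply(parts, `[`, character(1), 2L))
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Number of connected components of an undirected graph given as an
# integer edge matrix (two columns of node indices) over n nodes.
# Union-find; isolated indices count as their own components.
n_components <- function(edge_idx, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edge_idx)) {
    for (k in seq_len(nrow(edge_idx))) {
      ra <- find(edge_idx[k, 1L]); rb <- find(edge_idx[k, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
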