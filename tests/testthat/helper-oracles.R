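# Independent oracles: brute-force or enumeration-based references that
# never touch the code paths they check.

# Lower-tail hypergeometric CDF by direct summation of binomial-product
# terms. choose() on integer arguments <= ~50 is exact in double
# precision, so this is exact rational arithmetic up to the final
# division.
hyper_cdf_bruteforce <- function(l_pc, l_p, l_c, l_total) {
  k <- 0:l_pc
  sum(choose(l_p, k) * choose(l_total - l_p, l_c - k)) / choose(l_total, l_c)
}

# Upper-tail P(X >= k) for the common-neighbour statistic, same scheme.
hyper_upper_bruteforce <- function(k, K, n, N) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Exact rational lower-tail hypergeometric CDF for large L_total,
# evaluated with python's arbitrary-precision fractions. `tuples` is a
# 4-column matrix (l_pc, l_p, l_c, l_total); returns doubles.
py_hyper_cdf <- function(tuples) {
  inp <- tempfile(fileext = ".tsv")
  write.table(tuples, inp, sep = "\t", row.names = FALSE, col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in open(sys.argv[1]):",
    "    lpc, lp, lc, lt = map(int, line.split())",
    "    num = sum(comb(lp, k) * comb(lt - lp, lc - k) for k in range(lpc + 1))",
    "    print(float(Fraction(num, comb(lt, lc))))"), script)
  out <- system2("python", c(script, inp), stdout = TRUE)
  as.numeric(out)
}

# One-sided Wilcoxon rank-sum P-value (alternative: x stochastically
# greater) by exhaustive enumeration of all group assignments of the
# pooled midranks. Handles ties; permutation-exact.
wilcoxon_enum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  stat <- apply(sets, 2L, function(idx) sum(r[idx]))
  mean(stat >= obs)
}

# Line graph by brute force over all edge pairs.
line_graph_bruteforce <- function(net) {
  ids <- edge_ids(net)
  m <- length(ids)
  e <- net$edges
  links <- list()
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      shared <- intersect(c(e$node1[i], e$node2[i]),
                          c(e$node1[j], e$node2[j]))
      if (length(shared)) links[[length(links) + 1L]] <- c(i, j)
    }
  }
  list(n_nodes = m,
       links = if (length(links)) do.call(rbind, links)
               else matrix(integer(0), 0, 2))
}

# Adjusted Rand index between two labellings of the same items.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Triangle count through each node by exhaustive triple enumeration.
node_triangles_bruteforce <- function(net) {
  ids <- edge_ids(net)
  has_edge <- function(u, v) edge_id(u, v) %in% ids
  vapply(net$nodes, function(v) {
    nb <- c(net$edges$node2[net$edges$node1 == v],
            net$edges$node1[net$edges$node2 == v])
    if (length(nb) < 2) return(0L)
    pr <- utils::combn(nb, 2)
    sum(vapply(seq_len(ncol(pr)),
               function(k) has_edge(pr[1, k], pr[2, k]), logical(1)))
  }, integer(1))
}
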