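test_that("reference sets exclude destroyed edges and split cleanly", {
  g <- generate_planted_network(4, 12, p_in = 0.4, p_out = 0.02,
                                evidence_high_fraction = 1, seed = 2)
  inst <- rewire_fraction(g$network, 0.05, seed = 3)
  refs <- build_reference_sets(inst)
  ids <- edge_ids(inst$network)
  expect_setequal(refs$negatives, inst$rewired_edges)
  expect_setequal(refs$positives, setdiff(ids, inst$rewired_edges))
  expect_length(intersect(refs$positives, refs$negatives), 0)
  expect_length(intersect(refs$positives, inst$removed_edges), 0)

  # mixed evidence: only high-evidence survivors qualify
  g2 <- generate_planted_network(4, 12, p_in = 0.4, p_out = 0.02,
                                 evidence_high_fraction = 0.25, seed = 2)
  inst2 <- rewire_fraction(g2$network, 0.05, seed = 3)
  refs2 <- build_reference_sets(inst2)
  ev <- inst2$network$edges$evidence[match(refs2$positives,
                                           edge_ids(inst2$network))]
  expect_true(all(ev >= 3))

  # all evidence below threshold: ROC undefined
  g3 <- generate_planted_network(4, 12, p_in = 0.4, p_out = 0.02,
                                 evidence_high_fraction = 0, seed = 2)
  inst3 <- rewire_fraction(g3$network, 0.05, seed = 3)
  expect_error(build_reference_sets(inst3), "empty positive")
})

test_that("oracle, anti-oracle and constant scorers bracket the AUC scale", {
  g <- generate_planted_network(4, 12, p_in = 0.4, p_out = 0.02, seed = 13)
  oracle <- function(net, inst)
    stats::setNames(as.numeric(!(edge_ids(net) %in% inst$rewired_edges)),
                    edge_ids(net))
  anti <- function(net, inst)
    stats::setNames(as.numeric(edge_ids(net) %in% inst$rewired_edges),
                    edge_ids(net))
  r1 <- roc_analysis(g$network, oracle, n_runs = 3, seed = 1)
  expect_equal(r1$mean_auc, 1.0)
  r2 <- roc_analysis(g$network, anti, n_runs = 3, seed = 1)
  # the jump at fpr = 1 occupies half a grid cell under vertical
  # averaging, so the worst scorer bottoms out at 0.005 on a 101-point grid
  expect_lte(r2$mean_auc, 0.005 + 1e-12)
  r3 <- roc_analysis(g$network, "constant", n_runs = 3, seed = 1)
  expect_equal(r3$mean_auc, 0.5)
})

test_that("ROC curves are monotone and integrate to the reported AUC", {
  g <- generate_planted_network(4, 15, p_in = 0.35, p_out = 0.01, seed = 23)
  roc <- roc_analysis(g$network, "goldberg_roth", n_runs = 5, seed = 9)
  expect_true(all(diff(roc$mean_tpr) >= -1e-12))
  expect_true(all(roc$mean_tpr >= 0 & roc$mean_tpr <= 1))
  expect_true(all(roc$stderr_tpr >= 0))
  trapz <- cappic:::trapz
  expect_equal(trapz(roc$fpr_grid, roc$mean_tpr), roc$mean_auc,
               tolerance = 1e-9)
  # reproducibility
  roc2 <- roc_analysis(g$network, "goldberg_roth", n_runs = 5, seed = 9)
  expect_identical(roc$auc_runs, roc2$auc_runs)
})

test_that("common-neighbour baseline matches exact enumeration", {
  # triangle hanging off a path: the triangle edge has 1 common neighbour
  net <- ppi_network(c("A", "B", "C", "C", "D"),
                     c("B", "C", "A", "D", "E"))
  sc <- goldberg_roth_score(net, n_genes = 6000)
  p_exp <- 1 - choose(5998, 2) / choose(6000, 2)
  expect_equal(unname(sc[["A\tB"]]), -log10(p_exp), tolerance = 1e-10)
  expect_equal(unname(sc[["D\tE"]]), 0)  # no shared neighbour: unscored

  # K4: every edge sees 2 common neighbours among degrees 3, 3
  k4 <- ppi_network(c("A", "A", "A", "B", "B", "C"),
                    c("B", "C", "D", "C", "D", "D"))
  sck4 <- goldberg_roth_score(k4, n_genes = 50)
  p_exp <- hyper_upper_bruteforce(2, 3, 3, 50)
  expect_equal(unname(sck4), rep(-log10(p_exp), 6), tolerance = 1e-10)

  expect_error(goldberg_roth_score(k4, n_genes = 3), "n_genes")
})

test_that("common-neighbour P-values match brute force on random small graphs", {
  for (s in 1:12) {
    net <- random_net(8, 0.45, seed = 600 + s, min_edges = 6)
    N <- 8 + (s %% 5) * 8
    sc <- goldberg_roth_score(net, n_genes = N)
    adj <- lapply(net$nodes, function(v)
      c(net$edges$node2[net$edges$node1 == v],
        net$edges$node1[net$edges$node2 == v]))
    names(adj) <- net$nodes
    deg <- node_degrees(net)
    for (i in seq_len(n_edges(net))) {
      u <- net$edges$node1[i]; v <- net$edges$node2[i]
      k <- length(intersect(adj[[u]], adj[[v]]))
      want <- if (k == 0) 0 else
        -log10(hyper_upper_bruteforce(k, deg[[u]], deg[[v]], N))
      expect_equal(unname(sc[[edge_id(u, v)]]), unname(want),
                   tolerance = 1e-10)
    }
  }
})

test_that("score bins are contiguous, balanced, and average correctly", {
  ids <- sprintf("e%02d\tf%02d", 1:10, 1:10)
  scores <- stats::setNames(1:10, ids)
  b <- bin_scores(scores, scores, n_bins = 5)
  expect_equal(b$mean_value, c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_equal(b$n, rep(2L, 5))

  # constant values: all bin means equal
  b2 <- bin_scores(scores, stats::setNames(rep(7, 10), ids), n_bins = 5)
  expect_equal(b2$mean_value, rep(7, 5))

  # remainder goes to the first bins; sizes differ by at most one
  ids13 <- sprintf("g%02d\th%02d", 1:13, 1:13)
  b3 <- bin_scores(stats::setNames(13:1, ids13),
                   stats::setNames(rep(1, 13), ids13), n_bins = 5)
  expect_equal(b3$n, c(3L, 3L, 3L, 2L, 2L))
  expect_equal(sum(b3$n), 13L)
  expect_true(max(b3$n) - min(b3$n) <= 1)

  expect_error(bin_scores(scores[1:4], scores[1:4], n_bins = 5), "fewer")
  expect_error(bin_scores(scores, scores[-1]), "same edges")
})

test_that("confidence correlates with planted experimental weight", {
  g <- generate_planted_network(4, 18, p_in = 0.3, p_out = 0.005, seed = 81)
  inst <- rewire_fraction(g$network, 0.05, seed = 82)
  fit <- cappic(inst$network, seed = 83)
  rew <- names(fit$scores) %in% inst$rewired_edges
  weight <- withr::with_seed(84,
    ifelse(rew, 0.2, 1.0) + stats::runif(length(rew), 0, 0.05))
  names(weight) <- names(fit$scores)
  expect_gt(score_evidence_correlation(fit$scores, weight), 0)

  # binning the planted-edge indicator: low bins hold more rewired links
  ind <- stats::setNames(as.numeric(!rew), names(fit$scores))
  b <- bin_scores(fit$scores, ind, n_bins = 5)
  expect_gt(b$mean_value[5], b$mean_value[1])
})
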