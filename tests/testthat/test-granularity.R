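test_that("one-sided Wilcoxon P-values match hand-enumerated cases", {
  # identical tied samples: no separation (approximate mode; the
  # continuity correction pushes tiny samples slightly above 1/2)
  expect_lt(abs(wilcoxon_one_sided(c(3, 4, 5), c(3, 4, 5)) - 0.5), 0.15)
  # complete separation of 3 vs 3: p = 1/C(6,3)
  expect_equal(wilcoxon_one_sided(c(10, 11, 12), c(1, 2, 3)), 0.05,
               tolerance = 1e-12)
  # complete separation the wrong way round
  expect_equal(wilcoxon_one_sided(c(1, 2, 3), c(10, 11, 12)), 1.0,
               tolerance = 1e-12)
  expect_error(wilcoxon_one_sided(numeric(0), 1), "non-empty")
})

test_that("exact P-values agree with rank-permutation enumeration", {
  for (s in 1:20) {
    sizes <- withr::with_seed(s, sample(2:7, 2))
    x <- withr::with_seed(s * 2, sample(100, sizes[1]))
    y <- withr::with_seed(s * 3, sample(200, sizes[2]) + 0.5)
    expect_equal(wilcoxon_one_sided(x, y), wilcoxon_enum(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the scan grids follow the coarse-then-fine protocol", {
  expect_equal(cappic:::coarse_grid(), seq(1.1, 2.0, by = 0.1))
  fg <- cappic:::fine_grid(1.5)
  expect_equal(fg, seq(1.4, 1.6, by = 0.025))
  expect_lte(length(setdiff(fg, cappic:::coarse_grid())), 8L)
  # clipped: inflation must stay above 1.0 by one fine step
  expect_true(all(cappic:::fine_grid(1.1) >= 1.025))
})

test_that("P-value ties break to the smallest inflation", {
  ev <- data.frame(inflation = c(1.3, 1.1, 1.2), p_value = c(0.2, 0.5, 0.2))
  expect_equal(cappic:::select_optimal(ev), 1.2)
})

test_that("scan on a planted-module network finds a discriminating granularity", {
  g <- generate_planted_network(4, 20, p_in = 0.25, p_out = 0.005, seed = 21)
  scan <- scan_inflation(g$network, fraction = 0.03, seed = 31)
  ev <- scan$evaluations
  expect_true(all(ev$inflation > 1.0 & ev$inflation <= 30))
  expect_true(all(cappic:::coarse_grid() %in% ev$inflation))
  expect_lte(nrow(ev), 18L)  # 10 coarse + at most 8 fine
  expect_gte(scan$optimal_inflation, 1.1)
  expect_lte(scan$optimal_inflation, 2.1)
  expect_lt(min(ev$p_value), 0.05)
  expect_equal(scan$optimal_inflation, cappic:::select_optimal(ev))

  # reproducible given (network, fraction, seed)
  scan2 <- scan_inflation(g$network, fraction = 0.03, seed = 31)
  expect_identical(scan$evaluations, scan2$evaluations)
})

test_that("cappic scores the intact network at the tuned inflation", {
  g <- generate_planted_network(4, 16, p_in = 0.3, p_out = 0.01, seed = 6)
  fit <- cappic(g$network, seed = 17)
  expect_s3_class(fit, "cappic")
  expect_equal(fit$inflation, fit$scan$optimal_inflation)
  expect_setequal(names(fit$scores), edge_ids(g$network))
  # the scan's instance is rewired, the fit's network is the original
  expect_identical(fit$network$edges[, c("node1", "node2")],
                   g$network$edges[, c("node1", "node2")])

  w <- g$within_module[edge_ids(g$network)]
  expect_gt(mean(fit$scores[w]), mean(fit$scores[!w]))
})

test_that("a fixed inflation skips the scan", {
  net <- two_triangles_net()
  fit <- cappic(net, inflation = 1.4)
  expect_null(fit$scan)
  expect_equal(fit$inflation, 1.4)
  expect_equal(unname(fit$scores), rep(1, 6))
})

test_that("cappic separates planted from pre-rewired false interactions", {
  g <- generate_planted_network(4, 20, p_in = 0.3, p_out = 0.005, seed = 51)
  inst <- rewire_fraction(g$network, 0.03, seed = 52)
  fit <- cappic(inst$network, seed = 53)
  rew <- names(fit$scores) %in% inst$rewired_edges
  expect_gt(mean(fit$scores[!rew]), mean(fit$scores[rew]))
})

test_that("intact and partially rewired clusterings agree above chance on shared edges", {
  g <- generate_planted_network(4, 16, p_in = 0.35, p_out = 0.01, seed = 61)
  inst <- rewire_fraction(g$network, 0.03, seed = 62)
  inf <- 1.6
  cl_int <- cluster_interactions(g$network, inflation = inf)
  cl_rew <- cluster_interactions(inst$network, inflation = inf)
  shared <- intersect(names(cl_int$assignment), names(cl_rew$assignment))
  ari <- adjusted_rand_index(cl_int$assignment[shared],
                             cl_rew$assignment[shared])
  expect_gt(ari, 0.5)  # far above the ~0 expectation of a random partition
})

test_that("S3 methods of the fit expose scores and diagnostics", {
  g <- generate_planted_network(3, 10, p_in = 0.5, p_out = 0.02, seed = 71)
  fit <- cappic(g$network, inflation = 1.5)
  expect_identical(coef(fit), fit$scores)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), n_edges(g$network))
  expect_true(all(c("node1", "node2", "confidence", "cluster") %in% names(df)))
  s <- summary(fit)
  expect_s3_class(s, "summary.cappic")
  expect_equal(sum(s$cluster_sizes), n_edges(g$network))
  expect_output(print(fit), "inflation")
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
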