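test_that("pooled t test matches frozen reference values and t.test", {
  # {1,2,3} vs {7,8,9}: t = -7.348, df = 4, two-sided p ~ 0.00183
  r <- pooled_t_test(3, 2, 2, 3, 8, 2)
  expect_equal(r$statistic, -6 / sqrt((2 / 3)), tolerance = 1e-12)
  expect_equal(r$pvalue, 0.001826261, tolerance = 1e-6)

  # identical samples
  expect_equal(pooled_t_test(5, 1, 3, 5, 1, 4)$pvalue, 1)

  # small-sample rule: either n < 2 reports p = 1
  r1 <- pooled_t_test(1, 0, 0, 10, 5, 3)
  expect_equal(r1$pvalue, 1)
  expect_true(r1$degenerate)

  # zero pooled variance: separation p = 0, equality p = 1
  expect_equal(pooled_t_test(3, 0, 0, 3, 1, 0)$pvalue, 0)
  expect_equal(pooled_t_test(3, 1, 0, 3, 1, 0)$pvalue, 1)
  expect_equal(pooled_t_test(3, 0, 0, 3, 1, 0, "greater")$pvalue, 1)
  expect_equal(pooled_t_test(3, 0, 0, 3, 1, 0, "less")$pvalue, 0)

  # random agreement with stats::t.test(var.equal = TRUE)
  set.seed(201)
  for (i in 1:25) {
    x <- rnorm(pick(2:8)); y <- rnorm(pick(2:8), mean = pick(0:2))
    alt <- pick(c("two_sided", "greater", "less"))
    mine <- pooled_t_test(length(x), mean(x), sum((x - mean(x))^2),
                          length(y), mean(y), sum((y - mean(y))^2), alt)
    ref <- t.test(x, y, var.equal = TRUE,
                  alternative = sub("_sided", ".sided", alt))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$pvalue, ref$p.value, tolerance = 1e-10)
  }
})

test_that("proportion z test matches the pooled formula", {
  expect_equal(prop_z_test(4, 10, 8, 20)$pvalue, 1)      # equal proportions
  r <- prop_z_test(8, 10, 2, 10)
  expect_equal(r$statistic, 0.6 / sqrt(0.25 * 0.2), tolerance = 1e-12)
  expect_equal(r$pvalue, 0.007290358, tolerance = 1e-6)
  expect_equal(prop_z_test(0, 10, 0, 10)$pvalue, 1)      # pooled p = 0
  expect_equal(prop_z_test(10, 10, 10, 10)$pvalue, 1)    # pooled p = 1
  expect_true(prop_z_test(1, 1, 3, 10)$degenerate)
  # two-sided = 2 x smaller one-sided
  g <- prop_z_test(8, 10, 2, 10, "greater")$pvalue
  l <- prop_z_test(8, 10, 2, 10, "less")$pvalue
  expect_equal(min(g, l) * 2, prop_z_test(8, 10, 2, 10)$pvalue,
               tolerance = 1e-12)
})

test_that("Fisher exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_test(5, 5, 0, 5)$pvalue, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_test(5, 5, 0, 5, "greater")$pvalue, 1 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_test(1, 2, 1, 2)$pvalue, 1)
  set.seed(202)
  for (i in 1:30) {
    n1 <- pick(2:10); n2 <- pick(2:10)
    k1 <- pick(0:n1); k2 <- pick(0:n2)
    alt <- pick(c("two_sided", "greater", "less"))
    mine <- fisher_exact_test(k1, n1, k2, n2, alt)$pvalue
    ref <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE),
                       alternative = sub("_sided", ".sided", alt))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
    # two-sided >= each one-sided
    expect_gte(fisher_exact_test(k1, n1, k2, n2)$pvalue + 1e-12,
               min(fisher_exact_test(k1, n1, k2, n2, "greater")$pvalue,
                   fisher_exact_test(k1, n1, k2, n2, "less")$pvalue))
  }
})

test_that("binary test selection follows the any-cell-below-6 rule", {
  expect_identical(select_binary_test(5, 20, 10, 20), "fisher_exact")
  expect_identical(select_binary_test(10, 20, 8, 20), "proportion_z")
  expect_identical(select_binary_test(0, 20, 10, 20), "fisher_exact")
  expect_identical(select_binary_test(6, 12, 6, 12), "proportion_z")
})

test_that("junction feasibility uses p <= alpha and is monotone in alpha", {
  tc <- time_course(rep(1:6, each = 3),
                    c(1, 2, 3, 2, 3, 1, 3, 1, 2, 7, 8, 9, 8, 9, 7, 9, 7, 8))
  j <- junction_feasible(tc, c(1, 3), c(4, 6), 0.05)
  expect_true(j$feasible)
  # alpha = 0 never feasible for continuous data
  expect_false(junction_feasible(tc, c(1, 3), c(4, 6), 0)$feasible)
  expect_error(junction_feasible(tc, c(1, 2), c(4, 6), 0.05), "not adjacent")
  # single-observation block: degenerate p = 1, infeasible below alpha = 1
  tc1 <- time_course(1:5, c(0, 0, 0, 10, 10))
  expect_false(junction_feasible(tc1, c(1, 1), c(2, 5), 0.5)$feasible)
  expect_true(junction_feasible(tc1, c(1, 1), c(2, 5), 1)$feasible)
  # monotonicity over random junctions
  set.seed(203)
  for (i in 1:20) {
    tcr <- random_tc(n = pick(3:7), m_range = 1:4)
    s <- pick(1:(tcr$n - 1))
    p <- junction_pvalue(tcr, 1, s, tcr$n)
    grid <- sort(runif(5))
    f <- p <= grid
    expect_true(all(diff(f) >= 0))  # feasible at alpha stays feasible above
  }
})

test_that("R and compiled junction p-values agree across modes and tails", {
  set.seed(204)
  for (i in 1:60) {
    mode <- pick(c("continuous", "binary"))
    tc <- random_tc(n = pick(3:8), m_range = 1:5, mode = mode)
    alt <- pick(c("two_sided", "greater", "less"))
    sp <- test_spec(alternative = alt)
    cd <- adpart:::.spec_codes(tc, sp)
    s <- pick(1:(tc$n - 1)); a <- pick(1:s); b <- pick((s + 1):tc$n)
    expect_equal(junction_pvalue(tc, a, s, b, sp),
                 adpart:::junction_p_cpp(tc$cm, tc$cs, tc$css, a, s, b,
                                         cd$binary, cd$alt, cd$fam),
                 tolerance = 1e-12)
  }
})
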