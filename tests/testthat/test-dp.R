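test_that("limit alphas and the two-level example reproduce the known fits", {
  tc <- two_level_tc()
  f <- fit_dp(tc, 0.05)
  expect_identical(f$ends, c(2L, 4L))
  expect_equal(f$block_estimates, c(1, 11))
  expect_equal(f$objective, 8)
  expect_equal(f$change_points, 2)

  expect_identical(fit_dp(tc, 0)$ends, 4L)          # no partition at alpha 0
  expect_identical(fit_dp(tc, 1)$ends, 1:4)         # all singletons at alpha 1

  # binary mode limits
  tb <- time_course(rep(1:4, each = 8),
                    rep(c(0, 1), c(16, 16)), mode = "binary")
  expect_identical(fit_dp(tb, 0)$ends, 4L)
  expect_identical(fit_dp(tb, 0.05)$ends, c(2L, 4L))
})

test_that("triplet sets respect size, ordering and backtracking contracts", {
  set.seed(301)
  tc <- random_tc(n = 8, m_range = 2:4)
  fit <- fit_dp(tc, 0.2, keep_sets = TRUE)
  sets <- attr(fit, "triplet_sets")
  expect_length(sets, tc$n)
  for (t in seq_along(sets)) {
    st <- sets[[t]]
    expect_lte(nrow(st), t)                       # |S_t| <= t
    expect_true(all(diff(st$score) >= 0))         # sorted by score
    expect_true(all(st$link < t))
    expect_true(all(st$score >= 0))
    expect_identical(anyDuplicated(st$link), 0L)  # one triplet per link
  }
  # R-side backtracking reproduces the compiled partition
  expect_identical(backtrack_triplets(sets), fit$ends)
  # the first element of S_n carries the reported objective, and the
  # partition's recomputed objective matches it
  expect_equal(sets[[tc$n]]$score[1], fit$objective, tolerance = 1e-10)
  expect_equal(partition_objective(tc, fit$ends), fit$objective,
               tolerance = 1e-10)
  # chain via (link 2 at t=4) <- (link 0 at t=2)
  toy <- list(data.frame(link = 0L, index = 0L, score = 0),
              data.frame(link = 0L, index = 0L, score = 1),
              data.frame(link = 0L, index = 0L, score = 9),
              data.frame(link = 2L, index = 0L, score = 2))
  expect_identical(backtrack_triplets(toy), c(2L, 4L))
})

test_that("every junction of a DP fit is significant at alpha", {
  set.seed(302)
  for (i in 1:15) {
    mode <- pick(c("continuous", "binary"))
    tc <- random_tc(n = pick(4:9), m_range = 1:5, mode = mode)
    alpha <- pick(c(0.01, 0.05, 0.2, 0.5))
    fit <- fit_dp(tc, alpha)
    expect_true(fit$feasible)
    if (length(fit$junction_pvalues))
      expect_true(all(fit$junction_pvalues <= alpha))
  }
})

test_that("DP objective is non-increasing in alpha", {
  set.seed(303)
  for (i in 1:8) {
    tc <- random_tc(n = pick(5:9), m_range = 1:4)
    objs <- vapply(c(0, 0.001, 0.01, 0.05, 0.2, 0.5, 1),
                   function(a) fit_dp(tc, a)$objective, numeric(1))
    expect_true(all(diff(objs) <= 1e-9))
  }
})

test_that("exhaustive oracle enumerates compositions and honours alpha = 0", {
  tc <- time_course(1:3, c(1, 5, 9))
  expect_identical(exhaustive_oracle(tc, 0)$ends, 3L)
  expect_error(exhaustive_oracle(random_tc(n = 21), 0.05), "n <= 20")
})

test_that("DP equals the exhaustive oracle on random small instances", {
  # a quick version of acceptance criterion 1 (the full 200-instance run
  # lives in test-acceptance.R)
  set.seed(304)
  for (i in 1:40) {
    mode <- pick(c("continuous", "binary"))
    tc <- random_tc(n = pick(3:8), m_range = 1:5, mode = mode)
    alpha <- pick(c(default_alpha_grid(), 1))
    sp <- test_spec(alternative = pick(c("two_sided", "greater", "less")))
    fd <- fit_dp(tc, alpha, sp)
    fo <- exhaustive_oracle(tc, alpha, sp)
    expect_equal(fd$objective, fo$objective,
                 tolerance = 1e-10, ignore_attr = TRUE)
    if (attr(fo, "n_optima") == 1L) expect_same_partition(fd, fo)
  }
})

test_that("one-sided DP fits are monotone (reduced isotonic regression)", {
  set.seed(305)
  tc <- random_tc(n = 8, m_range = 3:5)
  up <- fit_dp(tc, 0.3, test_spec(alternative = "greater"))
  expect_true(all(diff(up$block_estimates) >= 0))
  dn <- fit_dp(tc, 0.3, test_spec(alternative = "less"))
  expect_true(all(diff(dn$block_estimates) <= 0))
})
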