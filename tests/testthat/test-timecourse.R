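test_that("construction sorts, groups and validates long-format input", {
  tc <- time_course(c(2, 1, 2), c(5, 3, 7))
  expect_identical(tc$times, c(1, 2))
  expect_identical(tc$obs, list(3, c(5, 7)))
  expect_identical(tc$m, c(1L, 2L))
  expect_identical(tc$N, 3L)

  tb <- time_course(c(1, 1), c(0, 1), mode = "binary")
  expect_identical(tb$times, 1)
  expect_identical(tb$obs, list(c(0, 1)))

  expect_error(time_course(numeric(0), numeric(0)), "no observations")
  expect_error(time_course(c(1, 2), c(0, 2), mode = "binary"),
               "non-binary response value 2 at row 2")
})

test_that("prefix stats invariants hold on random data", {
  set.seed(101)
  for (i in 1:20) {
    tc <- random_tc(n = pick(2:9), m_range = 1:5)
    expect_equal(tc$cm[tc$n + 1], tc$N)
    # entry i = entry i-1 + point-i contribution
    expect_equal(diff(tc$cm), as.numeric(tc$m))
    expect_equal(diff(tc$cs), vapply(tc$obs, sum, numeric(1)))
  }
})

test_that("block_stats matches direct two-pass summation", {
  tc <- time_course(c(1, 1, 2, 2), c(1, 2, 3, 4))
  bs <- block_stats(tc, 1, 2)
  expect_equal(bs$count, 4)
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$sse, 5)
  expect_equal(block_stats(tc, 1, 1)$sse, 0.5)

  set.seed(102)
  for (i in 1:30) {
    tc <- random_tc(n = pick(2:8), m_range = 1:5)
    a <- pick(seq_len(tc$n)); b <- pick(a:tc$n)
    y <- unlist(tc$obs[a:b])
    bs <- block_stats(tc, a, b)
    expect_equal(bs$sse, sum((y - mean(y))^2), tolerance = 1e-9)
    expect_gte(bs$sse, 0)
  }
  # single observation
  tc1 <- time_course(1, 3)
  expect_equal(block_stats(tc1, 1, 1)$sse, 0)
})

test_that("binomial negative log-likelihood follows the 0 log 0 convention", {
  tc <- time_course(rep(1, 10), c(rep(1, 3), rep(0, 7)), mode = "binary")
  expect_equal(block_negloglik(tc, 1, 1),
               -(3 * log(0.3) + 7 * log(0.7)), tolerance = 1e-10)
  tc0 <- time_course(rep(1, 5), rep(0, 5), mode = "binary")
  expect_equal(block_negloglik(tc0, 1, 1), 0)
  tch <- time_course(rep(1, 10), rep(c(0, 1), 5), mode = "binary")
  expect_equal(block_negloglik(tch, 1, 1), 10 * log(2), tolerance = 1e-12)
  expect_error(block_negloglik(time_course(1, 1), 1, 1),
               "binary objective on continuous data")
})

test_that("partition objective is additive and refinement-monotone", {
  set.seed(103)
  for (mode in c("continuous", "binary")) {
    for (i in 1:15) {
      tc <- random_tc(n = pick(3:7), m_range = 1:4, mode = mode)
      n <- tc$n
      # additivity: total equals sum of block objectives for a random partition
      cuts <- sort(sample(seq_len(n - 1), pick(0:(n - 1))))
      ends <- c(cuts, n)
      starts <- c(1L, ends[-length(ends)] + 1L)
      direct <- sum(vapply(seq_along(ends), function(k)
        if (mode == "binary") block_negloglik(tc, starts[k], ends[k])
        else block_stats(tc, starts[k], ends[k])$sse, numeric(1)))
      expect_equal(partition_objective(tc, ends), direct, tolerance = 1e-12)
      # refinement: adding one more cut never increases the objective
      free <- setdiff(seq_len(n - 1), cuts)
      if (length(free)) {
        finer <- sort(c(ends, pick(free)))
        expect_lte(partition_objective(tc, finer),
                   partition_objective(tc, ends) + 1e-9)
      }
    }
  }
  tc <- two_level_tc()
  expect_equal(partition_objective(tc, 4L), block_stats(tc, 1, 4)$sse)
  expect_equal(partition_objective(tc, 1:4), 8)  # all-singleton: 4 x SSE 2
  expect_error(partition_objective(tc, c(3L, 2L, 4L)), "strictly increasing")
})

test_that("variance estimator is SSE / N", {
  tc <- random_tc(n = 4, m_range = 3)
  expect_equal(estimate_variance(tc, 8), 8 / tc$N)
  expect_equal(estimate_variance(tc, 0), 0)
  tb <- random_tc(n = 3, m_range = 2, mode = "binary")
  expect_error(estimate_variance(tb, 1), "continuous mode only")
})

test_that("fitted pointwise estimates reconstruct block estimates exactly", {
  set.seed(104)
  tc <- random_tc(n = 8, m_range = 2:4)
  fit <- fit_dp(tc, 0.2)
  sizes <- fit$blocks$end - fit$blocks$start + 1L
  expect_identical(fit$pointwise_estimates,
                   rep.int(fit$block_estimates, sizes))
  expect_equal(fit$sigma2_hat, fit$objective / tc$N)
})
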