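# Shared generators for the suite.  All randomness is locally seeded by the
# calling test.

# sample one element of x (safe for length-1 vectors)
pick <- function(x) x[sample.int(length(x), 1L)]

# random replicated time course
random_tc <- function(n = 6, m_range = 1:4, mode = "continuous",
                      prob = 0.5) {
  m <- sample(m_range, n, replace = TRUE)
  y <- if (mode == "binary") rbinom(sum(m), 1, prob) else rnorm(sum(m))
  time_course(rep(seq_len(n), m), y, mode = mode)
}

# the two-level n=4, m=3 example course: means 1 and 11, total SSE 8 under
# the {1-2},{3-4} partition; an exact-tie instance for finer refinements
two_level_tc <- function() {
  time_course(rep(1:4, each = 3),
              c(0, 1, 2, 1, 2, 0, 10, 11, 12, 11, 12, 10))
}

expect_same_partition <- function(fit_a, fit_b) {
  expect_identical(fit_a$ends, fit_b$ends)
}
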