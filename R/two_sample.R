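#' Two-sample test configuration
#'
#' The significance requirement between adjacent blocks is defined by a
#' two-sample test.  Continuous responses use the pooled-variance Student t
#' test; binary responses use the two-sample z test for proportions, or
#' Fisher's exact test when any cell of the 2x2 table is small (the
#' `auto_binary` rule: any observed cell below 6 switches to Fisher).
#'
#' One-sided alternatives turn the fit into a reduced isotonic regression:
#' `"greater"` requires each right-hand block to exceed its left neighbour
#' (monotone increasing fit), `"less"` the reverse.
#'
#' @param family `"auto"` (t test in continuous mode, cell-count rule in
#'   binary mode), `"student_t"`, `"proportion_z"`, `"fisher_exact"` or
#'   `"auto_binary"`.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (right block
#'   relative to left block).
#' @export
test_spec <- function(family = c("auto", "student_t", "proportion_z",
                                 "fisher_exact", "auto_binary"),
                      alternative = c("two_sided", "greater", "less")) {
  structure(list(family = match.arg(family),
                 alternative = match.arg(alternative)),
            class = "test_spec")
}

test_result <- function(statistic, pvalue, family, degenerate = FALSE) {
  list(statistic = statistic, pvalue = pvalue,
       family_used = family, degenerate = degenerate)
}

# map "sample-1 vs sample-2" alternative onto one-sided tail probabilities
.alt_p <- function(stat, alternative, pfun) {
  switch(alternative,
         two_sided = min(2 * pfun(-abs(stat)), 1),
         greater   = pfun(-stat),   # H1: mean1 > mean2  <=>  large stat
         less      = pfun(stat))
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Works from counts, means and within-sample sums of squared deviations, so
#' adjacent blocks can be compared straight from prefix statistics.  The
#' small-sample rule applies: with fewer than two observations in either
#' sample the reported p-value is 1 (no comparison is attempted).  With zero
#' pooled variance the p-value is 1 for equal means, otherwise 0 (perfect
#' separation; direction respected for one-sided alternatives).
#'
#' @param n1,n2 sample sizes.
#' @param mean1,mean2 sample means.
#' @param ss1,ss2 within-sample sums of squared deviations.
#' @param alternative `"two_sided"`, `"greater"` (mean1 > mean2) or `"less"`.
#' @return list with `statistic`, `pvalue`, `family_used`, `degenerate`.
#' @export
pooled_t_test <- function(n1, mean1, ss1, n2, mean2, ss2,
                          alternative = "two_sided") {
  stopifnot(ss1 >= 0, ss2 >= 0)
  if (n1 < 2 || n2 < 2)
    return(test_result(NA_real_, 1, "student_t", degenerate = TRUE))
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  if (s2 <= 0) {
    if (mean1 == mean2) return(test_result(0, 1, "student_t"))
    p <- switch(alternative,
                two_sided = 0,
                greater   = if (mean1 > mean2) 0 else 1,
                less      = if (mean1 < mean2) 0 else 1)
    return(test_result(sign(mean1 - mean2) * Inf, p, "student_t"))
  }
  tstat <- (mean1 - mean2) / sqrt(s2 * (1 / n1 + 1 / n2))
  p <- .alt_p(tstat, alternative, function(q) stats::pt(q, df))
  test_result(tstat, p, "student_t")
}

#' Two-sample z test for proportions
#'
#' Pooled-proportion z test.  If the pooled proportion is 0 or 1 no evidence
#' of a difference is possible and the p-value is 1; the small-sample rule
#' (either sample below 2) also yields p = 1.
#'
#' @param k1,k2 success counts.
#' @param n1,n2 sample sizes.
#' @inheritParams pooled_t_test
#' @export
prop_z_test <- function(k1, n1, k2, n2, alternative = "two_sided") {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 >= 1, n2 >= 1)
  if (n1 < 2 || n2 < 2)
    return(test_result(NA_real_, 1, "proportion_z", degenerate = TRUE))
  pbar <- (k1 + k2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1)
    return(test_result(0, 1, "proportion_z"))
  z <- (k1 / n1 - k2 / n2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  p <- .alt_p(z, alternative, stats::pnorm)
  test_result(z, p, "proportion_z")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test of equal proportions between two samples.  The
#' two-sided p-value follows the probability-mass convention: the sum of the
#' probabilities of all tables no more probable than the observed one (the
#' same convention as [stats::fisher.test()], including its 1e-7 relative
#' tolerance on "no more probable").
#'
#' @inheritParams prop_z_test
#' @export
fisher_exact_test <- function(k1, n1, k2, n2, alternative = "two_sided") {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 >= 1, n2 >= 1)
  K <- k1 + k2; Ntot <- n1 + n2
  lo <- max(0, K - n2); hi <- min(K, n1)
  p <- switch(alternative,
    greater = stats::phyper(k1 - 1, K, Ntot - K, n1, lower.tail = FALSE),
    less    = stats::phyper(k1, K, Ntot - K, n1),
    two_sided = {
      d <- stats::dhyper(lo:hi, K, Ntot - K, n1)
      dobs <- stats::dhyper(k1, K, Ntot - K, n1)
      sum(d[d <= dobs * (1 + 1e-7)])
    })
  test_result(NA_real_, min(p, 1), "fisher_exact")
}

#' Choose the binary-mode two-sample test from the 2x2 cell counts
#'
#' Fisher's exact test when any observed cell of the contingency table
#' (`k1`, `n1 - k1`, `k2`, `n2 - k2`) is below 6, otherwise the proportion
#' z test.
#'
#' @inheritParams prop_z_test
#' @return `"fisher_exact"` or `"proportion_z"`.
#' @export
select_binary_test <- function(k1, n1, k2, n2) {
  if (min(k1, n1 - k1, k2, n2 - k2) < 6) "fisher_exact" else "proportion_z"
}

# resolve a spec's family for the course's mode
resolve_family <- function(spec, mode) {
  fam <- spec$family
  if (fam == "auto") fam <- if (mode == "binary") "auto_binary" else "student_t"
  if (mode == "continuous" && fam != "student_t")
    stop("continuous mode permits only the student_t family", call. = FALSE)
  if (mode == "binary" && fam == "student_t")
    stop("binary mode requires a proportion test family", call. = FALSE)
  fam
}

# The user-facing alternative is right-block vs left-block ("greater" =
# monotone increasing).  Tests take (sample1, sample2) = (left, right), so
# one-sided alternatives flip.
.junction_alt <- function(alternative) {
  switch(alternative, two_sided = "two_sided", greater = "less",
         less = "greater")
}

#' Two-sample p-value between two adjacent blocks
#'
#' Compares all observations in time points `a..s` (left block) with all in
#' `s+1..b` (right block), using the test family implied by `spec` and the
#' course's mode.  Vectorised over `a`, `s`, `b`.
#'
#' @param tc a [time_course()].
#' @param a,s,b time-point indices: left block `a..s`, right block `s+1..b`.
#' @param spec a [test_spec()].
#' @export
junction_pvalue <- function(tc, a, s, b, spec = test_spec()) {
  fam <- resolve_family(spec, tc$mode)
  alt <- .junction_alt(spec$alternative)
  n1v <- tc$cm[s + 1] - tc$cm[a];      n2v <- tc$cm[b + 1] - tc$cm[s + 1]
  s1v <- tc$cs[s + 1] - tc$cs[a];      s2v <- tc$cs[b + 1] - tc$cs[s + 1]
  if (tc$mode == "continuous") {
    ss1v <- pmax(tc$css[s + 1] - tc$css[a] - s1v^2 / n1v, 0)
    ss2v <- pmax(tc$css[b + 1] - tc$css[s + 1] - s2v^2 / n2v, 0)
    m1 <- s1v / n1v; m2 <- s2v / n2v
    df <- pmax(n1v + n2v - 2, 1)  # df < 1 entries are overwritten below
    sp2 <- (ss1v + ss2v) / df
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1v + 1 / n2v))
    p <- switch(alt,
                two_sided = pmin(2 * stats::pt(-abs(tt), df), 1),
                greater   = stats::pt(-tt, df),
                less      = stats::pt(tt, df))
    zv <- sp2 <= 0                       # zero pooled variance
    if (any(zv, na.rm = TRUE)) {
      eq <- m1 == m2
      p[zv & eq] <- 1
      sep <- zv & !eq
      p[sep] <- switch(alt,
                       two_sided = 0,
                       greater   = ifelse(m1[sep] > m2[sep], 0, 1),
                       less      = ifelse(m1[sep] < m2[sep], 0, 1))
    }
    p[n1v < 2 | n2v < 2] <- 1            # small-sample rule
    p
  } else {
    vapply(seq_along(n1v), function(i) {
      k1 <- s1v[i]; n1 <- n1v[i]; k2 <- s2v[i]; n2 <- n2v[i]
      if (n1 < 2 || n2 < 2) return(1)
      f <- fam
      if (f == "auto_binary") f <- select_binary_test(k1, n1, k2, n2)
      if (f == "fisher_exact") fisher_exact_test(k1, n1, k2, n2, alt)$pvalue
      else prop_z_test(k1, n1, k2, n2, alt)$pvalue
    }, numeric(1))
  }
}

#' Is a junction between two adjacent blocks significant at level alpha?
#'
#' Feasibility in the restricted parameter space: the two-sample p-value of
#' left block vs right block must satisfy `p <= alpha`.  The non-strict
#' comparison reproduces both stated limits: `alpha = 0` admits no junction
#' (single block), `alpha = 1` admits every junction (all singletons).
#'
#' @param tc a [time_course()].
#' @param left,right adjacent blocks, each `c(start, end)` with
#'   `left[2] + 1 == right[1]`.
#' @param alpha significance level in `[0, 1]`.
#' @param spec a [test_spec()].
#' @return list with `feasible` (logical) and `pvalue`.
#' @export
junction_feasible <- function(tc, left, right, alpha, spec = test_spec()) {
  if (left[2] + 1 != right[1])
    stop("blocks are not adjacent", call. = FALSE)
  p <- junction_pvalue(tc, left[1], left[2], right[2], spec)
  list(feasible = p <= alpha, pvalue = p)
}
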