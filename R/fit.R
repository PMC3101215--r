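# Fit-object plumbing shared by the DP and the greedy baselines.

# spec family/alternative -> integer codes for the C++ core
.spec_codes <- function(tc, spec) {
  fam <- resolve_family(spec, tc$mode)
  list(binary = as.integer(tc$mode == "binary"),
       alt = match(spec$alternative, c("two_sided", "greater", "less")) - 1L,
       fam = match(fam, c("auto_binary", "proportion_z", "fisher_exact")) - 1L)
}

# assemble the user-facing fit object from a vector of block ends
make_fit <- function(tc, ends, alpha, spec, method, objective = NULL) {
  ends <- as.integer(ends)
  K <- length(ends)
  starts <- c(1L, ends[-K] + 1L)
  if (is.null(objective)) objective <- partition_objective(tc, ends)
  bs <- block_summary_vec(tc, starts, ends)
  est <- bs$sum / bs$count
  sizes <- ends - starts + 1L
  pointwise <- rep.int(est, sizes)
  jp <- if (K > 1)
    junction_pvalue(tc, starts[-K], ends[-K], ends[-1], spec) else numeric(0)
  structure(list(
    blocks = data.frame(start = starts, end = ends,
                        start_time = tc$times[starts], end_time = tc$times[ends],
                        n_obs = bs$count, estimate = est),
    ends = ends,
    change_points = if (K > 1) tc$times[ends[-K]] else numeric(0),
    block_estimates = est,
    pointwise_estimates = pointwise,
    junction_pvalues = jp,
    feasible = all(jp <= alpha),
    objective = objective,
    sigma2_hat = if (tc$mode == "continuous") objective / tc$N else NULL,
    alpha = alpha, method = method, mode = tc$mode, spec = spec,
    times = tc$times, m = tc$m, N = tc$N, n = tc$n
  ), class = "ap_fit")
}

#' @export
print.ap_fit <- function(x, ...) {
  cat(sprintf("Adaptive-partition fit (%s, %s mode), alpha = %g\n",
              toupper(x$method), x$mode, x$alpha))
  cat(sprintf("  %d block(s), objective = %.6g", nrow(x$blocks), x$objective))
  if (!is.null(x$sigma2_hat)) cat(sprintf(", sigma2_hat = %.6g", x$sigma2_hat))
  cat("\n")
  if (length(x$change_points))
    cat("  change-points after time:",
        paste(signif(x$change_points, 6), collapse = ", "), "\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Globally optimal significance-restricted partition (modified DP)
#'
#' Finds the partition of the time course into consecutive blocks that
#' minimises the objective (SSE, or binomial negative log-likelihood in
#' binary mode) over all partitions whose every adjacent pair of blocks
#' differs significantly at level `alpha` by the configured two-sample test.
#' This is the maximum-likelihood estimate over the restricted parameter
#' space; the modification of the classical dynamic program is a feasibility
#' screen of predecessor states at every time point.
#'
#' `alpha = 0` always returns the single-block fit; `alpha = 1` returns the
#' all-singleton partition whenever every junction is non-degenerate.
#'
#' @param tc a [time_course()].
#' @param alpha significance level in `[0, 1]` required between adjacent
#'   blocks.
#' @param spec a [test_spec()].
#' @param keep_sets keep the per-time-point triplet sets (diagnostics /
#'   backtracking); memory O(n^2).
#' @return An object of class `ap_fit`; when `keep_sets = TRUE` it carries a
#'   `triplet_sets` attribute, a list of data frames `(link, index, score)`
#'   sorted by score.
#' @examples
#' tc <- time_course(rep(1:4, each = 3),
#'                   c(0, 1, 2, 1, 2, 0, 10, 11, 12, 11, 12, 10))
#' fit <- fit_dp(tc, alpha = 0.05)
#' fit$ends        # 2 4
#' fit$objective   # 8
#' @export
fit_dp <- function(tc, alpha, spec = test_spec(), keep_sets = FALSE) {
  stopifnot(inherits(tc, "time_course"), alpha >= 0, alpha <= 1)
  cd <- .spec_codes(tc, spec)
  res <- dp_fit_cpp(tc$cm, tc$cs, tc$css, alpha, cd$binary, cd$alt, cd$fam,
                    keep_sets)
  fit <- make_fit(tc, res$ends, alpha, spec, "dp", objective = res$objective)
  if (keep_sets) attr(fit, "triplet_sets") <- res$sets
  fit
}

#' Backtrack a partition from retained triplet sets
#'
#' Follows `(link, index)` pointers from a designated element of the final
#' triplet set down to link 0, emitting the block ends.  Used to cross-check
#' the compiled backtracking and for diagnostics.
#'
#' @param sets list of triplet-set data frames (the `triplet_sets` attribute
#'   of a [fit_dp()] call with `keep_sets = TRUE`).
#' @param t time point to start from (default: the last).
#' @param pos 1-based position within that set (default 1, the optimum).
#' @return integer vector of block end indices.
#' @export
backtrack_triplets <- function(sets, t = length(sets), pos = 1L) {
  ends <- integer(0)
  repeat {
    st <- sets[[t]]
    if (pos < 1 || pos > nrow(st)) stop("broken pointer chain", call. = FALSE)
    ends <- c(t, ends)
    lk <- st$link[pos]; ix <- st$index[pos]
    if (lk == 0L) break
    if (lk >= t) stop("broken pointer chain", call. = FALSE)
    t <- lk; pos <- ix + 1L
  }
  ends
}

#' Exhaustive-search oracle for the restricted optimum
#'
#' Enumerates all `2^(n-1)` compositions of the time points, keeps those in
#' which every adjacent junction is significant at `alpha`, and returns the
#' feasible composition with the smallest objective.  The single-block
#' composition is always feasible, so a solution always exists.  Intended as
#' an independent verification of [fit_dp()] at small `n`; it shares none of
#' the compiled code.
#'
#' Ties are broken the way the DP's stable sort breaks them: among
#' equal-objective optima the partition that is finer from the right end
#' wins (compare block starts from the last block backwards, larger start
#' first), so `alpha = 1` yields the all-singleton partition even on
#' exact-tie data.
#'
#' @inheritParams fit_dp
#' @return An `ap_fit` (method `"oracle"`) with attribute `n_optima`, the
#'   number of feasible compositions attaining the optimal objective exactly.
#' @export
exhaustive_oracle <- function(tc, alpha, spec = test_spec()) {
  n <- tc$n
  if (n > 20) stop("exhaustive oracle guarded at n <= 20", call. = FALSE)
  # memoised junction p-values p[a, s, b] and block objectives o[a, b]
  pv <- array(NA_real_, c(n, n, n))
  ov <- matrix(NA_real_, n, n)
  objf <- function(a, b) {
    if (is.na(ov[a, b])) ov[a, b] <<- block_objective(tc, a, b)
    ov[a, b]
  }
  feas <- function(a, s, b) {
    if (is.na(pv[a, s, b]))
      pv[a, s, b] <<- junction_pvalue(tc, a, s, b, spec)
    pv[a, s, b] <= alpha
  }
  best_obj <- Inf; best_ends <- NULL; n_optima <- 0L
  # reversed-start lexicographic order: TRUE if e1 preferred over e2
  prefer <- function(e1, e2) {
    s1 <- rev(c(1L, e1[-length(e1)] + 1L))
    s2 <- rev(c(1L, e2[-length(e2)] + 1L))
    len <- min(length(s1), length(s2))
    for (i in seq_len(len)) {
      if (s1[i] > s2[i]) return(TRUE)
      if (s1[i] < s2[i]) return(FALSE)
    }
    length(s1) > length(s2)
  }
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- if (n > 1) which(bitwAnd(mask, 2^(0:(n - 2))) > 0) else integer(0)
    ends <- c(cuts, n)
    starts <- c(1L, ends[-length(ends)] + 1L)
    ok <- TRUE
    if (length(ends) > 1) {
      for (j in seq_len(length(ends) - 1)) {
        if (!feas(starts[j], ends[j], ends[j + 1])) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    tot <- 0
    for (j in seq_along(ends)) tot <- tot + objf(starts[j], ends[j])
    if (tot < best_obj) {
      best_obj <- tot; best_ends <- ends; n_optima <- 1L
    } else if (tot == best_obj) {
      n_optima <- n_optima + 1L
      if (prefer(ends, best_ends)) best_ends <- ends
    }
  }
  fit <- make_fit(tc, best_ends, alpha, spec, "oracle", objective = best_obj)
  attr(fit, "n_optima") <- n_optima
  fit
}
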