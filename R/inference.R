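# Permutation F-type test of "no change-point" and bootstrap time-point-wise
# confidence intervals.

#' F-type statistic comparing the null (single-block) and fitted objectives
#'
#' Continuous mode: `(SSE_null - SSE_alt) / SSE_alt`, the SSE-ratio form of
#' the likelihood ratio; binary mode: the deviance `2 * (NLL_null -
#' NLL_alt)`.  Any monotone transform is equivalent under the permutation
#' calibration, so no degrees-of-freedom normalisation is applied (the block
#' count is data-dependent anyway).  Clamped at 0; a perfect alternative fit
#' (`objective_alt = 0`) in continuous mode returns `Inf`.
#'
#' @param objective_null objective of the single-block fit.
#' @param objective_alt objective of the fitted restricted partition.
#' @param mode `"continuous"` or `"binary"`.
#' @export
f_statistic <- function(objective_null, objective_alt, mode = "continuous") {
  stopifnot(objective_alt <= objective_null + 1e-8 * max(objective_null, 1))
  d <- max(objective_null - objective_alt, 0)
  if (mode == "binary") return(2 * d)
  if (objective_alt <= 0) return(if (d > 0) Inf else 0)
  d / objective_alt
}

# F-type statistic for one expanded response vector on tc's slot structure
.f_for_response <- function(tc, y, alpha, cd) {
  tcp <- replace_response(tc, y)
  r <- dp_fit_cpp(tcp$cm, tcp$cs, tcp$css, alpha, cd$binary, cd$alt, cd$fam,
                  FALSE)
  null_obj <- block_objective(tcp, 1L, tcp$n)
  f_statistic(null_obj, r$objective, tcp$mode)
}

#' Permutation test of the no-change-point null
#'
#' Permutes the pooled observations across the expanded time-point slots
#' (the per-point replicate counts are preserved -- equivalent to permuting
#' the expanded time variable), refits the restricted DP at the same
#' `alpha` on each permutation, and compares the observed F-type statistic
#' with the permuted ones.  The conservative p-value
#' `(#\{F* >= F\} + 1) / (B + 1)` counts the observed ordering as one of the
#' permutations and can never be zero; it is the default.
#'
#' @inheritParams fit_dp
#' @param B number of permutations.
#' @param seed integer seed for the permutation stream (local to this call).
#' @param conservative include the observed statistic in the null set.
#' @return list of class `ap_permtest`: `f_observed`, `null_scores`,
#'   `pvalue`, `conservative`, `B`, `seed`.
#' @export
permutation_test <- function(tc, alpha, spec = test_spec(), B = 99,
                             seed = 1L, conservative = TRUE) {
  stopifnot(B >= 1)
  cd <- .spec_codes(tc, spec)
  y <- unlist(tc$obs, use.names = FALSE)
  f_obs <- .f_for_response(tc, y, alpha, cd)
  fstar <- local_seed(seed, {
    vapply(seq_len(B), function(b)
      .f_for_response(tc, sample(y), alpha, cd), numeric(1))
  })
  hits <- sum(fstar >= f_obs)
  pvalue <- if (conservative) (hits + 1) / (B + 1) else hits / B
  structure(list(f_observed = f_obs, null_scores = fstar, pvalue = pvalue,
                 conservative = conservative, B = B, seed = seed),
            class = "ap_permtest")
}

#' @export
print.ap_permtest <- function(x, ...) {
  cat(sprintf("Permutation F-type test: F = %.4g, p = %.4g (B = %d%s)\n",
              x$f_observed, x$pvalue, x$B,
              if (x$conservative) ", conservative" else ""))
  invisible(x)
}

#' Bootstrap time-point-wise confidence intervals
#'
#' Resamples the `N` expanded `(time, response)` pairs with replacement,
#' refits the restricted DP at the same `alpha` on each resample, and reads
#' off the fitted value at every original time point (the plug-in
#' principle).  A time point absent from a resample contributes a missing
#' value to that resample's row.  Bounds are the empirical
#' `(1 - level)/2` and `1 - (1 - level)/2` percentiles of the non-missing
#' resample estimates per time point.
#'
#' @inheritParams fit_dp
#' @param B number of bootstrap resamples.
#' @param seed integer seed (local to this call).
#' @param level nominal coverage of the intervals.
#' @return list of class `ap_bootstrap`: `estimates` (B x n matrix with NA
#'   at unsampled time points), `lower`, `upper`, `level`, `n_effective`
#'   (non-missing resamples per time point), `times`, `B`, `seed`.
#' @export
bootstrap_cis <- function(tc, alpha, spec = test_spec(), B = 200,
                          seed = 1L, level = 0.95) {
  stopifnot(B >= 1, level > 0, level < 1)
  cd <- .spec_codes(tc, spec)
  z <- rep.int(tc$times, tc$m)
  w <- unlist(tc$obs, use.names = FALSE)
  N <- tc$N
  est <- local_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      zb <- z[idx]; wb <- w[idx]
      o <- order(zb)
      zb <- zb[o]; wb <- wb[o]
      ut <- unique(zb)
      r <- rle(match(zb, ut))
      tcb <- new_time_course(ut, split(wb, rep.int(seq_along(ut), r$lengths)),
                             mode = tc$mode)
      fr <- dp_fit_cpp(tcb$cm, tcb$cs, tcb$css, alpha, cd$binary, cd$alt,
                       cd$fam, FALSE)
      kends <- fr$ends
      kstarts <- c(1L, kends[-length(kends)] + 1L)
      bsum <- block_summary_vec(tcb, kstarts, kends)
      pw <- rep.int(bsum$mean, kends - kstarts + 1L)
      pw[match(tc$times, ut)]            # NA where a time point was unsampled
    }, numeric(tc$n)))
  })
  n_eff <- colSums(!is.na(est))
  if (any(n_eff == 0))
    warning("time point(s) absent from every resample: ",
            paste(tc$times[n_eff == 0], collapse = ", "))
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(est, 2, function(col)
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else stats::quantile(col, pr, na.rm = TRUE, names = FALSE))
  structure(list(estimates = est, lower = qs[1, ], upper = qs[2, ],
                 level = level, n_effective = n_eff, times = tc$times,
                 B = B, seed = seed),
            class = "ap_bootstrap")
}

#' @export
print.ap_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap pointwise CIs: B = %d, level = %g\n", x$B, x$level))
  print(data.frame(time = x$times, lower = x$lower, upper = x$upper,
                   n_effective = x$n_effective), row.names = FALSE)
  invisible(x)
}

# evaluate `expr` under a locally seeded RNG, restoring the caller's state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
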