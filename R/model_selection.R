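# Cross-validated choice of the significance level alpha.

#' Cross-validation scheme
#'
#' @param scheme `"loo"` (leave-one-out over observations) or `"kfold"`.
#' @param k number of folds (kfold only).
#' @param seed integer seed for the fold assignment (kfold only).
#' @export
cv_spec <- function(scheme = c("loo", "kfold"), k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold") stopifnot(k >= 2)
  structure(list(scheme = scheme, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Default grid of candidate significance levels
#'
#' Twelve values spanning five orders of magnitude, from 1e-5 to 0.5.
#' @export
default_alpha_grid <- function() {
  c(1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5)
}

#' Predict the fitted mean at an arbitrary time value
#'
#' Returns the fitted (piecewise-constant) value at a training time point;
#' between training time points, the linear interpolation of the two nearest
#' fitted values; outside the training range, the fitted value at the
#' nearest endpoint (constant extrapolation).
#'
#' @param fit an `ap_fit`.
#' @param time numeric vector of query time values.
#' @export
predict_heldout <- function(fit, time) {
  xs <- fit$times; ys <- fit$pointwise_estimates
  if (length(xs) == 0) stop("empty training set", call. = FALSE)
  if (length(xs) == 1) return(rep.int(ys, length(time)))
  stats::approx(xs, ys, xout = time, rule = 2, ties = "ordered")$y
}

#' @rdname predict_heldout
#' @param object an `ap_fit`.
#' @param newdata numeric vector of time values (default: training times).
#' @param ... unused.
#' @export
predict.ap_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$pointwise_estimates)
  predict_heldout(object, newdata)
}

.fit_method <- function(tc, alpha, spec, method) {
  switch(method,
         dp = fit_dp(tc, alpha, spec),
         rc = fit_recursive_combination(tc, alpha, spec),
         rp = fit_recursive_partition(tc, alpha, spec),
         stop("unknown method: ", method, call. = FALSE))
}

#' Cross-validated prediction error at a fixed alpha
#'
#' Folds split the expanded observations (not the time points), so a time
#' point with replicates can appear on both sides of a split.  Each held-out
#' observation is predicted from a fit on the remaining observations
#' ([predict_heldout()] handles time points that drop out of the training
#' set); the total squared prediction error is returned.  Binary mode uses
#' the same squared-error (Brier) loss on the fitted proportions.
#'
#' @inheritParams fit_dp
#' @param cv a [cv_spec()].
#' @param method `"dp"`, `"rc"` or `"rp"`.
#' @export
cv_error <- function(tc, alpha, spec = test_spec(), cv = cv_spec(),
                     method = "dp") {
  z <- rep.int(tc$times, tc$m)
  y <- unlist(tc$obs, use.names = FALSE)
  N <- tc$N
  fold <- if (cv$scheme == "loo") seq_len(N)
          else local_seed(cv$seed, sample(rep_len(seq_len(cv$k), N)))
  err <- 0
  for (f in unique(fold)) {
    hold <- fold == f
    if (all(hold)) stop("a training fold would be empty", call. = FALSE)
    tc_tr <- time_course(z[!hold], y[!hold], mode = tc$mode)
    fit <- .fit_method(tc_tr, alpha, spec, method)
    pred <- predict_heldout(fit, z[hold])
    err <- err + sum((y[hold] - pred)^2)
  }
  err
}

#' Choose alpha by cross-validation over a grid
#'
#' Computes [cv_error()] at every grid value and returns the minimiser;
#' exact ties go to the smallest alpha (a smaller alpha means more
#' significant detected changes and is preferred).
#'
#' @inheritParams cv_error
#' @param grid numeric vector of candidate alpha values.
#' @return list of class `alpha_selection`: `grid` (sorted ascending),
#'   `cv_errors`, `chosen`.
#' @export
select_alpha <- function(tc, grid = default_alpha_grid(), spec = test_spec(),
                         cv = cv_spec(), method = "dp") {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  errs <- vapply(grid, function(a) cv_error(tc, a, spec, cv, method),
                 numeric(1))
  structure(list(grid = grid, cv_errors = errs,
                 chosen = grid[which.min(errs)]),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat("Cross-validated alpha selection\n")
  print(data.frame(alpha = x$grid, cv_error = x$cv_errors),
        row.names = FALSE)
  cat(sprintf("chosen alpha = %g\n", x$chosen))
  invisible(x)
}
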