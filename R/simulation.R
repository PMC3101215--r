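# Synthetic-scenario generator and the evaluation metrics used to compare
# the DP against the greedy baselines.

#' Piecewise-constant mean profiles for simulation scenarios
#'
#' Named shapes over `n` equally spaced time points (times `1..n`):
#' \describe{
#'   \item{flat}{`levels[1]` everywhere (null scenario).}
#'   \item{step}{first half `levels[1]`, second half `levels[2]`.}
#'   \item{multistep}{three equal thirds at `levels[1..3]`.}
#'   \item{ushape}{three equal thirds at `levels[1]`, `levels[2]`,
#'     `levels[1]` (symmetric U).}
#' }
#' Break positions default to equal segments; pass `breaks` (last index of
#' each segment but the final one) to override.
#'
#' @param shape profile name.
#' @param n number of time points.
#' @param levels segment levels (recycled/truncated to the shape's needs).
#' @param breaks optional custom break positions.
#' @return numeric vector of true means, one per time point.
#' @export
scenario_profile <- function(shape = c("flat", "step", "multistep", "ushape"),
                             n = 20, levels = NULL, breaks = NULL) {
  shape <- match.arg(shape)
  stopifnot(n >= 2)
  seg_levels <- switch(shape,
    flat      = if (is.null(levels)) 0 else levels[1],
    step      = if (is.null(levels)) c(0, 1) else levels[1:2],
    multistep = if (is.null(levels)) c(0, 1, 0.3) else levels[1:3],
    ushape    = if (is.null(levels)) c(0.5, 0, 0.5)
                else c(levels[1], levels[2], levels[1]))
  k <- length(seg_levels)
  if (is.null(breaks)) breaks <- round(seq_len(k - 1) * n / k)
  stopifnot(length(breaks) == k - 1)
  sizes <- diff(c(0, breaks, n))
  stopifnot(all(sizes >= 1))
  rep.int(seg_levels, sizes)
}

#' Simulation scenario recipe
#'
#' @param profile numeric vector of true per-time-point means (e.g. from
#'   [scenario_profile()]); in binary mode all values must lie in `[0, 1]`.
#' @param sigma noise standard deviation (continuous mode).
#' @param m replicates per time point.
#' @param mode `"continuous"` or `"binary"`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param name label carried into reports.
#' @export
scenario_spec <- function(profile, sigma = 1, m = 1,
                          mode = c("continuous", "binary"), seed = NULL,
                          name = "scenario") {
  mode <- match.arg(mode)
  stopifnot(length(profile) >= 2, m >= 1)
  if (mode == "continuous") stopifnot(sigma > 0)
  if (mode == "binary") stopifnot(all(profile >= 0 & profile <= 1))
  structure(list(profile = profile, sigma = sigma, m = as.integer(m),
                 mode = mode, seed = seed, name = name, n = length(profile)),
            class = "scenario_spec")
}

#' The four default simulation scenarios
#'
#' Step (n=20, levels 0 to 1), flat null (n=20, level 0), three-level
#' multi-step (n=30, levels 0/1/0.3) and small-amplitude U-shape (n=30,
#' levels 0.5/0/0.5), all with `sigma = 1`.
#'
#' @param m replicates per time point.
#' @export
default_scenarios <- function(m = 1) {
  list(
    scenario_spec(scenario_profile("step", 20), m = m, name = "step"),
    scenario_spec(scenario_profile("flat", 20), m = m, name = "flat"),
    scenario_spec(scenario_profile("multistep", 30), m = m, name = "multistep"),
    scenario_spec(scenario_profile("ushape", 30), m = m, name = "ushape"))
}

#' Simulate a time course from a scenario
#'
#' Continuous mode: `y = mu_i + sigma * epsilon`, epsilon i.i.d. standard
#' normal; binary mode: `y ~ Bernoulli(mu_i)`.
#'
#' @param spec a [scenario_spec()].
#' @return list with `tc` (a [time_course()]) and `truth` (the per-point
#'   means).
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  gen <- function() {
    n <- spec$n; m <- spec$m
    mu <- rep(spec$profile, each = m)
    y <- if (spec$mode == "binary") stats::rbinom(n * m, 1, mu)
         else mu + spec$sigma * stats::rnorm(n * m)
    obs <- split(y, rep(seq_len(n), each = m))
    names(obs) <- NULL
    new_time_course(seq_len(n), obs, rep.int(spec$m, n), spec$mode)
  }
  tc <- if (is.null(spec$seed)) gen() else local_seed(spec$seed, gen())
  list(tc = tc, truth = spec$profile)
}

#' Overall mean squared error of a fit against the truth
#'
#' Observation-weighted: `sum_i m_i (muhat_i - mu_i)^2 / N`.
#'
#' @param fit an `ap_fit`.
#' @param truth numeric vector of true per-time-point means.
#' @export
overall_mse <- function(fit, truth) {
  stopifnot(length(truth) == fit$n)
  sum(fit$m * (fit$pointwise_estimates - truth)^2) / fit$N
}

#' Time-point-wise MSE, bias and variance across replicates
#'
#' All three use denominator `R` (not `R - 1`), so the decomposition
#' `mse = bias^2 + variance` holds exactly.
#'
#' @param estimates R x n matrix of per-replicate estimates.
#' @param truth length-n vector of true means.
#' @return list with vectors `mse`, `bias`, `variance`.
#' @export
pointwise_stats <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  stopifnot(ncol(estimates) == length(truth), nrow(estimates) >= 1)
  mu_bar <- colMeans(estimates)
  bias <- mu_bar - truth
  variance <- colMeans(sweep(estimates, 2, mu_bar)^2)
  mse <- colMeans(sweep(estimates, 2, truth)^2)
  list(mse = mse, bias = bias, variance = variance)
}

#' Simulation comparison of DP against the greedy baselines
#'
#' For each scenario and replicate, simulates one data set, fits every
#' method at every alpha in the grid, and records the minimal overall MSE
#' across the grid together with the alpha attaining it (exact ties to the
#' smallest alpha) -- the oracle-alpha protocol that stands in for
#' cross-validation when the truth is known.
#'
#' @param scenarios list of [scenario_spec()]s (each carries its own `m`).
#' @param methods subset of `c("dp", "rc", "rp")`.
#' @param alpha_grid candidate significance levels.
#' @param R replicates per scenario.
#' @param seed integer master seed; replicate streams are drawn from it.
#' @param spec a [test_spec()].
#' @return data frame of class `ap_comparison`, one row per
#'   scenario/replicate/method with `best_mse` and `best_alpha`.
#' @export
run_comparison <- function(scenarios, methods = c("dp", "rc", "rp"),
                           alpha_grid = default_alpha_grid(), R = 100,
                           seed = 1L, spec = test_spec()) {
  stopifnot(R >= 1)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  alpha_grid <- sort(alpha_grid)
  seeds <- local_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(scenarios) * R),
           nrow = length(scenarios)))
  rows <- vector("list", length(scenarios) * R * length(methods))
  ri <- 0L
  for (sc in seq_along(scenarios)) {
    spec_sc <- scenarios[[sc]]
    for (r in seq_len(R)) {
      spec_sc$seed <- seeds[sc, r]
      sim <- simulate_scenario(spec_sc)
      for (mth in methods) {
        mses <- vapply(alpha_grid, function(a)
          overall_mse(.fit_method(sim$tc, a, spec, mth), sim$truth),
          numeric(1))
        j <- which.min(mses)             # grid ascending: ties -> smallest
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          scenario = spec_sc$name, m = spec_sc$m, replicate = r,
          method = mth, best_mse = mses[j], best_alpha = alpha_grid[j])
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ap_comparison", "data.frame")
  out
}

#' Summarise a method comparison
#'
#' Median best MSE and selected alpha per scenario and method, plus the
#' per-replicate MSE ratios of each baseline against the DP.
#'
#' @param object an `ap_comparison` from [run_comparison()].
#' @param ... unused.
#' @export
summary.ap_comparison <- function(object, ...) {
  agg <- stats::aggregate(cbind(best_mse, best_alpha) ~ scenario + m + method,
                          data = object, FUN = stats::median)
  names(agg)[4:5] <- c("median_best_mse", "median_best_alpha")
  ratios <- NULL
  if ("dp" %in% object$method) {
    dp <- object[object$method == "dp", ]
    for (mth in setdiff(unique(object$method), "dp")) {
      other <- object[object$method == mth, ]
      key <- c("scenario", "m", "replicate")
      mg <- merge(dp, other, by = key, suffixes = c("_dp", paste0("_", mth)))
      ratios <- rbind(ratios, data.frame(
        scenario = mg$scenario, m = mg$m, replicate = mg$replicate,
        baseline = mth,
        mse_ratio = mg[[paste0("best_mse_", mth)]] / mg$best_mse_dp,
        alpha_ratio = mg[[paste0("best_alpha_", mth)]] / mg$best_alpha_dp))
    }
  }
  list(medians = agg, ratios = ratios)
}

#' Write a comparison as a tidy TSV
#'
#' @param x an `ap_comparison`.
#' @param path output file.
#' @export
write_comparison <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
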