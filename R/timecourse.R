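#' Replicated time-course data
#'
#' Builds the central data structure of the package from long-format input:
#' one row per observation, a "time" value (any ordered continuous or ordinal
#' predictor -- calendar time, age, BMI, chromosomal position, ...) and a
#' response.  Observations sharing a time value become replicates at one
#' distinct time point.  Cumulative (prefix) counts, sums and sums of squares
#' over the ordered time points are precomputed so that any block of
#' consecutive time points can be summarised in O(1).
#'
#' @param time numeric vector of time values, one per observation.
#' @param response numeric vector of responses; in binary mode every value
#'   must be 0 or 1.
#' @param mode `"continuous"` (normal model, SSE objective) or `"binary"`
#'   (Bernoulli model, negative log-likelihood objective).
#' @return An object of class `time_course`: a list with elements `times`
#'   (strictly increasing distinct time values), `obs` (list of replicate
#'   vectors, input order preserved within a time point), `m` (replicate
#'   counts), `n` (number of distinct time points), `N` (total observations),
#'   `mode`, and prefix arrays `cm`, `cs`, `css` of length `n + 1`
#'   (position 1 is the empty prefix).
#' @examples
#' tc <- time_course(c(2, 1, 2), c(5, 3, 7))
#' tc$times  # 1 2
#' tc$m      # 1 2
#' @export
time_course <- function(time, response, mode = c("continuous", "binary")) {
  mode <- match.arg(mode)
  if (length(time) == 0L || length(response) == 0L)
    stop("no observations", call. = FALSE)
  if (length(time) != length(response))
    stop("'time' and 'response' must have equal length", call. = FALSE)
  if (anyNA(time) || anyNA(response))
    stop("missing values in 'time' or 'response'", call. = FALSE)
  if (mode == "binary") {
    bad <- which(!(response %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary response value %g at row %d",
                   response[bad[1]], bad[1]), call. = FALSE)
  }
  ord <- order(time)                       # stable: within-time input order kept
  time <- time[ord]; response <- response[ord]
  times <- unique(time)
  grp <- match(time, times)
  obs <- split(response, grp)
  names(obs) <- NULL
  m <- lengths(obs)
  new_time_course(times, obs, m, mode)
}

# fast internal constructor: inputs already grouped/sorted, no validation
new_time_course <- function(times, obs, m = lengths(obs), mode = "continuous") {
  y <- unlist(obs, use.names = FALSE)
  cm <- c(0, cumsum(as.numeric(m)))
  edge <- cm[-1]                           # expanded index of each point's last obs
  cy <- cumsum(y); cy2 <- cumsum(y * y)
  structure(list(
    times = times, obs = obs, m = as.integer(m),
    n = length(times), N = length(y), mode = mode,
    cm = cm, cs = c(0, cy[edge]), css = c(0, cy2[edge])
  ), class = "time_course")
}

# prefix arrays for a permuted/replaced expanded response on the same slots
replace_response <- function(tc, y) {
  cy <- cumsum(y); cy2 <- cumsum(y * y)
  edge <- tc$cm[-1]
  tc$cs <- c(0, cy[edge]); tc$css <- c(0, cy2[edge])
  tc$obs <- split(y, rep.int(seq_len(tc$n), tc$m))
  names(tc$obs) <- NULL
  tc
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %d time points, %d observations (%s mode)\n",
              x$n, x$N, x$mode))
  cat(sprintf("  time range [%g, %g], replicates per point %d-%d\n",
              x$times[1], x$times[x$n], min(x$m), max(x$m)))
  invisible(x)
}

#' Summary statistics of a block of consecutive time points
#'
#' @param tc a [time_course()].
#' @param start,end 1-based inclusive time-point indices of the block.
#' @return list with `count`, `mean` and `sse` (sum of squared deviations of
#'   all observations in the block from the block mean).  Computed from the
#'   prefix arrays; tiny negative floating-point residue in the SSE is
#'   clamped to zero.
#' @examples
#' tc <- time_course(c(1, 1, 2, 2), c(1, 2, 3, 4))
#' block_stats(tc, 1, 2)  # count 4, mean 2.5, sse 5
#' @export
block_stats <- function(tc, start, end) {
  stopifnot(start >= 1, end <= tc$n, start <= end)
  cnt <- tc$cm[end + 1] - tc$cm[start]
  s <- tc$cs[end + 1] - tc$cs[start]
  ss <- tc$css[end + 1] - tc$css[start]
  mu <- s / cnt
  sse <- ss - cnt * mu * mu
  if (sse < 0) {
    if (sse < -1e-12 * max(ss, 1)) stop("internal: negative block SSE")
    sse <- 0
  }
  list(count = cnt, mean = mu, sse = sse)
}

# vectorised block summaries over index vectors (internal hot path)
block_summary_vec <- function(tc, start, end) {
  cnt <- tc$cm[end + 1] - tc$cm[start]
  s <- tc$cs[end + 1] - tc$cs[start]
  ss <- tc$css[end + 1] - tc$css[start]
  mu <- s / cnt
  sse <- pmax(ss - cnt * mu * mu, 0)
  list(count = cnt, sum = s, mean = mu, sse = sse)
}

#' Binomial negative log-likelihood of a block (binary mode)
#'
#' With `k` successes among `c` observations and `p = k/c`, returns
#' `-(k log p + (c - k) log(1 - p))`, using the convention `0 log 0 = 0`.
#'
#' @inheritParams block_stats
#' @export
block_negloglik <- function(tc, start, end) {
  if (tc$mode != "binary")
    stop("binary objective on continuous data", call. = FALSE)
  stopifnot(start >= 1, end <= tc$n, start <= end)
  cnt <- tc$cm[end + 1] - tc$cm[start]
  k <- tc$cs[end + 1] - tc$cs[start]
  binom_negll(k, cnt)
}

binom_negll <- function(k, cnt) {
  ll <- 0
  if (k > 0) ll <- ll + k * log(k / cnt)
  if (cnt - k > 0) ll <- ll + (cnt - k) * log(1 - k / cnt)
  max(-ll, 0)
}

# block objective in the course's own mode
block_objective <- function(tc, start, end) {
  if (tc$mode == "binary") block_negloglik(tc, start, end)
  else block_stats(tc, start, end)$sse
}

# vectorised objectives
block_objective_vec <- function(tc, start, end) {
  if (tc$mode == "binary") {
    cnt <- tc$cm[end + 1] - tc$cm[start]
    k <- tc$cs[end + 1] - tc$cs[start]
    p <- k / cnt
    t1 <- ifelse(k > 0, k * log(p), 0)
    t2 <- ifelse(cnt - k > 0, (cnt - k) * log(1 - p), 0)
    pmax(-(t1 + t2), 0)
  } else {
    block_summary_vec(tc, start, end)$sse
  }
}

#' Total objective of a partition
#'
#' Sums the per-block objective (SSE in continuous mode, binomial negative
#' log-likelihood in binary mode) over the blocks of a partition given as a
#' vector of block end indices.  Additivity over blocks is what the dynamic
#' program exploits.
#'
#' @param tc a [time_course()].
#' @param ends strictly increasing integer vector of block end indices; the
#'   last element must equal `tc$n` (blocks are `1..ends[1]`,
#'   `ends[1]+1..ends[2]`, ...).
#' @export
partition_objective <- function(tc, ends) {
  ends <- as.integer(ends)
  if (length(ends) == 0 || is.unsorted(ends, strictly = TRUE) ||
      ends[length(ends)] != tc$n || ends[1] < 1)
    stop("'ends' must be strictly increasing block end indices covering 1..n",
         call. = FALSE)
  starts <- c(1L, ends[-length(ends)] + 1L)
  tot <- 0
  for (b in seq_along(ends))
    tot <- tot + block_objective(tc, starts[b], ends[b])
  tot
}

#' Maximum-likelihood variance estimate (continuous mode)
#'
#' `sse / N`: the MLE denominator under the common-variance normal model.
#'
#' @param tc a [time_course()].
#' @param sse total sum of squared errors of a fitted partition.
#' @export
estimate_variance <- function(tc, sse) {
  if (tc$mode != "continuous")
    stop("variance estimate applies to continuous mode only", call. = FALSE)
  stopifnot(sse >= 0)
  sse / tc$N
}
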