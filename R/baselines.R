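# Greedy approximation baselines: bottom-up recursive combination and
# top-down recursive partition.  Both use the likelihood criterion to pick
# among admissible moves (the merge/split that leaves the smallest total
# objective), one move per loop.

#' Recursive combination (bottom-up merging) baseline
#'
#' Starts from the all-singleton partition.  In each loop, every adjacent
#' pair of blocks whose two-sample p-value exceeds `alpha` is a merge
#' candidate; among candidates the merge that minimises the resulting total
#' objective (equivalently, maximises the overall likelihood) is performed.
#' Stops when every adjacent junction has `p <= alpha`, so the output is
#' always feasible in the restricted space -- but not necessarily the
#' restricted optimum (see [fit_dp()]).
#'
#' @inheritParams fit_dp
#' @export
fit_recursive_combination <- function(tc, alpha, spec = test_spec()) {
  stopifnot(inherits(tc, "time_course"), alpha >= 0, alpha <= 1)
  ends <- seq_len(tc$n)
  while (length(ends) > 1) {
    K <- length(ends)
    starts <- c(1L, ends[-K] + 1L)
    p <- junction_pvalue(tc, starts[-K], ends[-K], ends[-1], spec)
    cand <- which(p > alpha)
    if (!length(cand)) break
    # objective increase of merging pair (i, i+1)
    delta <- block_objective_vec(tc, starts[cand], ends[cand + 1]) -
      block_objective_vec(tc, starts[cand], ends[cand]) -
      block_objective_vec(tc, starts[cand + 1], ends[cand + 1])
    i <- cand[which.min(delta)]          # ties: leftmost
    ends <- ends[-i]
  }
  make_fit(tc, ends, alpha, spec, "rc")
}

#' Recursive partition (top-down splitting) baseline
#'
#' Starts from the single whole-course block.  In each loop, every internal
#' split point of every block is examined; a split is admissible iff all
#' junction tests it changes have `p <= alpha` -- for a middle block the
#' "triplet" (left neighbour vs left part, left part vs right part, right
#' part vs right neighbour), for a boundary block the pair that exists, and
#' for the initial whole-course block just the internal test.  Among
#' admissible splits the one minimising the total objective is performed.
#' Stops when no split is admissible.
#'
#' @inheritParams fit_dp
#' @param check_neighbors if `FALSE`, only the new internal junction is
#'   tested for admissibility (a sensitivity-analysis variant); the default
#'   `TRUE` tests all changed junctions, which keeps every intermediate
#'   configuration feasible.
#' @export
fit_recursive_partition <- function(tc, alpha, spec = test_spec(),
                                    check_neighbors = TRUE) {
  stopifnot(inherits(tc, "time_course"), alpha >= 0, alpha <= 1)
  ends <- tc$n
  repeat {
    K <- length(ends)
    starts <- c(1L, ends[-K] + 1L)
    best_gain <- -Inf; best <- NULL
    for (k in seq_len(K)) {
      a <- starts[k]; b <- ends[k]
      if (a == b) next
      s <- a:(b - 1L)                     # candidate split points
      adm <- junction_pvalue(tc, rep.int(a, length(s)), s,
                             rep.int(b, length(s)), spec) <= alpha
      if (check_neighbors) {
        if (k > 1) {                      # left neighbour vs left part
          pa <- junction_pvalue(tc, rep.int(starts[k - 1], length(s)),
                                rep.int(a - 1L, length(s)), s, spec)
          adm <- adm & (pa <= alpha)
        }
        if (k < K) {                      # right part vs right neighbour
          pb <- junction_pvalue(tc, s + 1L, rep.int(b, length(s)),
                                rep.int(ends[k + 1], length(s)), spec)
          adm <- adm & (pb <= alpha)
        }
      }
      if (!any(adm)) next
      sa <- s[adm]
      gain <- block_objective(tc, a, b) -
        block_objective_vec(tc, rep.int(a, length(sa)), sa) -
        block_objective_vec(tc, sa + 1L, rep.int(b, length(sa)))
      j <- which.max(gain)                # ties: leftmost split of leftmost block
      if (gain[j] > best_gain) { best_gain <- gain[j]; best <- sa[j] }
    }
    if (is.null(best)) break
    ends <- sort(c(ends, best))
  }
  make_fit(tc, ends, alpha, spec, "rp")
}
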