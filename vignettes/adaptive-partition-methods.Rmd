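---
title: "Significance-restricted segmentation of a time course: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Significance-restricted segmentation of a time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpart)
```

## The model

Observations arrive at $n$ distinct ordered "time points" $x_1 < \dots <
x_n$ — the predictor need not be calendar time; age, BMI or a chromosomal
coordinate work the same way.  At point $i$ there are $m_i \ge 1$ replicate
responses $y_{ij}$, modelled as

$$y_{ij} = \mu_i + \varepsilon_{ij}, \qquad
\varepsilon_{ij} \sim \mathrm{N}(0, \sigma^2) \ \text{i.i.d.},$$

with a **common** variance across time points (binary mode replaces this
with $y_{ij} \sim \mathrm{Bernoulli}(\mu_i)$).  The scientific object is a
partition of $1..n$ into consecutive blocks $B_1, \dots, B_K$ on which the
mean is constant.  Unrestricted maximum likelihood would happily return the
all-singleton partition; the restriction that makes the problem meaningful
is *statistical*: a partition is admissible only if, for every adjacent
pair of blocks, a two-sample test on the observations in the two blocks is
significant at a user-chosen level $\alpha$.  Within the admissible set the
fit minimises the total sum of squared errors (equivalently, maximises the
normal likelihood; in binary mode it minimises the binomial negative
log-likelihood).

Because the two-sample test may be one-sided, the same machinery yields
*reduced isotonic regression*: with alternative `"greater"` every block
must sit significantly above its left neighbour, so the fitted profile is
non-decreasing.

## The modified dynamic program

Classical segmentation DP fails here because an optimal sub-partition may
become inadmissible when extended — admissibility couples adjacent blocks.
The fix is to carry, at every time point $t$, not a single best state but a
set of *triplets* `(link, index, score)`, at most one per possible start of
the current last block: `link` is the time point just before that block,
`index` points into the predecessor's triplet set, `score` is the
accumulated objective.  Extending to a new block $(s{+}1)..t$ scans the
predecessor set of $s$ in score order and keeps the **first** triplet whose
own last block differs significantly from the new block.  That suffices for
global optimality: whether a future block can attach to $(s{+}1)..t$
depends on the data in $(s{+}1)..t$ only, not on how $1..s$ was subdivided,
so one optimal feasible predecessor per link value is all that is ever
needed.  The final answer is backtracked from the lowest-score triplet at
$t = n$.  Block summaries come from prefix counts/sums/sums-of-squares, so
each junction test is O(1); the whole fit is $O(n^2)$–$O(n^3)$ junction
evaluations.  The recursion is implemented in C++; an independent pure-R
exhaustive enumeration (`exhaustive_oracle()`, $2^{n-1}$ compositions)
verifies optimality exactly on small instances in the test suite.

Two design points deserve a note:

* **Variance estimation happens after the recursion.**  The score is the
  raw SSE; $\hat\sigma^2 = \mathrm{SSE}/N$ (the ML denominator) is computed
  once the partition is fixed.  A variance estimated inside the recursion
  would destroy the additive substructure the DP needs.
* **Tie-breaking.**  Exact objective ties are possible (e.g. merging two
  blocks with identical sample means costs zero SSE).  Triplets are
  inserted with the *finer* predecessors first (`s = t-1, \dots, 1`, then
  the single-block state) and sorted stably by score, so among
  equal-objective optima the finer partition wins.  This keeps both limit
  laws exact even on tie data: $\alpha = 0$ always returns one block (no
  junction can achieve $p \le 0$), and $\alpha = 1$ always returns $n$
  singletons.  The exhaustive oracle applies the same rule (compare block
  starts from the right; larger first).

## The junction tests

* Continuous: pooled-variance two-sample $t$ test, computed from summary
  statistics.  The *small-sample rule*: if either side has fewer than two
  observations the reported p-value is 1 — such a junction can never be
  called significant (so isolated singleton blocks only appear at
  $\alpha = 1$).  Zero pooled variance is handled explicitly: equal means
  give $p = 1$, perfect separation gives $p = 0$.
* Binary: two-sample $z$ test for proportions when all four cells of the
  2×2 table are at least 6, otherwise Fisher's exact test (probability-mass
  two-sided convention, identical to `stats::fisher.test`).
* Feasibility is $p \le \alpha$, non-strict.  Strict `<` would break the
  $\alpha = 1$ limit at degenerate junctions ($p = 1$).
* One-sided alternatives are stated as *right block vs left block*;
  internally the sample-1-centric test is called with the flipped tail.

## Inference

**F-type permutation test.**  The statistic compares the single-block
objective with the restricted optimum: $F = (\mathrm{SSE}_0 -
\mathrm{SSE}_A)/\mathrm{SSE}_A$ (deviance $2(\ell_0 - \ell_A)$ in binary
mode).  Its null distribution is intractable — the block count is
data-dependent — so it is calibrated by permuting the pooled responses
across the expanded time slots (replicate counts preserved) and refitting
at the same $\alpha$.  Any monotone transform of $F$ gives the same
permutation p-value, which is why no degrees-of-freedom normalisation is
applied.  The default p-value is the conservative
$(\#\{F^* \ge F\} + 1)/(B + 1)$, which cannot be zero.  $\alpha$ is held
fixed across permutations; re-running the cross-validated selection inside
every permutation would be a different and far costlier procedure.

**Bootstrap pointwise intervals.**  The $N$ expanded $(x, y)$ pairs are
resampled with replacement, refit at the same $\alpha$, and the fitted
value at each original time point is recorded — *missing* when the point
was not drawn into the resample.  Percentile bounds are taken over the
non-missing values per point.  With $m_i = m$ the chance a point is absent
from a resample is $(1 - m/N)^N \approx e^{-m}$, so missingness matters
mainly for $m = 1$ designs.

## Choice of alpha

$\alpha$ acts as a smoothing parameter: 0 gives one block, 1 gives $n$.
`select_alpha()` minimises a cross-validated squared prediction error over
a grid; folds split *observations*, so replicated time points can appear on
both sides.  A held-out observation whose time point vanished from the
training set is predicted by linear interpolation between the nearest
fitted neighbours (constant extrapolation beyond the range — the interior
rule is standard, the boundary rule is this package's choice).  Exact ties
in CV error go to the smallest $\alpha$: a smaller level means more
significant detected changes.  The default 12-value grid
`r paste(default_alpha_grid(), collapse = ", ")` spans the range that is
useful in practice; it is a package default, not a law, and is fully
configurable.  Binary mode uses the same squared-error (Brier) loss on
fitted proportions by default; log-loss would also be defensible but keeps
less comparable magnitudes across modes.

## The synthetic-data generator and what a green test establishes

`simulate_scenario()` draws i.i.d. normal (or Bernoulli) replicates around
a piecewise-constant profile — exactly the model the estimator assumes.
The four default scenarios are: step (n=20, levels 0→1), flat null (n=20),
three-level multi-step (n=30, levels 0/1/0.3) and a small-amplitude U-shape
(n=30, levels 0.5/0/0.5), all with $\sigma = 1$ and $m \in \{1, 10, 100\}$
replicates; where the source material for these scenarios is not explicit
the defaults were fixed once, before any acceptance outcome was observed.
Real time courses violate this world in ways the generator deliberately
does not emulate: unequal variances across time points, serial correlation
of residuals, non-normal tails, unequal $m_i$.  A green simulation test
therefore establishes correctness *under the stated model*, not robustness.

The comparison harness (`run_comparison()`) mirrors the oracle-$\alpha$
protocol: since the truth is known, each method reports its best overall
MSE across the grid and the $\alpha$ attaining it.  Evaluation metrics:
overall MSE is observation-weighted, $\sum_i m_i(\hat\mu_i -
\mu_i)^2 / N$; time-point-wise MSE/bias/variance all use denominator $R$
so that $\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{variance}$ holds exactly,
which the tests assert to $10^{-10}$.

The consistency check fixes $\alpha = 0.001$: recovery of the true
partition requires the small-$\alpha$ regime (at fixed $\alpha$, spurious
feasible refinements appear at a roughly $\alpha$-proportional rate however
large $m$ grows, while the power of the true junctions tends to one — so
$\alpha$ small and $m \to \infty$ is the regime in which exact recovery is
attainable).

## Numerical choices and degenerate inputs

* Block SSEs computed from prefix statistics can go negative by round-off;
  they are clamped at zero (guarded at $10^{-12}$ of the raw sum of
  squares).
* DP-vs-oracle equality is asserted at relative $10^{-10}$, not bitwise:
  the compiled accumulation and the R summation may differ in the last ulp.
* Greedy baselines: recursive combination merges the adjacent pair with
  $p > \alpha$ whose merge costs the least objective (its stopping state is
  exactly feasibility); recursive partition admits a split only if *all*
  junction tests it changes pass — the "triplet" of tests for an interior
  block, a pair at the boundary, the single internal test for the first
  split.  Under this reading every intermediate configuration stays
  feasible; the variant that checks only the new internal junction (and can
  terminate infeasible) is available as `check_neighbors = FALSE`.
* One merge or split per loop; ties go to the leftmost candidate.
* `n = 1` courses, empty junctions (`K = 1` fits) and constant data are all
  legal inputs and exercised in the tests.
* Times equal after rounding (`read_timecourse(granularity = )`,
  round-half-up) are merged into one time point *before* grouping.

## Known limitations

* Heteroscedastic models and covariates beyond the single time variable
  are out of scope.
* The permutation and bootstrap procedures refit the DP only; they do not
  propagate uncertainty in the choice of $\alpha$.
* Welch's unequal-variance junction test is intentionally absent (the
  model assumes a common variance).
* The exhaustive oracle is a verification device; it is guarded at
  $n \le 20$ and meant for $n \lesssim 12$.
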