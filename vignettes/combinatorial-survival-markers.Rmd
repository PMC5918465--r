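---
title: "Mining combinatorial survival markers with FWER control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining combinatorial survival markers with FWER control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(survlamp)
```

## The problem

Prognostic biomarker screens usually test markers one at a time: for each
gene, split the cohort into carriers (say, samples with expression z-score
above 2) and non-carriers, compare their survival with a log-rank test,
and Bonferroni-correct over the number of genes. This misses combinations:
a set of markers that is individually unremarkable can define a small
carrier group with drastically worse survival. Testing all $2^M - 1$
subsets of $M$ markers head-on is hopeless twice over — computationally,
and statistically, because a Bonferroni factor of $2^M - 1$ buries
everything.

`survlamp` implements the testability workaround for the log-rank test.
The key fact (Tarone's idea, popularized for pattern mining by the
Limitless Arity Multiple-testing Procedure, LAMP) is that a combination
carried by very few samples has a *minimum attainable* p-value: however
extreme its survival split, the p-value cannot go below a floor that
depends only on its support. Combinations whose floor lies above the
adjusted threshold can never be significant, contribute nothing to the
family-wise error rate (FWER), and need not be counted in the correction
factor. The search for the support threshold and the enumeration of the
surviving ("testable") combinations is what this package automates.

## Model and notation

Samples $s_\ell$, $\ell = 1 \ldots N$, carry binary markers
$g_i(s_\ell) \in \{0, 1\}$, $i = 1 \ldots M$, and have observed times
$\tau_\ell > 0$ (months) with event indicators $y_\ell \in \{0, 1\}$
($1$ = event, $0$ = censored). A combination $X$ is a marker set; its
carriers are the samples with $g_i = 1$ for every $g_i \in X$, and its
support is the number of carriers.

Let $t_1 < \cdots < t_K$ be the distinct failure times, $Y_j$ the number
of samples with $\tau_\ell \ge t_j$ (at risk; censoring exactly at $t_j$
keeps a sample in the risk set), and $n_j$ the events at $t_j$. For a
combination with $\lambda_j$ carriers at risk and $n_{1j}$ carrier events
at $t_j$, the log-rank statistic is

$$
Z = \frac{\sum_j \left(n_{1j} - n_j \lambda_j / Y_j\right)}
         {\sqrt{\sum_j V_j}},
\qquad
V_j = \frac{\lambda_j (Y_j - \lambda_j)\, n_j (Y_j - n_j)}
           {Y_j^2 (Y_j - 1)},
$$

and $Z^2$ is referred to $\chi^2_1$. Failure times with $Y_j \le 1$ are
skipped in both sums (the variance denominator vanishes); when the total
variance is zero (a combination carried by everyone or no one at risk)
the p-value is defined as 1 with a warning rather than an error, so bulk
enumeration does not stop. P-values always come from the $\chi^2_1$ upper
tail, never from a normal approximation of $Z$.

### The two variance conventions

The derivation this package follows prints the variance with the factor
$(Y_j - \lambda_j - n_j + n_{1j})$ — an observed inner cell of the
contingency table — where the standard margin-only hypergeometric
variance has $(Y_j - \lambda_j)$. No published log-rank derivation makes
the variance depend on the observed cell, and the margin-only form is
what reference implementations (e.g. `survival::survdiff`) compute, so
`variant = "standard"` is the default and the basis of every significance
decision and test oracle in this package. `variant = "paper"` evaluates
the printed form verbatim for literal reproduction. We surface both
rather than silently correcting, since the difference is a documented
discrepancy, not a resolvable typo.

## The minimum p-value bound

For a combination of support $\lambda$, the bound is

$$
f(\lambda) = \prod_{j=1}^{K} f_j(\lambda), \qquad
f_j(\lambda) =
\begin{cases}
\binom{n_j}{\lambda} \big/ \binom{Y_j}{\lambda} & \lambda \le n_j \\[4pt]
1 \big/ \binom{Y_j}{n_j} & \lambda > n_j,
\end{cases}
$$

each factor being the probability of the most biased table achievable at
$t_j$ under the Fisher null. The printed second branch contains
$n_{1j}$, a pattern-dependent observed cell, inside what must be a
function of $\lambda$ alone; we implement it as $1/\binom{Y_j}{n_j}$,
the floor attained when all $n_j$ failures fall among carriers. That is
the unique reading that is constant in $\lambda$ for $\lambda > n_j$, as
the monotonicity argument ($f_j(\lambda + 1) =
\frac{n_j - \lambda}{Y_j - \lambda} f_j(\lambda)$ for $\lambda < n_j$)
requires, and it makes the two branches agree at $\lambda = n_j$.

Numerics: the product runs over up to hundreds of failure times and
underflows double precision, so factors are evaluated as log-gamma
differences and summed in log space; `bound_factor()` exposes single
factors as probabilities. Supports beyond $\max_j Y_j$ are clamped there
(the bound is constant beyond). Monotonicity and agreement with direct
rational arithmetic (all $Y_j \le 30$) are property-tested.

Validity caveat: the justification of $p \ge f(\lambda)$ leans on a
Fisher-method argument that is heuristic for small $K$, and it is
genuinely false in corner cases — with a single failure time,
$Y_1 = 4$, $n_1 = 2$, a support-2 combination attains the chi-square
p-value $0.083$ while $f(2) = 1/6$. The test suite therefore verifies
the bound *empirically*, by exhaustive enumeration over hundreds of
random instances with non-trivial $K$ (moderate censoring, $N \ge 15$),
rather than assuming it; in that regime no violation occurs because the
$K$-fold product is far smaller than any achievable p-value.

## The support-threshold search

Only closed combinations are enumerated and counted: a combination is
closed when adding any marker would shrink its carrier set, and every
frequent non-closed combination has the same carrier set — hence
identical tables and p-value — as exactly one closed representative.
This is the output an LCM-style miner produces, it is what the original
LAMP counts, and counting all frequent combinations instead would
inflate the correction factor $k$ without changing which carrier sets
get tested. The miner is an in-package depth-first prefix-preserving
closure extension (the LCM traversal); its equivalence with naive
powerset enumeration is a test, and the binarized matrix can be exported
in the standard transaction format (`export_transactions()`) for
cross-checking against external miners.

The search initializes $\lambda$ at the largest single-marker support
(equal, by anti-monotonicity, to the largest support of any combination),
clamped to $\max_j Y_j$ — the clamp affects efficiency only, never the
result, because $f$ is constant beyond it. Then, with $k(\lambda)$ the
closed-combination count at support $\ge \lambda$: while $\lambda > 2$
and $f(\lambda - 1) \le \alpha / k(\lambda)$, decrement $\lambda$ and
re-mine. The printed loop condition appears once with $\le$ and once
with $<$; we decrement on $\le$, which matches the original LAMP
semantics, and validate the whole search against a brute-force scan over
every threshold on small instances. On return, `lambda_star`, $k$, and
$\delta = \alpha/k$ are fixed; a combination is significant when its raw
log-rank p-value is at most $\delta$, and reported adjusted p-values are
$\min(1, p \cdot k)$. Re-mining at every $\lambda$ (rather than a
single-pass miner) is deliberate: it is the procedure as described, and
at package scale the mining is not the bottleneck.

## Chunked execution

For wide panels the markers are split into consecutive chunks
(`chunk_size = 250` by default, in input order), each chunk analysed
independently, and the per-chunk correction factors summed into a total
$k$. A combination is finally reported significant when
$\text{raw } p \times \text{total } k < \alpha$ (strict), and adjusted
p-values are recomputed with the total. Two consequences are worth
stating plainly: combinations spanning chunks are unreachable by
construction, so results are sensitive to chunk boundaries; and the
two-stage filter is conservative — a chunk-level candidate can fail the
total-$k$ filter (e.g. raw $p = 0.004$ with $k_i = 10$ passes its chunk
at $0.005$, but at total $k = 20$ gives $0.08 \ge 0.05$). We do not
re-run the per-chunk threshold search with knowledge of the total
factor; the aggregation is exactly the two-stage protocol, kept for
fidelity even though a global search would be less conservative.

## The synthetic generator

`simulation_spec()` + `generate_dataset()` produce datasets with the
structure the method assumes, not a replica of real expression data:

* Carriage is i.i.d. Bernoulli per marker and sample. Default carrier
  probability 21/500 = 0.042, the shape of z-score-binarized tumour
  expression panels (about 21 "highly expressed" samples per gene in a
  ~500-sample cohort). No co-expression or correlation structure is
  emulated, so passing tests say nothing about correlated-marker
  behaviour on real data.
* Event times are exponential, censoring independent exponential — the
  simplest pair satisfying the log-rank assumption that censoring is
  uninformative. Defaults: baseline hazard 0.02/month (median survival
  ≈ 35 months, a plausible oncology scale) and censoring rate
  $0.02 \cdot 3/7$, which censors ≈ 30% of samples. Weibull or other
  shapes can be layered on by replacing the generator, not by flags.
* A planted combination multiplies the hazard *conjunctively*: only
  samples carrying every planted marker are affected. This is exactly
  the individually-weak, jointly-strong scenario the method targets, and
  it is what the power tests recover.
* Times are continuous, so ties have probability zero; a
  `time_granularity` option rounds times up onto a grid to create ties
  deliberately, and tied data are unit-tested separately.

`estimate_fwer()` runs the complete pipeline on fresh null datasets
(replicate $i$ uses seed `base_seed + i - 1`) and reports the fraction
with at least one significant combination, with a Wilson 95% interval.

## What the desk-scale calibration shows

The test suite and the acceptance script estimate the null FWER at a
deliberately small scale: $N = 50$ samples, $M = 15$ markers, carrier
probability 0.2, $\alpha = 0.05$, 1000 replicates. The estimate is *far
above* $\alpha$ (about 0.6), and we report it rather than hide it,
because it is a property of the procedure, not an implementation fault
(the statistic agrees with `survival::survdiff` to machine precision).
Two effects compound:

1. With tens of failure times the $K$-fold product bound is vacuously
   small, so the threshold search always descends to $\lambda^* = 2$ and
   admits support-2 and support-3 combinations as testable.
2. The $\chi^2_1$ tail is a poor approximation for the log-rank test at
   such supports: measured on null data, a fixed support-2 group attains
   $p \le 5.3 \times 10^{-4}$ about 2.4% of the time — nearly 50-fold
   anti-conservative. Bonferroni at $\alpha/k$ assumes valid p-values,
   so the FWER guarantee does not survive the approximation error.

The guarantee is an assertion about *exact* p-values; at cohort sizes
and supports where the chi-square approximation is adequate (hundreds of
samples, supports in the tens), the pruning logic and the correction
behave as intended. Practically: treat support-2/3 hits at small $N$
with suspicion, or pre-filter to a minimum support your cohort can
calibrate. A tighter bound and an exact small-sample log-rank tail are
the two obvious improvements; both are out of scope here.

## Problem sizes used by the checks

Chosen as the package's own testing budget: bound validity by exhaustive
powerset enumeration on 200 random instances with $N \le 40$,
$M \le 10$; threshold-search equivalence against brute force on 60 such
instances; log-rank agreement with the reference implementation on 100
random datasets (relative error $\le 10^{-10}$); monotonicity on ~150
random risk structures across all supports; null FWER on 1000
replicates at the desk scale above; planted-recovery power (3-marker
conjunction, hazard ratio 8, $N = 200$, carrier probability 0.3) on 50
seeded replicates.

## Known limitations

* Exhaustiveness holds within chunks only.
* The bound is loose ("relaxed"): $\lambda^*$ descends further than an
  exact-test analysis would need, inflating $k$ and runtime.
* No stratified or weighted log-rank variants, no Cox adjustment, no
  FDR alternative; the correction is FWER by design.
* The miner materializes every testable closed combination; extremely
  dense matrices (carrier probability far above the defaults at large
  $M$) will be slow.

## A worked example

```{r example}
spec <- simulation_spec(
  n_samples = 200, n_markers = 10, carrier_prob = 0.3,
  planted_markers = 1:3, hazard_ratio = 8, seed = 70001
)
ds <- generate_dataset(spec)
ds

report <- run_chunked(ds, alpha = 0.05)
glance(report)
head(tidy(report))
```

The planted triple `m01,m02,m03` (or a closed superset with the same
carriers) should appear among the significant rows, with its raw p-value
orders of magnitude below the per-combination threshold.
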