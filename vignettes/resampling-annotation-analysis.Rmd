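---
title: "Resampling significance analysis of annotation terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling significance analysis of annotation terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resanno)
```

## The question the method answers

Large-scale proteomics and transcriptomics experiments attach one number to
each gene or protein group: a log fold-change, a stable-isotope incorporation
rate, an intensity. Annotation resources (KEGG pathways, Gene Ontology terms,
Pfam families, or any custom classification) group those rows into terms, and
the scientific question is whether the values of a term's members are
*collectively unusual* — shifted up or down, unusually homogeneous, unusually
dispersed — relative to the dataset they came from.

Classical enrichment tools answer a different question: they require the user
to cut the dataset into a "regulated" target set and a background, and then
test term membership against that cutoff. The cutoff is arbitrary, discards
the actual values, and hides the shape of each term's distribution. The
approach implemented here avoids the cutoff entirely:

1. Collect the `m` experimental values carried by a term.
2. Compute an estimator statistic `e_s` of that sample.
3. Draw `R` random samples of size `m` **with replacement** from all `n`
   dataset values and compute the same estimator for each, giving the
   empirical resampling distribution (RD).
4. Locate `e_s` in the sorted RD; its interpolated relative rank approximates
   the probability of an equally or more extreme value by chance.
5. Optionally refine p-values that fall into the extreme tails with a
   generalized Pareto fit to the RD's outer 2%.

Because the null is resampled from the observed values themselves, the method
makes no distributional assumption, and any row-level value — ratios,
incorporation rates, intensities — can be tested directly.

## Estimators

The choice of estimator selects the alternative being probed:

| name            | statistic                              | detects                          |
|-----------------|----------------------------------------|----------------------------------|
| `mean`          | arithmetic mean                        | location shift                   |
| `mean_deviation`| sample mean − dataset mean (signed)    | location shift, centered         |
| `mean_over_sd`  | mean / SD (t-statistic-like)           | shift supported by low spread    |
| `sd`            | sample SD (m−1 denominator)            | homogeneity / heterogeneity      |
| `cv`            | SD / mean                              | relative spread                  |
| `p10_p90_width` | 90th − 10th percentile                 | spread, robust to outliers       |

`mean_over_sd` rewards a shifted mean that comes with a tight spread, which
is the natural screen for terms whose members are co-regulated.
`p10_p90_width` asks the same homogeneity question as `sd` but a single
outlier member cannot dominate it — replacing the maximum of a 100-point
sample by ten times its value moves `p10_p90_width` far less than it moves
the SD (this is asserted as a test).

Ratio estimators degenerate when their denominator vanishes (`cv` with mean
zero, `mean_over_sd` with zero spread). A degenerate term is excluded and
reported in the skipped-terms output rather than tested; the identical rule
applies *inside* RD construction, where a degenerate resample is redrawn (at
most 100 consecutive rounds, after which the whole RD for that sample size is
declared untestable). Handling both sides identically keeps the RD an honest
null for the statistic actually computed.

`mean_deviation` is *signed*; the default two-sided test covers both
directions. Percentiles everywhere (estimators, seven-figure summaries) use
linear interpolation between order statistics with plotting position
`(k−1)/(m−1)` — one convention, centralized in a single internal helper so it
could be swapped in one place.

## Ranks, tails, and the p-value floor

With `R` resamplings the raw empirical p-value has resolution `1/R`, and an
`e_s` beyond the RD extremes would naively get p = 0. Two refinements address
this:

* **Interpolated ranks.** Order statistic `i` of the RD is assigned the
  Hazen plotting position `(i − 0.5)/R`; probes between order statistics are
  linearly interpolated, tied runs take the midpoint of their positions, and
  probes beyond the extremes clamp to `0.5/R` and `1 − 0.5/R`. Ranks are
  therefore always strictly inside (0, 1), and so are p-values. The clamp
  also makes the minimum attainable one-sided p exactly `0.5/R`, which is
  why `R` directly states the p-value resolution.
* **Generalized Pareto tails.** Extreme-value theory says exceedances over a
  high threshold approach a GPD. Each RD tail's outer 2% (`round(0.02·R)`
  values, so at least 10 at the minimum `R = 500`) is treated as exceedances
  over the adjacent order statistic and fitted by maximum likelihood
  (Nelder–Mead on shape and log-scale, method-of-moments start values, 200
  iterations; the lower tail is fitted after negation). Beyond the threshold
  the tail probability becomes `0.02 · (1 − F_GPD(excess))`, resolving
  p-values far below `1/R`. Inside the body the interpolated empirical rank
  is always used, and the two expressions agree at the threshold to within
  `0.5/R` by construction. A fit that fails to converge or returns a
  non-positive scale simply falls back to the clamped empirical rank.

Two-sidedness: the p-value is `min(1, 2·min(lower rank, upper rank))`;
one-sided modes are exposed by a flag. The default is two-sided because both
significantly high and significantly low terms are of interest.

A deliberate speed optimization: terms of equal size `m` share one cached RD
per estimator (the resampled null depends only on `m`, the estimator, and
the value pool). The consequence — p-values of same-size terms are ranked
against the same realization and are not independent across terms — is
accepted, and the permutation FDR below inherits the same dependence, which
is exactly why it is estimated by permutation rather than by a formula that
assumes independence. RD random streams are derived deterministically from
the top-level seed and the cache key, so results do not depend on term
iteration order; this is also what guarantees that raising the minimum term
size never changes the p-value of a surviving term.

## Empirical FDR by rank ratio

The null (H0) p-value pool is built by permuting the value column against the
fixed row/annotation structure and re-running the entire p-value machinery on
every permutation. Permutation preserves which rows share terms, so
between-term dependence carries into the null. The number of permutations is
`ceiling(1000 / n_terms)` — the pool is the smallest multiple of the testable
term count that reaches 1000 p-values. ("A multiple of the term count" is the
only reading that tiles the pool: each permutation contributes exactly one
p-value per term.) Since permuting values does not change the value multiset,
the observed analysis' cached RDs are reused unchanged for every permutation,
which makes the FDR phase cheap.

Each observed p-value's rank in the null pool (`rpH0`, ties counted at or
below) is divided by its rank among the observed p-values (`rpH1`, maximal
rank among ties — the conservative choice), after normalizing both by their
list lengths. Two post-processing steps are additions of this implementation,
both exposed by flags: the raw ratio is clipped to [0, 1], and a running
minimum from the largest p downward makes the FDR monotone non-decreasing in
p, so thresholding at a target FDR is well-defined. A term whose estimator
degenerates on a permuted dataset would break the pool-size invariant if
dropped; it contributes a conservative null p of 1 instead (with continuous
values this does not occur in practice).

## Tunable parameters

| parameter     | default | meaning and rationale                                   |
|---------------|---------|---------------------------------------------------------|
| `resamplings` | 1000    | R, in [500, 10000]; resolution of p is `0.5/R` one-sided; cost is linear in R. 1000 balances resolution and time |
| `min_size`    | 5       | minimum term size m; purely a cutoff for small samples — no effect on larger terms |
| `estimator`   | `sd`    | see table above; choose by the alternative of interest  |
| `sidedness`   | two-sided | both directions by default                            |
| `gpd`         | on      | tail refinement; off gives the pure clamped rank        |
| `tail_fraction` | 0.02  | RD fraction fitted per tail; must leave ≥ 10 exceedances |
| `min_null_pvalues` | 1000 | floor of the permutation pool size                   |
| `seed`        | 1       | one top-level seed; all streams derive from it, so a run is exactly reproducible |

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces datasets with the statistical structure the
method operates on: one value per row (standard normal by default; a
logit-normal preset keeps values in (0, 1) like isotope incorporation rates
H/(H+L); uniform for completeness), identifier columns, and one or more
annotation types whose terms are assigned to uniformly random row sets — so
terms overlap on rows the way GO terms do, which is precisely what exercises
RD reuse and the dependence-preserving FDR. Spiked terms redraw their member
values with a shifted mean (in population-SD units) or a scaled spread
(useful as a "tight pathway" analogue), and the generator returns the ground
truth alongside the data. Defaults (2000 rows, 100 terms of size 10) are the
study conditions used throughout the test suite.

What the generator does **not** emulate: real annotation structure is
hierarchical and far from uniformly random (GO terms nest; pathway sizes are
heavy-tailed), real value distributions are skewed mixtures with missing
data, and real effects come in continua rather than point spikes. Passing
tests therefore demonstrate the statistical machinery is correct and
calibrated under controlled conditions, not that any particular biological
dataset will show effects.

Test-suite problem sizes were chosen so that each property is measured with
adequate replication while the whole suite stays quick: calibration and FDR
checks use 20 generated datasets of 2000 rows each at R = 1000; the
stability experiment uses triplicate analyses at R = 500/1000/5000.

## The replicate-stability experiment

The suite re-creates, at synthetic scale, the classic stability analysis:
run the same dataset in triplicate at several resampling depths and measure
(a) the 90th-percentile coefficient of variation of each term's p-value
across replicates, per depth, and (b) the overlap of the significant term
sets at R = 1000. One design point deserves explanation. A term whose
statistic lies many RD standard errors outside the RD support gets its
p-value by deep GPD extrapolation; such p-values are many orders of
magnitude below the significance threshold, so their *significance* is
perfectly stable, but their *numeric* replicate CV is dominated by tail-fit
noise and does not shrink with R. The CV surface must therefore be measured
on a broad term universe dominated by null and weakly regulated terms (whose
p-values sit in the range R can resolve), while the overlap surface needs a
term family dominated by strong, stably significant regulation. The
stability fixture consequently carries two annotation types analyzed in one
run — a 400-term universe with weak shifts (0.4–0.9 SD) and a compact
60-term "pathway" family with strong shifts (±1.5 SD) — mirroring how such
experiments look on real data, where CV histograms span all terms but
stability-of-significance is judged on the strongly regulated family.

```{r stability, eval = FALSE}
# the shape of the experiment (full version in tests/testthat)
weak <- data.frame(term = sprintf("T%03d", 1:120), effect = "mean_shift",
                   value = rep(c(0.65, -0.65), 60))      # 0.4..0.9 in tests
strong <- data.frame(term = sprintf("T%03d", 1:30), effect = "mean_shift",
                     value = rep(c(1.5, -1.5), 15))
spec <- fixture_spec(n_terms = 400L, term_size = c(5L, 15L), spikes = weak,
                     extra_types = list(Pathway = list(
                       n_terms = 60L, term_size = c(8L, 15L),
                       spikes = strong)))
fx <- generate_dataset(spec, seed = 1)
# triplicate analyses at R = 500, 1000, 5000 differing only in the analysis
# seed: the 90th-percentile replicate CV of p decreases with R, and the
# pathway terms significant at R = 1000 overlap >= 97% across replicates
```

## Numerical choices and degenerate inputs

* **Percentile convention**: linear interpolation, plotting position
  `(k−1)/(m−1)`, everywhere.
* **Rank ties** in the RD (common for small discrete value sets): midpoint
  of the tied run's plotting positions, making the rank a symmetric function
  of the data.
* **GPD fit failure** (non-convergence, non-positive scale, degenerate
  exceedances): recorded as `converged = FALSE`; p-values fall back to the
  clamped empirical rank. The GPD tail probability is floored at 1e-300 so
  p > 0 always holds even under a negative fitted shape whose support ends
  before the probe.
* **Constant resample detection** is exact (column-wise equality), not
  tolerance-based, so the vectorized resampling path degenerates exactly
  where the scalar estimator does.
* **Duplicate terms within one cell** (`T;T`) collapse at parse time — a row
  contributes one membership per term, since double-counting would bias `m`.
* **Identifier matching** for GO annotation: case-sensitive for accessions,
  case-insensitive for gene symbols (symbol casing varies between sources;
  accession case is meaningful).
* **Missing or non-numeric value cells are hard errors** naming the line
  number; the value column is mandatory and imputation is out of scope.

## Known limitations

* Same-size terms share an RD realization; their p-values co-fluctuate.
  This is the documented trade of the caching design, and the permutation
  FDR is built to tolerate it, but p-values of equal-size terms should not
  be treated as independent evidence.
* The GPD refinement extrapolates; p-values many orders of magnitude below
  `1/R` are order-of-magnitude statements, not precise probabilities.
* The FDR estimator is empirical with a pool of ~1000 null p-values; FDR
  values below ~0.001 are resolution-limited by the pool size.
* GO slim mapping requires a precomputed slim map file; ontology graph
  traversal is out of scope, as are fetching annotation releases and any
  non-TSV input format.
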