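# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test:
# ranks are computed by counting, percentiles by the plotting-position
# formula written out directly, and GPD samples by inverse-CDF.

# Count-and-interpolate relative rank: order statistic i has plotting
# position (i - 0.5) / R; ties take the midpoint of their run; probes
# between distinct values are linearly interpolated; probes beyond the
# extremes clamp to 0.5/R and 1 - 0.5/R.
oracle_relative_rank <- function(stats, e) {
  s <- sort(stats)
  R <- length(s)
  run_pos <- function(v) {
    # midpoint plotting position of the run of values equal to v
    (sum(s < v) + sum(s == v) / 2) / R
  }
  n_eq <- sum(s == e)
  if (n_eq > 0) return(run_pos(e))
  if (e < s[1]) return(0.5 / R)
  if (e > s[R]) return(1 - 0.5 / R)
  a <- max(s[s < e])
  b <- min(s[s > e])
  pa <- run_pos(a)
  pb <- run_pos(b)
  pa + (e - a) / (b - a) * (pb - pa)
}

# Percentile by direct plotting-position arithmetic, h = (m - 1) p + 1.
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  m <- length(xs)
  h <- (m - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, m)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Inverse-CDF sampler for the generalized Pareto distribution.
roracle_gpd <- function(n, shape, scale) {
  u <- runif(n)
  if (abs(shape) < 1e-12) {
    -scale * log(1 - u)
  } else {
    scale / shape * ((1 - u)^(-shape) - 1)
  }
}

# Minimal RD wrapper so rank/p-value functions can be probed against
# hand-picked sorted statistics.
make_rd <- function(stats, m = 5L, estimator = "sd") {
  structure(
    list(sorted_stats = sort(stats), m = m, R = length(stats),
         estimator = estimator, seed = NA_integer_,
         population_mean = NA_real_),
    class = "resa_rd")
}

# Distinct small seeds per (repetition, label) pair for test loops.
derive_test_seed <- function(seed, label) {
  seed * 131L + sum(utf8ToInt(label)) %% 1000L
}

# GO-term lookup for a single identifier (shorthand over the internal).
lookup_ids <- function(mapping, id) resanno:::lookup_go(mapping, id)

# Small worked dataset in the tab-separated dialect (value, gene, KEGG, Pfam).
toy_lines <- function() {
  c("Ratio\tGene\tKEGG\tPfam",
    "0.55\tCtnnb1\thsa04310;hsa04390\tPF00514",
    "0.18\tLamc1\thsa04512\tPF00052;PF00053",
    "-0.20\tGsk3b\thsa04310\t",
    "0.07\tCsnk1a1\thsa04310\tPF00069",
    "1.30\tActb\t\tPF00022")
}

toy_dataset <- function() {
  parse_dataset(toy_lines(), n_annotation_cols = 2L, id_cols = 1L)
}

# Spiked study-condition presets shared between tests and examples:
# 2000 rows, 100 terms of size 10, 10 terms mean-shifted by 3 population SDs.
spiked_spec <- function() {
  fixture_spec(spikes = data.frame(term = sprintf("T%03d", 1:10),
                                   effect = "mean_shift", value = 3))
}

# Stability-analogue preset: one run over two annotation families, as the
# replicate-stability experiment requires. "SetA" is a broad term universe
# (400 terms, sizes 5-15, 120 carrying weak-to-moderate shifts of 0.4-0.9
# population SDs) whose p-values span the resolvable range - the surface on
# which replicate CVs are measured. "Pathway" is a compact family dominated
# by strong regulation (30 of 60 terms shifted by +/-1.5 SDs) - the surface
# on which significant-set overlap is measured.
stability_spec <- function() {
  weak_mag <- rep(seq(0.4, 0.9, length.out = 15), 8)
  weak <- data.frame(term = sprintf("T%03d", 1:120), effect = "mean_shift",
                     value = (as.vector(rbind(weak_mag, -weak_mag)))[1:120])
  strong <- data.frame(term = sprintf("T%03d", 1:30), effect = "mean_shift",
                       value = rep(c(1.5, -1.5), 15))
  fixture_spec(n_terms = 400L, term_size = c(5L, 15L), spikes = weak,
               extra_types = list(Pathway = list(n_terms = 60L,
                                                 term_size = c(8L, 15L),
                                                 spikes = strong)))
}
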