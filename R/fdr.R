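# Empirical false-discovery-rate estimation from permutation null p-values.
#
# The null (H0) distribution of p-values is generated by permuting the value
# column against the fixed row/annotation structure and re-running the whole
# p-value machinery on every permuted dataset. Because every term is
# re-tested on each permutation, between-term overlap (rows shared by
# several terms) is preserved in the null - the interdependence of the data
# carries over into the FDR estimate.

#' Generate the permutation null p-value pool
#'
#' Permutes the value column uniformly at random over rows, recomputes every
#' testable term's p-value with the same estimator, `R` and RD-caching scheme
#' as the observed analysis, and pools the results. The number of
#' permutations is `ceiling(min_null / n_terms)`, so the pool size is the
#' smallest multiple of the term count that is at least `min_null`
#' (default 1000). Permuting values does not change the value multiset, so
#' the RDs built for the observed analysis are reused unchanged for every
#' permutation.
#'
#' A term whose estimator degenerates on a permuted dataset (possible only
#' for ratio estimators on discrete values) contributes a conservative null
#' p of 1, keeping the pool size exact.
#'
#' @param dataset A [resa_dataset()].
#' @param term_samples Testable term samples ([build_term_samples()]), after
#'   removal of degenerate terms.
#' @param estimator,R,sidedness,gpd,tail_fraction Settings of the observed
#'   analysis.
#' @param base_seed Top-level analysis seed; permutation streams are derived
#'   from it deterministically.
#' @param min_null Minimum pool size (default 1000).
#' @param cache RD cache from [rd_cache()]; pass the observed analysis' cache
#'   to reuse its RDs.
#' @return An object of class `resa_null_pool`: sorted `p_null`,
#'   `n_permutations`, `per_permutation_count`.
#' @export
generate_null_pool <- function(dataset, term_samples,
                               estimator = estimator_kinds(), R = 1000L,
                               sidedness = "two_sided", gpd = TRUE,
                               tail_fraction = 0.02, base_seed = 1L,
                               min_null = 1000L, cache = rd_cache()) {
  estimator <- match.arg(estimator)
  n_terms <- length(term_samples)
  if (n_terms < 1L) config_error("need at least one testable term")
  n_perm <- as.integer(ceiling(min_null / n_terms))
  vals <- dataset$values
  pop_mean <- mean(vals)
  p_null <- numeric(n_perm * n_terms)
  idx <- 0L
  for (k in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(base_seed, 104729L, k),
                      sample.int(dataset$n))
    permuted <- vals[perm]
    for (ts in term_samples) {
      idx <- idx + 1L
      member_vals <- permuted[ts$member_rows]
      e_s <- estimate(member_vals, estimator, population_mean = pop_mean)
      if (is.na(e_s)) {
        p_null[idx] <- 1
        next
      }
      rd <- rd_cache_get_or_build(cache, vals, ts$m, R, estimator,
                                  base_seed = base_seed,
                                  population_mean = pop_mean, gpd = gpd,
                                  tail_fraction = tail_fraction)
      p_null[idx] <- p_value(rd, e_s, sidedness, gpd = gpd,
                             tail_fraction = tail_fraction)$p
    }
  }
  structure(
    list(p_null = sort(p_null), n_permutations = n_perm,
         per_permutation_count = n_terms),
    class = "resa_null_pool")
}

#' @export
print.resa_null_pool <- function(x, ...) {
  cat(sprintf("<resa_null_pool> %d null p-values (%d permutations x %d terms)\n",
              length(x$p_null), x$n_permutations, x$per_permutation_count))
  invisible(x)
}

#' Estimate empirical FDR by the rank-ratio method
#'
#' For each observed p-value, its rank in the null pool (`rpH0`, the number
#' of null p-values at or below it) is divided by its rank among the observed
#' p-values (`rpH1`, maximal rank among ties, which is conservative), each
#' normalized by its list length. The raw ratio is clipped to `[0, 1]` and,
#' by default, made monotone non-decreasing in p by a running minimum from
#' the largest p downward, so that thresholding on FDR is well-defined.
#'
#' @param p_observed Numeric vector of observed p-values.
#' @param pool A `resa_null_pool` from [generate_null_pool()].
#' @param monotone Apply the monotonicity pass (default `TRUE`).
#' @return A data frame with columns `p`, `rpH0`, `rpH1`, `fdr`, in the input
#'   order of `p_observed`.
#' @export
estimate_fdr <- function(p_observed, pool, monotone = TRUE) {
  stopifnot(inherits(pool, "resa_null_pool"))
  if (length(p_observed) < 1L) config_error("p_observed is empty")
  p_null <- pool$p_null
  n0 <- length(p_null)
  n1 <- length(p_observed)
  rpH0 <- findInterval(p_observed, p_null)  # #{null <= p}; p_null is sorted
  rpH1 <- rank(p_observed, ties.method = "max")
  fdr <- pmin(1, pmax(0, (rpH0 / n0) / (rpH1 / n1)))
  if (monotone) {
    ord <- order(p_observed, decreasing = TRUE)
    fdr[ord] <- cummin(fdr[ord])
  }
  data.frame(p = p_observed, rpH0 = rpH0, rpH1 = rpH1, fdr = fdr)
}
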