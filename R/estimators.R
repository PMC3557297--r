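# Estimator statistics evaluated on a term's sample and on every resample.

#' Names of the available estimator statistics
#'
#' * `sd` - sample standard deviation (denominator m - 1)
#' * `cv` - coefficient of variation, sd / mean
#' * `mean` - arithmetic mean
#' * `mean_over_sd` - mean / sd, related to the t-statistic: a shifted sample
#'   mean gains significance when paired with a low spread
#' * `mean_deviation` - signed deviation of the sample mean from the
#'   full-dataset mean
#' * `p10_p90_width` - width of the interval from the 10th to the 90th
#'   percentile, a non-parametric spread measure robust to outliers
#'
#' @return Character vector of estimator names.
#' @export
estimator_kinds <- function() {
  c("sd", "cv", "mean", "mean_over_sd", "mean_deviation", "p10_p90_width")
}

estimator_code <- function(kind) match(kind, estimator_kinds())

min_sample_size <- function(kind) {
  if (kind %in% c("mean", "mean_deviation")) 1L else 2L
}

#' Compute an estimator statistic of a sample
#'
#' Ratio estimators are degenerate when their denominator vanishes (`cv` with
#' mean 0, `mean_over_sd` with sd 0); the degenerate case is signaled by
#' returning `NA`, which excludes the term from testing rather than poisoning
#' the resampling distribution.
#'
#' @param values Numeric sample.
#' @param kind One of [estimator_kinds()].
#' @param population_mean Full-dataset mean; required for `mean_deviation`.
#' @return The estimator value, or `NA` for a degenerate ratio.
#' @export
estimate <- function(values, kind = estimator_kinds(),
                     population_mean = NULL) {
  kind <- match.arg(kind)
  m <- length(values)
  if (m < min_sample_size(kind)) {
    config_error(sprintf("estimator '%s' needs at least %d values, got %d",
                         kind, min_sample_size(kind), m))
  }
  switch(kind,
    sd = stats::sd(values),
    cv = {
      mu <- mean(values)
      if (mu == 0) NA_real_ else stats::sd(values) / mu
    },
    mean = mean(values),
    mean_over_sd = {
      s <- stats::sd(values)
      if (s == 0) NA_real_ else mean(values) / s
    },
    mean_deviation = {
      if (is.null(population_mean)) {
        config_error("mean_deviation requires population_mean")
      }
      mean(values) - population_mean
    },
    p10_p90_width = diff(pctl(values, c(0.1, 0.9)))
  )
}

# Vectorized estimator over the columns of an m x R resample matrix.
# Constant columns are detected exactly so that degenerate ratios signal NA
# just as the scalar path does.
estimate_columns <- function(X, kind, population_mean = NULL) {
  m <- nrow(X)
  mu <- colMeans(X)
  col_sd <- function() {
    ss <- colSums((X - rep(mu, each = m))^2)
    s <- sqrt(ss / (m - 1))
    const <- colSums(X == X[rep.int(1L, m), , drop = FALSE]) == m
    s[const] <- 0
    s
  }
  switch(kind,
    mean = mu,
    mean_deviation = mu - population_mean,
    sd = col_sd(),
    cv = {
      s <- col_sd()
      ifelse(mu == 0, NA_real_, s / mu)
    },
    mean_over_sd = {
      s <- col_sd()
      ifelse(s == 0, NA_real_, mu / s)
    },
    p10_p90_width = {
      Xs <- apply(X, 2L, sort)
      h <- (m - 1) * c(0.1, 0.9) + 1
      lo <- floor(h)
      hi <- pmin(lo + 1, m)
      q <- function(k) Xs[lo[k], ] + (h[k] - lo[k]) * (Xs[hi[k], ] - Xs[lo[k], ])
      q(2L) - q(1L)
    }
  )
}
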