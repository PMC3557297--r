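# Empirical resampling distributions, interpolated relative ranks, and
# generalized Pareto refinement of tail p-values.
#
# For a term of size m the null model is: draw m values with replacement from
# the complete dataset (the term's own values included), compute the
# estimator, repeat R times, sort. The relative rank of the observed
# statistic in this resampling distribution (RD) approximates the probability
# of an equally or more extreme value by chance.

RESAMPLINGS_RANGE <- c(500L, 10000L)

#' Build the empirical resampling distribution for one sample size
#'
#' Draws `R` independent samples of size `m` with replacement from all `n`
#' dataset values, applies the estimator to each, and stores the sorted
#' results. Deterministic given `seed`. A resample on which a ratio estimator
#' degenerates (e.g. zero spread for `mean_over_sd`) is redrawn; after 100
#' consecutive failed redraw rounds construction aborts with a diagnostic.
#'
#' @param all_values Numeric vector: the complete dataset's value column.
#' @param m Sample size (the term size whose null this RD represents).
#' @param R Number of resamplings, in `[500, 10000]`. The value of `R` sets
#'   the resolution of the empirical p-value directly.
#' @param estimator One of [estimator_kinds()].
#' @param seed Integer seed for this RD's random stream.
#' @param population_mean Full-dataset mean, used by `mean_deviation`.
#' @return An object of class `resa_rd` with fields `sorted_stats`, `m`, `R`,
#'   `estimator`, `seed`, `population_mean`.
#' @export
build_rd <- function(all_values, m, R, estimator = estimator_kinds(),
                     seed = 1L, population_mean = mean(all_values)) {
  estimator <- match.arg(estimator)
  if (R < RESAMPLINGS_RANGE[1] || R > RESAMPLINGS_RANGE[2]) {
    config_error(sprintf("R must be in [%d, %d], got %s",
                         RESAMPLINGS_RANGE[1], RESAMPLINGS_RANGE[2], R))
  }
  if (m < min_sample_size(estimator)) {
    config_error(sprintf("sample size m = %d too small for estimator '%s'",
                         m, estimator))
  }
  n <- length(all_values)
  stats_out <- with_seed(seed, {
    X <- matrix(all_values[sample.int(n, m * R, replace = TRUE)], nrow = m)
    st <- estimate_columns(X, estimator, population_mean)
    retries <- 0L
    while (anyNA(st)) {
      retries <- retries + 1L
      if (retries > 100L) {
        resa_error(sprintf(
          "RD construction failed for m = %d, estimator '%s': degenerate resamples persisted after 100 redraws",
          m, estimator), "resa_degenerate_rd")
      }
      bad <- which(is.na(st))
      Xb <- matrix(all_values[sample.int(n, m * length(bad), replace = TRUE)],
                   nrow = m)
      st[bad] <- estimate_columns(Xb, estimator, population_mean)
    }
    st
  })
  structure(
    list(sorted_stats = sort(stats_out), m = as.integer(m), R = as.integer(R),
         estimator = estimator, seed = seed, population_mean = population_mean),
    class = "resa_rd")
}

#' @export
print.resa_rd <- function(x, ...) {
  cat(sprintf("<resa_rd> estimator '%s', m = %d, R = %d%s\n", x$estimator,
              x$m, x$R, if (!is.null(x$gpd)) ", GPD tails fitted" else ""))
  invisible(x)
}

#' Interpolated relative rank of a statistic in a resampling distribution
#'
#' Order statistic i of the RD is assigned the plotting position
#' (i - 0.5) / R; a probe between two order statistics is linearly
#' interpolated, probes beyond the extremes are clamped to `0.5 / R` and
#' `1 - 0.5 / R`, and a probe tied with a run of equal RD values takes the
#' midpoint of the run's positions. The result is strictly inside (0, 1).
#'
#' @param rd A `resa_rd` object.
#' @param e_s Numeric vector of probe statistics.
#' @return Relative rank(s) in (0, 1).
#' @export
relative_rank <- function(rd, e_s) {
  s <- rd$sorted_stats
  R <- length(s)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- ((starts + ends) / 2 - 0.5) / R  # midpoint plotting positions
  u <- runs$values
  rr <- numeric(length(e_s))
  below <- e_s < s[1]
  above <- e_s > s[R]
  rr[below] <- 0.5 / R
  rr[above] <- 1 - 0.5 / R
  mid <- !below & !above
  if (any(mid)) {
    rr[mid] <- if (length(u) == 1L) {
      pos[1]
    } else {
      stats::approx(u, pos, xout = e_s[mid], ties = "ordered")$y
    }
  }
  rr
}

# ---- Generalized Pareto tail refinement --------------------------------

#' Generalized Pareto distribution function of exceedances
#'
#' CDF of the GPD with shape `xi` and scale `beta` evaluated at exceedance
#' `q >= 0` over the threshold. The shape-zero limit is exponential.
#'
#' @param q Exceedances (numeric vector).
#' @param shape,scale GPD shape (xi) and scale (beta > 0).
#' @return Probabilities in `[0, 1]`.
#' @export
pgpd <- function(q, shape, scale) {
  q <- pmax(q, 0)
  if (abs(shape) < 1e-9) {
    return(1 - exp(-q / scale))
  }
  w <- 1 + shape * q / scale
  if (shape < 0) w <- pmax(w, 0)  # beyond the finite endpoint: CDF = 1
  1 - w^(-1 / shape)
}

#' Fit a generalized Pareto distribution to exceedances by maximum likelihood
#'
#' Nelder-Mead optimization of the GPD log-likelihood, started from method-
#' of-moments estimates. The fit is declared failed (`converged = FALSE`) if
#' the optimizer does not converge within 200 iterations, the scale is not
#' positive, or the exceedances are degenerate; callers then fall back to the
#' clamped empirical rank.
#'
#' @param exceedances Non-negative excesses over the threshold; at least 10.
#' @return List with `shape`, `scale`, `n_exceedances`, `converged`.
#' @export
fit_gpd <- function(exceedances) {
  y <- as.numeric(exceedances)
  if (length(y) < 10L) {
    config_error(sprintf("GPD fit needs >= 10 exceedances, got %d", length(y)))
  }
  if (any(y < 0)) config_error("exceedances must be non-negative")
  n <- length(y)
  v <- stats::var(y)
  mu <- mean(y)
  if (!is.finite(v) || v <= 0 || mu <= 0) {
    return(list(shape = 0, scale = NA_real_, n_exceedances = n,
                converged = FALSE))
  }
  # method-of-moments start: mean^2/var = 1 - 2*xi, beta = mean*(1 - xi)
  xi0 <- 0.5 * (1 - mu^2 / v)
  if (xi0 >= 0.5) xi0 <- 0.4
  beta0 <- mu * (1 - xi0)
  if (beta0 <= 0) beta0 <- mu

  nll <- function(par) {
    xi <- par[1]
    beta <- exp(par[2])
    z <- y / beta
    if (abs(xi) < 1e-8) {
      return(n * par[2] + sum(z))
    }
    w <- 1 + xi * z
    if (any(w <= 0)) return(1e10)
    n * par[2] + (1 + 1 / xi) * sum(log(w))
  }
  opt <- tryCatch(
    stats::optim(c(xi0, log(beta0)), nll, method = "Nelder-Mead",
                 control = list(maxit = 200L)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value)) {
    return(list(shape = xi0, scale = beta0, n_exceedances = n,
                converged = FALSE))
  }
  scale <- exp(opt$par[2])
  list(shape = opt$par[1], scale = scale, n_exceedances = n,
       converged = is.finite(scale) && scale > 0)
}

#' Fit a GPD to one 2% tail of a resampling distribution
#'
#' Takes the `round(tail_fraction * R)` most extreme RD values as exceedances
#' over the adjacent order statistic (the empirical tail quantile) and fits a
#' GPD by maximum likelihood. The lower tail is handled by negation: the fit
#' is applied to `u - x` for RD values `x` below the threshold `u`.
#'
#' @param rd A `resa_rd` object.
#' @param tail `"lower"` or `"upper"`.
#' @param tail_fraction Fraction of the RD treated as tail, in `(0, 0.1]`
#'   (default 0.02); must leave at least 10 exceedances.
#' @return An object of class `resa_gpd_fit` with fields `tail`, `threshold`,
#'   `shape`, `scale`, `n_exceedances`, `converged`, `tail_fraction`.
#' @export
fit_gpd_tail <- function(rd, tail = c("upper", "lower"), tail_fraction = 0.02) {
  tail <- match.arg(tail)
  if (tail_fraction <= 0 || tail_fraction > 0.1) {
    config_error("tail_fraction must be in (0, 0.1]")
  }
  s <- rd$sorted_stats
  R <- length(s)
  k <- round(tail_fraction * R)
  if (k < 10L) {
    config_error(sprintf(
      "tail fraction %.3g of R = %d leaves only %d exceedances (>= 10 needed)",
      tail_fraction, R, k))
  }
  if (tail == "upper") {
    u <- s[R - k]
    y <- s[(R - k + 1L):R] - u
  } else {
    u <- s[k + 1L]
    y <- u - s[1:k]
  }
  fit <- fit_gpd(y)
  structure(
    list(tail = tail, threshold = u, shape = fit$shape, scale = fit$scale,
         n_exceedances = fit$n_exceedances, converged = fit$converged,
         tail_fraction = tail_fraction),
    class = "resa_gpd_fit")
}

# Fit both tails once and attach them to the RD so repeated p-value calls
# against a cached RD do not refit.
attach_gpd_tails <- function(rd, tail_fraction = 0.02) {
  if (!is.null(rd$gpd) && identical(rd$gpd$tail_fraction, tail_fraction)) {
    return(rd)
  }
  rd$gpd <- list(
    lower = fit_gpd_tail(rd, "lower", tail_fraction),
    upper = fit_gpd_tail(rd, "upper", tail_fraction),
    tail_fraction = tail_fraction)
  rd
}

# Tail probability beyond a converged GPD fit, floored to stay positive.
gpd_tail_prob <- function(fit, e_s) {
  excess <- if (fit$tail == "upper") e_s - fit$threshold else fit$threshold - e_s
  p <- fit$tail_fraction * (1 - pgpd(excess, fit$shape, fit$scale))
  max(p, 1e-300)
}

#' Empirical p-value of a term's statistic, optionally GPD-refined
#'
#' The two tail relative ranks come from [relative_rank()]; the one-sided
#' p-value is the requested tail's rank and the two-sided p-value is
#' `min(1, 2 * min(lower, upper))`. When `gpd = TRUE` and the statistic lies
#' beyond the 2% empirical tail quantile and that tail's GPD fit converged,
#' the tail probability is `tail_fraction * (1 - F_GPD(excess))` instead of
#' the clamped empirical rank, resolving p-values far below `1 / R` while
#' keeping them strictly positive.
#'
#' @param rd A `resa_rd` object.
#' @param e_s Observed estimator statistic.
#' @param sidedness `"two_sided"`, `"lower"` or `"upper"`.
#' @param gpd Use generalized Pareto tail refinement (default `TRUE`).
#' @param tail_fraction Tail fraction for the GPD fits (default 0.02).
#' @return An object of class `resa_pvalue`: list with `p`, `lower_tail_rr`,
#'   `upper_tail_rr` and `method` (one of `empirical_interpolated`,
#'   `gpd_lower`, `gpd_upper`).
#' @export
p_value <- function(rd, e_s, sidedness = c("two_sided", "lower", "upper"),
                    gpd = TRUE, tail_fraction = 0.02) {
  sidedness <- match.arg(sidedness)
  lower_rr <- relative_rank(rd, e_s)
  upper_rr <- 1 - lower_rr
  method <- "empirical_interpolated"
  if (gpd) {
    rd <- attach_gpd_tails(rd, tail_fraction)
    lo <- rd$gpd$lower
    up <- rd$gpd$upper
    if (lo$converged && e_s < lo$threshold) {
      lower_rr <- gpd_tail_prob(lo, e_s)
      method <- "gpd_lower"
    }
    if (up$converged && e_s > up$threshold) {
      upper_rr <- gpd_tail_prob(up, e_s)
      method <- "gpd_upper"
    }
  }
  p <- switch(sidedness,
    lower = lower_rr,
    upper = upper_rr,
    two_sided = min(1, 2 * min(lower_rr, upper_rr)))
  if (sidedness == "two_sided" &&
      method != "empirical_interpolated" &&
      min(lower_rr, upper_rr) ==
        (if (method == "gpd_lower") upper_rr else lower_rr)) {
    # the GPD-refined tail was not the one that set the p-value
    method <- "empirical_interpolated"
  }
  structure(list(p = p, lower_tail_rr = lower_rr, upper_tail_rr = upper_rr,
                 method = method),
            class = "resa_pvalue")
}

# ---- RD cache -----------------------------------------------------------

#' Create an empty resampling-distribution cache
#'
#' Within one analysis run, terms of equal size `m` share a single RD (the
#' value pool and estimator are the same), which is the main speed
#' optimization of the method. A documented consequence: p-values of
#' same-size terms are ranked against the same RD and are therefore not
#' independent across terms.
#'
#' @return An environment used as cache by [rd_cache_get_or_build()].
#' @export
rd_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$n_built <- 0L
  e$n_reused <- 0L
  e
}

#' Fetch an RD from the cache, building it on first request
#'
#' Cache keys are `(m, R, estimator)`. The RD's random stream is derived
#' deterministically from `base_seed` and the key, so RD content does not
#' depend on the order in which terms are processed.
#'
#' @param cache Environment from [rd_cache()].
#' @param all_values,m,R,estimator,population_mean As in [build_rd()].
#' @param base_seed Top-level analysis seed.
#' @param gpd If `TRUE`, GPD tails are fitted once and stored with the RD.
#' @param tail_fraction Tail fraction for the GPD fits.
#' @return A `resa_rd`, identical across calls with equal keys.
#' @export
rd_cache_get_or_build <- function(cache, all_values, m, R, estimator,
                                  base_seed = 1L,
                                  population_mean = mean(all_values),
                                  gpd = TRUE, tail_fraction = 0.02) {
  key <- paste("rd", m, R, estimator, sep = ":")
  if (!is.null(cache[[key]])) {
    cache$n_reused <- cache$n_reused + 1L
    return(cache[[key]])
  }
  seed <- derive_seed(base_seed, m, estimator_code(estimator))
  rd <- build_rd(all_values, m, R, estimator, seed = seed,
                 population_mean = population_mean)
  if (gpd) rd <- attach_gpd_tails(rd, tail_fraction)
  cache[[key]] <- rd
  cache$n_built <- cache$n_built + 1L
  rd
}
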