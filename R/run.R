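# Pipeline orchestration: parse -> (optional GO annotation) -> term building
# -> resampling p-values with GPD refinement -> permutation FDR -> results.

#' Assemble and validate an analysis configuration
#'
#' @param input Path to a tab-separated dataset file (or character vector of
#'   lines); alternatively pass a parsed `dataset`.
#' @param dataset A [resa_dataset()], used instead of `input` when given.
#' @param annotation_cols Number of trailing annotation columns in `input`.
#' @param id_cols Number of identifier columns in `input`.
#' @param has_header Whether `input` has a header line.
#' @param estimator One of [estimator_kinds()] (default `"sd"`).
#' @param resamplings Number of resamplings R, in `[500, 10000]`; the default
#'   of 1000 is a compromise between accuracy and running time.
#' @param min_size Minimum term size m (default 5). Acts purely as a cutoff
#'   for small samples; it has no effect on terms larger than m.
#' @param sidedness `"two_sided"` (default), `"lower"` or `"upper"`.
#' @param gpd Refine tail p-values with generalized Pareto fits (default on).
#' @param tail_fraction Fraction of each RD tail used for the GPD fit.
#' @param fdr Estimate empirical FDRs from permutations (default on).
#' @param min_null_pvalues Minimum size of the permutation null pool.
#' @param fdr_monotone Apply the FDR monotonicity pass (default on).
#' @param gaf Optional path to a GAF 2.x file for GO annotation.
#' @param evidence_mode `"full"` or `"experimental"` GAF evidence filtering.
#' @param slim Optional path to a two-column slim-mapping TSV.
#' @param go_column Title of the GO annotation column added from the GAF.
#' @param seed Top-level RNG seed; all random streams derive from it, so
#'   identical configurations reproduce identical results.
#' @param out_dir If non-`NULL`, result TSVs are written there.
#' @param verbose Emit progress messages.
#' @return An object of class `resa_config`.
#' @export
run_config <- function(input = NULL, dataset = NULL, annotation_cols = NULL,
                       id_cols = 0L, has_header = TRUE,
                       estimator = "sd", resamplings = 1000L, min_size = 5L,
                       sidedness = "two_sided", gpd = TRUE,
                       tail_fraction = 0.02, fdr = TRUE,
                       min_null_pvalues = 1000L, fdr_monotone = TRUE,
                       gaf = NULL, evidence_mode = "full", slim = NULL,
                       go_column = "GO", seed = 1L, out_dir = NULL,
                       verbose = FALSE) {
  if (is.null(input) && is.null(dataset)) {
    config_error("either 'input' or 'dataset' must be given")
  }
  if (!is.null(dataset) && !inherits(dataset, "resa_dataset")) {
    config_error("'dataset' must be a resa_dataset")
  }
  if (is.null(dataset) && is.null(annotation_cols) && is.null(gaf)) {
    config_error("'annotation_cols' is required when parsing an input file")
  }
  if (!estimator %in% estimator_kinds()) {
    config_error(sprintf("unknown estimator '%s'", estimator))
  }
  if (resamplings < RESAMPLINGS_RANGE[1] ||
      resamplings > RESAMPLINGS_RANGE[2]) {
    config_error(sprintf("resamplings must be in [%d, %d], got %s",
                         RESAMPLINGS_RANGE[1], RESAMPLINGS_RANGE[2],
                         resamplings))
  }
  if (min_size < 1L) config_error("min_size must be >= 1")
  if (!sidedness %in% c("two_sided", "lower", "upper")) {
    config_error(sprintf("unknown sidedness '%s'", sidedness))
  }
  if (!evidence_mode %in% c("full", "experimental")) {
    config_error(sprintf("unknown evidence_mode '%s'", evidence_mode))
  }
  if (min_null_pvalues < 1L) config_error("min_null_pvalues must be >= 1")
  structure(
    list(input = input, dataset = dataset,
         annotation_cols = annotation_cols %||% 0L,
         id_cols = as.integer(id_cols), has_header = has_header,
         estimator = estimator, resamplings = as.integer(resamplings),
         min_size = as.integer(min_size), sidedness = sidedness,
         gpd = gpd, tail_fraction = tail_fraction, fdr = fdr,
         min_null_pvalues = as.integer(min_null_pvalues),
         fdr_monotone = fdr_monotone, gaf = gaf,
         evidence_mode = evidence_mode, slim = slim, go_column = go_column,
         seed = as.integer(seed), out_dir = out_dir, verbose = verbose),
    class = "resa_config")
}

log_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Run the full resampling analysis
#'
#' Executes the pipeline on every annotation type of the dataset in a single
#' run: per-term estimator statistics, empirical resampling p-values with
#' optional GPD tail refinement (terms of equal size share one cached RD),
#' and permutation-based empirical FDRs. Results are returned and, when
#' `out_dir` is set, written as TSV files by [write_results()]. All outputs
#' are deterministic for a fixed seed and inputs.
#'
#' @param config A [run_config()].
#' @return An object of class `resa_results`: `terms` (per-term data frame
#'   with statistics, seven-figure summary, p and FDR), `members` (per-term
#'   member rows), `skipped` (excluded terms with reasons), `null_pool`
#'   (when FDR was estimated) and `log` (counters: rows parsed, terms per
#'   type, RDs built/reused, permutations).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "resa_config"))
  t0 <- proc.time()[["elapsed"]]

  dataset <- config$dataset %||%
    parse_dataset(config$input, config$annotation_cols,
                  id_cols = config$id_cols, has_header = config$has_header)
  log_msg(config, "parsed %d rows, %d annotation type(s)", dataset$n,
          length(dataset$annotation_types))

  if (!is.null(config$gaf)) {
    slim_map <- if (!is.null(config$slim)) read_slim_map(config$slim)
    mapping <- read_gaf(config$gaf, config$evidence_mode, slim_map = slim_map)
    dataset <- annotate_go(dataset, mapping, config$go_column)
    log_msg(config, "GO annotation added (%d usable GAF records)",
            mapping$n_records)
  }

  samples <- build_term_samples(dataset, config$min_size)
  vals <- dataset$values
  pop_mean <- mean(vals)
  cache <- rd_cache()

  skipped <- list()
  kept <- list()
  pvals <- list()
  for (ts in samples) {
    e_s <- estimate(ts$values, config$estimator, population_mean = pop_mean)
    if (is.na(e_s)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        annotation_type = ts$annotation_type, term = ts$term, m = ts$m,
        reason = "degenerate estimator value")
      next
    }
    rd <- tryCatch(
      rd_cache_get_or_build(cache, vals, ts$m, config$resamplings,
                            config$estimator, base_seed = config$seed,
                            population_mean = pop_mean, gpd = config$gpd,
                            tail_fraction = config$tail_fraction),
      resa_degenerate_rd = function(e) NULL)
    if (is.null(rd)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        annotation_type = ts$annotation_type, term = ts$term, m = ts$m,
        reason = "resampling distribution degenerate for this sample size")
      next
    }
    pv <- p_value(rd, e_s, config$sidedness, gpd = config$gpd,
                  tail_fraction = config$tail_fraction)
    ts$e_s <- e_s
    ts$pv <- pv
    kept[[length(kept) + 1L]] <- ts
    pvals[[length(pvals) + 1L]] <- pv$p
  }
  p_observed <- unlist(pvals) %||% numeric(0)
  log_msg(config, "%d testable term(s), %d skipped; %d RD(s) built, %d reused",
          length(kept), length(skipped), cache$n_built, cache$n_reused)

  null_pool <- NULL
  fdr_vals <- rep(NA_real_, length(kept))
  if (config$fdr && length(kept) > 0) {
    null_pool <- generate_null_pool(
      dataset, kept, config$estimator, config$resamplings,
      sidedness = config$sidedness, gpd = config$gpd,
      tail_fraction = config$tail_fraction, base_seed = config$seed,
      min_null = config$min_null_pvalues, cache = cache)
    fdr_tab <- estimate_fdr(p_observed, null_pool,
                            monotone = config$fdr_monotone)
    fdr_vals <- fdr_tab$fdr
    log_msg(config, "null pool: %d p-values from %d permutation(s)",
            length(null_pool$p_null), null_pool$n_permutations)
  }

  rows <- lapply(seq_along(kept), function(i) {
    ts <- kept[[i]]
    s <- seven_figure_summary(ts$values)
    data.frame(annotation_type = ts$annotation_type, term = ts$term,
               m = ts$m, e_s = ts$e_s, mean = s$mean,
               sd = if (ts$m >= 2) stats::sd(ts$values) else NA_real_,
               min = s$min, p10 = s$p10, q1 = s$q1, median = s$median,
               q3 = s$q3, p90 = s$p90, max = s$max,
               p = ts$pv$p, fdr = fdr_vals[i], method = ts$pv$method)
  })
  empty_terms <- data.frame(
    annotation_type = character(0), term = character(0), m = integer(0),
    e_s = numeric(0), mean = numeric(0), sd = numeric(0), min = numeric(0),
    p10 = numeric(0), q1 = numeric(0), median = numeric(0), q3 = numeric(0),
    p90 = numeric(0), max = numeric(0), p = numeric(0), fdr = numeric(0),
    method = character(0))
  terms_tab <- if (length(rows)) do.call(rbind, rows) else empty_terms

  members <- lapply(kept, function(ts) {
    data.frame(
      annotation_type = ts$annotation_type, term = ts$term,
      identifiers = vapply(dataset$identifiers[ts$member_rows],
                           paste, "", collapse = ";"),
      value = fmt_stat(ts$values))
  })

  skipped_tab <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(annotation_type = character(0), term = character(0),
               m = integer(0), reason = character(0))

  results <- structure(
    list(terms = terms_tab, members = members, skipped = skipped_tab,
         null_pool = null_pool, config = config,
         log = list(rows = dataset$n,
                    terms_per_type = table(terms_tab$annotation_type),
                    n_testable = length(kept), n_skipped = length(skipped),
                    rds_built = cache$n_built, rds_reused = cache$n_reused,
                    permutations = null_pool$n_permutations %||% 0L,
                    elapsed_s = proc.time()[["elapsed"]] - t0)),
    class = "resa_results")

  if (!is.null(config$out_dir)) {
    write_results(results, config$out_dir)
    log_msg(config, "results written to %s", config$out_dir)
  }
  results
}
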