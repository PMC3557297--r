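# Per-term result assembly and TSV serialization.
#
# The output mirrors a three-level navigable view as files:
#   level1_types.tsv     - annotation types with term frequencies
#   level2_<type>.tsv    - per type: term statistics, sorted by p
#   level3_members.tsv   - term -> member identifiers and values
#   complete_results.tsv - all types combined (the downloadable dataset)
#   skipped_terms.tsv    - excluded terms with reasons

#' Seven-figure summary of a sample
#'
#' A box-plot-like digest: minimum and maximum (outer whiskers), 10th and
#' 90th percentiles (inner whiskers), first and third quartiles (box) and
#' median, with the arithmetic mean as an auxiliary eighth mark. Percentiles
#' follow the same linear-interpolation convention as the estimators.
#'
#' @param values Numeric vector, length >= 1.
#' @return Named list `min, p10, q1, median, q3, p90, max, mean`.
#' @export
seven_figure_summary <- function(values) {
  if (length(values) < 1L) config_error("seven_figure_summary needs values")
  q <- pctl(values, c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1))
  list(min = q[1], p10 = q[2], q1 = q[3], median = q[4], q3 = q[5],
       p90 = q[6], max = q[7], mean = mean(values))
}

# Fixed numeric formatting: p/FDR in scientific notation with 4 significant
# digits, all other statistics with 6 significant digits.
fmt_p <- function(x) trimws(formatC(x, format = "e", digits = 3L))
fmt_stat <- function(x) trimws(formatC(x, format = "g", digits = 6L))

results_table <- function(results) {
  stopifnot(inherits(results, "resa_results"))
  results$terms
}

#' @export
print.resa_results <- function(x, ...) {
  cat(sprintf(
    "<resa_results> %d tested term(s) in %d annotation type(s), %d skipped\n",
    nrow(x$terms), length(unique(x$terms$annotation_type)), nrow(x$skipped)))
  invisible(x)
}

#' Seven figures per term in tidy long format
#'
#' Helper for plotting layers: one row per (term, figure) pair.
#'
#' @param results A `resa_results` object from [run_analysis()].
#' @return Data frame with columns `annotation_type`, `term`, `figure`,
#'   `value`.
#' @export
summary_long <- function(results) {
  tab <- results_table(results)
  figures <- c("min", "p10", "q1", "median", "q3", "p90", "max", "mean")
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(annotation_type = tab$annotation_type[i], term = tab$term[i],
               figure = figures,
               value = unlist(tab[i, figures], use.names = FALSE))
  }))
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    resa_error(sprintf("failed to write '%s': %s", path,
                       conditionMessage(ok)), "resa_io_error")
  }
  invisible(path)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

level2_columns <- c("term", "m", "e_s", "mean", "sd", "min", "p10", "q1",
                    "median", "q3", "p90", "max", "p", "fdr")

format_level2 <- function(tab) {
  stat_cols <- c("e_s", "mean", "sd", "min", "p10", "q1", "median", "q3",
                 "p90", "max")
  out <- tab
  for (cc in stat_cols) out[[cc]] <- fmt_stat(tab[[cc]])
  out$p <- fmt_p(tab$p)
  out$fdr <- fmt_p(tab$fdr)
  out
}

#' Write analysis results as three-level TSV files
#'
#' Serializes a `resa_results` object into `out_dir`: `level1_types.tsv`
#' (annotation type, term count), one `level2_<type>.tsv` per annotation type
#' (term statistics sorted ascending by p, ties by term name),
#' `level3_members.tsv` (one row per term member with its identifiers and
#' value), `complete_results.tsv` (everything combined) and
#' `skipped_terms.tsv` (excluded terms with reasons). All files are UTF-8,
#' tab-separated, `.` decimal point; p and FDR are printed in scientific
#' notation with 4 significant digits, other statistics with 6.
#'
#' @param results A `resa_results` object from [run_analysis()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the character vector of file paths written.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "resa_results"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tab <- results_table(results)
  ord <- order(tab$p, tab$term)
  tab <- tab[ord, , drop = FALSE]
  paths <- character(0)

  types <- unique(tab$annotation_type)
  level1 <- data.frame(annotation_type = types,
                       n_terms = vapply(types, function(ty)
                         sum(tab$annotation_type == ty), 1L))
  if (nrow(level1) == 0L) {
    level1 <- data.frame(annotation_type = character(0),
                         n_terms = integer(0))
  }
  paths <- c(paths, write_tsv(level1, file.path(out_dir, "level1_types.tsv")))

  for (ty in types) {
    sub <- tab[tab$annotation_type == ty, level2_columns, drop = FALSE]
    f <- file.path(out_dir, paste0("level2_", sanitize_filename(ty), ".tsv"))
    paths <- c(paths, write_tsv(format_level2(sub), f))
  }

  members <- results$members
  level3 <- if (length(members)) do.call(rbind, members) else
    data.frame(annotation_type = character(0), term = character(0),
               identifiers = character(0), value = character(0))
  paths <- c(paths, write_tsv(level3, file.path(out_dir, "level3_members.tsv")))

  complete <- format_level2(tab[, c("annotation_type", level2_columns),
                                drop = FALSE])
  complete$method <- tab$method
  paths <- c(paths,
             write_tsv(complete, file.path(out_dir, "complete_results.tsv")))

  paths <- c(paths,
             write_tsv(results$skipped,
                       file.path(out_dir, "skipped_terms.tsv")))
  invisible(paths)
}
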