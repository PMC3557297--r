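# Dataset container and the tab-separated input dialect.
#
# Input layout: column 1 is the numeric experimental value (log fold-change,
# isotope incorporation rate, intensity, ...), followed by optional identifier
# columns (gene symbols / UniProt accessions) and then the annotation columns,
# which must be the LAST columns. Multiple identifiers or terms within one
# cell are separated by semicolons.

#' Construct a dataset of experimental values with annotations
#'
#' @param values Numeric vector of finite experimental values, one per row.
#' @param identifiers List of character vectors (possibly empty), one per row:
#'   gene symbols and/or UniProt accessions.
#' @param terms Named list, one element per annotation type; each element is a
#'   list of character vectors (the row's terms of that type, possibly empty).
#' @return An object of class `resa_dataset`.
#' @export
resa_dataset <- function(values, identifiers = NULL, terms = list()) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) parse_error("dataset must contain at least one row")
  if (!all(is.finite(values))) {
    parse_error(sprintf("non-finite value in row %d",
                        which(!is.finite(values))[1]))
  }
  if (is.null(identifiers)) identifiers <- rep(list(character(0)), n)
  stopifnot(length(identifiers) == n)
  types <- names(terms)
  if (length(terms) > 0) {
    if (is.null(types) || any(!nzchar(types))) {
      parse_error("annotation types must be non-empty strings")
    }
    if (anyDuplicated(types)) {
      parse_error("duplicate annotation-column titles")
    }
    for (ty in types) stopifnot(length(terms[[ty]]) == n)
  }
  structure(
    list(values = values, identifiers = identifiers, terms = terms,
         annotation_types = types %||% character(0), n = n),
    class = "resa_dataset"
  )
}

#' @export
print.resa_dataset <- function(x, ...) {
  cat(sprintf("<resa_dataset> %d rows, %d annotation type(s)%s\n", x$n,
              length(x$annotation_types),
              if (length(x$annotation_types))
                paste0(": ", paste(x$annotation_types, collapse = ", "))
              else ""))
  invisible(x)
}

split_cell <- function(cell) {
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  unique(parts[nzchar(parts)])
}

#' Parse a tab-separated annotated dataset
#'
#' Reads the tab-separated dialect: value column first, then `id_cols`
#' identifier columns, then `n_annotation_cols` annotation columns (the last
#' columns of the table). Semicolon-separated cells are split into multiple
#' identifiers/terms; surrounding whitespace is stripped, empty fragments are
#' discarded and duplicate terms within one cell collapse to a single
#' membership.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param n_annotation_cols Number of trailing annotation columns (>= 0).
#' @param id_cols Number of identifier columns between the value column and
#'   the annotation columns.
#' @param has_header Whether the first line holds column titles. Annotation
#'   column titles become the annotation types; without a header the types
#'   are named `Annotation1`, `Annotation2`, ...
#' @return A [resa_dataset()].
#' @export
parse_dataset <- function(source, n_annotation_cols, id_cols = 0L,
                          has_header = TRUE) {
  if (n_annotation_cols < 0) config_error("n_annotation_cols must be >= 0")
  if (id_cols < 0) config_error("id_cols must be >= 0")
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) parse_error("empty input")

  ncol_expected <- 1L + id_cols + n_annotation_cols
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; pad rows that are one short
  cells <- lapply(cells, function(x) {
    if (length(x) == ncol_expected - 1L) c(x, "") else x
  })

  line_no <- seq_along(lines)
  if (has_header) {
    header <- cells[[1]]
    if (length(header) != ncol_expected) {
      parse_error(sprintf(
        "header has %d columns, expected %d (1 value + %d id + %d annotation)",
        length(header), ncol_expected, id_cols, n_annotation_cols))
    }
    ann_titles <- trimws(header[seq_len(n_annotation_cols) + 1L + id_cols])
    cells <- cells[-1]
    line_no <- line_no[-1]
  } else {
    ann_titles <- if (n_annotation_cols > 0)
      paste0("Annotation", seq_len(n_annotation_cols)) else character(0)
  }
  if (length(cells) == 0L) parse_error("no data rows")
  if (n_annotation_cols > 0 && any(!nzchar(ann_titles))) {
    parse_error("empty annotation-column title")
  }
  if (anyDuplicated(ann_titles)) {
    parse_error("duplicate annotation-column titles")
  }

  bad <- which(vapply(cells, length, 1L) != ncol_expected)
  if (length(bad)) {
    parse_error(sprintf("line %d: expected %d columns, found %d",
                        line_no[bad[1]], ncol_expected,
                        length(cells[[bad[1]]])))
  }

  raw_vals <- vapply(cells, `[[`, "", 1L)
  values <- suppressWarnings(as.numeric(raw_vals))
  if (anyNA(values) || any(!is.finite(values))) {
    i <- which(is.na(values) | !is.finite(values))[1]
    parse_error(sprintf("line %d: value column is not a finite number: '%s'",
                        line_no[i], raw_vals[i]))
  }

  identifiers <- if (id_cols > 0) {
    lapply(cells, function(row) {
      unique(unlist(lapply(row[1L + seq_len(id_cols)], split_cell),
                    use.names = FALSE))
    })
  } else {
    rep(list(character(0)), length(cells))
  }

  terms <- list()
  for (j in seq_len(n_annotation_cols)) {
    col_idx <- 1L + id_cols + j
    terms[[ann_titles[j]]] <- lapply(cells, function(row) {
      split_cell(row[[col_idx]])
    })
  }

  resa_dataset(values, identifiers, terms)
}

#' Write a dataset back to the tab-separated dialect
#'
#' Inverse of [parse_dataset()]: one header line, then one line per row with
#' semicolon-joined identifier and term cells.
#'
#' @param dataset A [resa_dataset()].
#' @param path Output file path; if `NULL`, the lines are returned invisibly
#'   without writing.
#' @param value_title,id_title Column titles for the value and identifier
#'   columns.
#' @return Invisibly, the character vector of lines written.
#' @export
write_dataset <- function(dataset, path = NULL, value_title = "Value",
                          id_title = "Identifiers") {
  stopifnot(inherits(dataset, "resa_dataset"))
  has_ids <- any(lengths(dataset$identifiers) > 0)
  header <- c(value_title, if (has_ids) id_title, dataset$annotation_types)
  rows <- vapply(seq_len(dataset$n), function(i) {
    cells <- c(
      format(dataset$values[i], digits = 15, scientific = FALSE, trim = TRUE),
      if (has_ids) paste(dataset$identifiers[[i]], collapse = ";"),
      vapply(dataset$annotation_types, function(ty) {
        paste(dataset$terms[[ty]][[i]], collapse = ";")
      }, "")
    )
    paste(cells, collapse = "\t")
  }, "")
  lines <- c(paste(header, collapse = "\t"), rows)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Collect per-term samples of experimental values
#'
#' Builds one sample per (annotation type, term) pair carrying at least
#' `min_size` member rows. Each member row contributes its value exactly once
#' per term; terms below the size cutoff are excluded. The cutoff only removes
#' small samples - it has no effect on the analysis of larger terms.
#'
#' @param dataset A [resa_dataset()].
#' @param min_size Minimum number of member rows per term (default 5).
#' @return A list of `resa_term_sample` objects, each with fields
#'   `annotation_type`, `term`, `values`, `member_rows` and `m`.
#' @export
build_term_samples <- function(dataset, min_size = 5L) {
  stopifnot(inherits(dataset, "resa_dataset"))
  if (min_size < 1) config_error("min_size must be >= 1")
  out <- list()
  for (ty in dataset$annotation_types) {
    per_row <- dataset$terms[[ty]]
    reps <- lengths(per_row)
    if (sum(reps) == 0) next
    flat <- unlist(per_row, use.names = FALSE)
    row_of <- rep.int(seq_along(per_row), reps)
    by_term <- split(row_of, flat)
    for (term in names(by_term)) {
      rows <- by_term[[term]]
      if (length(rows) < min_size) next
      out[[length(out) + 1L]] <- structure(
        list(annotation_type = ty, term = term,
             values = dataset$values[rows],
             member_rows = rows, m = length(rows)),
        class = "resa_term_sample")
    }
  }
  out
}
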