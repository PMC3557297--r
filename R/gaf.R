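# GAF 2.x gene-association parsing and GO annotation of datasets.

# Experimental evidence codes retained under evidence_mode = "experimental".
GO_EXPERIMENTAL_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")

#' Read a GAF 2.x gene-association file into a GO mapping
#'
#' Parses a Gene Association File (tab-separated, comment lines starting with
#' `!`). The mapping is keyed by BOTH the DB object ID (UniProt accession,
#' matched case-sensitively) and the DB object symbol (gene symbol, matched
#' case-insensitively, since symbol casing varies between sources). Records
#' whose qualifier contains `NOT` are dropped; in `experimental` mode only
#' records with an experimental evidence code (EXP, IDA, IPI, IMP, IGI, IEP)
#' are kept. Malformed lines are skipped with a warning reporting the count.
#'
#' @param source Path to a GAF file, or a character vector of GAF lines.
#' @param evidence_mode `"full"` (all evidence codes) or `"experimental"`.
#' @param slim_map Optional named list mapping GO accessions to character
#'   vectors of slim GO accessions, as returned by [read_slim_map()].
#' @return An object of class `resa_go_mapping`.
#' @export
read_gaf <- function(source, evidence_mode = c("full", "experimental"),
                     slim_map = NULL) {
  evidence_mode <- match.arg(evidence_mode)
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  acc_map <- new.env(parent = emptyenv())
  sym_map <- new.env(parent = emptyenv())
  n_skipped <- 0L
  n_records <- 0L
  add <- function(env, key, term) {
    if (!nzchar(key)) return(invisible())
    assign(key, c(get0(key, envir = env, ifnotfound = character(0)), term),
           envir = env)
  }
  for (f in fields) {
    # GAF 2.0-2.2 column positions: 2 = DB object ID, 3 = symbol,
    # 4 = qualifier, 5 = GO ID, 7 = evidence code
    if (length(f) < 7L || !grepl("^GO:[0-9]{7}$", f[[5]])) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (grepl("NOT", f[[4]], fixed = TRUE)) next
    if (evidence_mode == "experimental" &&
        !(f[[7]] %in% GO_EXPERIMENTAL_CODES)) next
    n_records <- n_records + 1L
    add(acc_map, f[[2]], f[[5]])
    add(sym_map, tolower(f[[3]]), f[[5]])
  }
  if (n_skipped > 0) {
    warning(sprintf("skipped %d malformed GAF line(s)", n_skipped))
  }
  if (n_records == 0L) parse_error("no usable GAF records")
  for (env in list(acc_map, sym_map)) {
    for (k in ls(env)) assign(k, unique(get(k, envir = env)), envir = env)
  }
  structure(
    list(acc_map = acc_map, sym_map = sym_map, evidence_mode = evidence_mode,
         slim_map = slim_map, n_records = n_records, n_skipped = n_skipped),
    class = "resa_go_mapping")
}

#' @export
print.resa_go_mapping <- function(x, ...) {
  cat(sprintf("<resa_go_mapping> %d records (%s evidence)%s\n", x$n_records,
              x$evidence_mode, if (!is.null(x$slim_map)) ", slim-mapped" else ""))
  invisible(x)
}

#' Read a GO slim mapping from a two-column TSV
#'
#' Each line maps a full GO accession to one slim accession; one-to-many
#' mappings are expressed as repeated rows.
#'
#' @param source Path or character vector of lines (`term<TAB>slim_term`).
#' @return Named list: GO accession -> character vector of slim accessions.
#' @export
read_slim_map <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (!all(ok)) parse_error("slim map lines must have two tab-separated columns")
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  lapply(split(to, from), unique)
}

# Look up all GO terms for one row's identifiers: accession keys are
# case-sensitive, symbol keys case-insensitive.
lookup_go <- function(mapping, ids) {
  hits <- character(0)
  for (id in ids) {
    hits <- c(hits,
              get0(id, envir = mapping$acc_map, ifnotfound = character(0)),
              get0(tolower(id), envir = mapping$sym_map,
                   ifnotfound = character(0)))
  }
  unique(hits)
}

#' Attach GO terms to a dataset as a new annotation type
#'
#' For every row, the union of GO terms over all of the row's identifiers is
#' attached under `column_title`. If the mapping carries a slim map, each term
#' is replaced by its slim term(s) before the union (terms without a slim
#' mapping are dropped). Rows with no mapped identifier get an empty term set
#' and stay in the dataset.
#'
#' @param dataset A [resa_dataset()] whose rows carry identifiers.
#' @param mapping A `resa_go_mapping` from [read_gaf()].
#' @param column_title Name of the new annotation type (default `"GO"`); must
#'   not collide with an existing type.
#' @return The dataset with one additional annotation type.
#' @export
annotate_go <- function(dataset, mapping, column_title = "GO") {
  stopifnot(inherits(dataset, "resa_dataset"),
            inherits(mapping, "resa_go_mapping"))
  if (column_title %in% dataset$annotation_types) {
    config_error(sprintf("annotation type '%s' already exists", column_title))
  }
  slim <- mapping$slim_map
  go_terms <- lapply(dataset$identifiers, function(ids) {
    terms <- lookup_go(mapping, ids)
    if (!is.null(slim)) {
      terms <- unique(unlist(lapply(terms, function(t) slim[[t]]),
                             use.names = FALSE)) %||% character(0)
    }
    terms
  })
  terms <- dataset$terms
  terms[[column_title]] <- go_terms
  resa_dataset(dataset$values, dataset$identifiers, terms)
}
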