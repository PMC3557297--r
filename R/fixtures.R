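# Synthetic dataset and GAF generation with controlled null/spiked structure.
#
# The generator emulates the statistical shape of a SILAC incorporation-rate
# experiment: one numeric value per protein group, identifier columns, and
# overlapping annotation terms. Presets: a plain normal draw for
# log-ratio-like values, a uniform draw, and a logit-normal draw confined to
# (0, 1) for incorporation-rate-like values H/(H+L). Spiked terms carry
# either a mean shift (in units of the population SD) or a within-term
# scale factor, giving a known ground truth for power and FDR checks.

#' Describe a synthetic dataset
#'
#' Defaults encode the standard study conditions used throughout the test
#' suite: 2000 rows of standard-normal values carrying 100 terms of size 10
#' in one annotation type, terms assigned uniformly at random (so terms
#' overlap on rows, as GO terms do).
#'
#' @param n_rows Number of dataset rows.
#' @param value_distribution `"normal"`, `"uniform"` or `"logit_normal"`.
#' @param dist_params Named list of distribution parameters: `mean`/`sd` for
#'   normal and logit_normal (on the latent scale), `min`/`max` for uniform.
#' @param n_terms Number of annotation terms.
#' @param term_size Integer term size, or a length-2 range sampled uniformly.
#' @param annotation_type Title of the generated annotation column.
#' @param spikes `NULL`, or a data frame with columns `term` (existing term
#'   name, e.g. `"T001"`), `effect` (`"mean_shift"` or `"scale_factor"`) and
#'   `value` (shift in population-SD units, or the SD multiplier kappa > 0).
#' @param extra_types Optional named list of additional annotation types to
#'   attach to the same rows (the multi-type situation the analysis handles
#'   in one run). Each element is a list with fields `n_terms`, `term_size`
#'   and optionally `spikes`, interpreted as above; term names restart at
#'   `T001` within each type.
#' @return An object of class `resa_fixture_spec`.
#' @export
fixture_spec <- function(n_rows = 2000L,
                         value_distribution = c("normal", "uniform",
                                                "logit_normal"),
                         dist_params = NULL,
                         n_terms = 100L,
                         term_size = 10L,
                         annotation_type = "SetA",
                         spikes = NULL,
                         extra_types = NULL) {
  value_distribution <- match.arg(value_distribution)
  dist_params <- dist_params %||% switch(value_distribution,
    normal = list(mean = 0, sd = 1),
    logit_normal = list(mean = 0, sd = 1),
    uniform = list(min = 0, max = 1))

  check_type <- function(n_terms, term_size, spikes) {
    if (length(term_size) == 1L) term_size <- c(term_size, term_size)
    if (any(term_size < 2L)) config_error("term sizes must be >= 2")
    if (!is.null(spikes)) {
      stopifnot(is.data.frame(spikes),
                all(c("term", "effect", "value") %in% names(spikes)))
      if (!all(spikes$effect %in% c("mean_shift", "scale_factor"))) {
        config_error("spike effect must be 'mean_shift' or 'scale_factor'")
      }
      if (any(spikes$effect == "scale_factor" & spikes$value <= 0)) {
        config_error("scale_factor kappa must be > 0")
      }
      term_names <- sprintf("T%03d", seq_len(n_terms))
      if (!all(spikes$term %in% term_names)) {
        config_error("spiked terms must reference existing terms")
      }
    }
    list(n_terms = as.integer(n_terms), term_size = as.integer(term_size),
         spikes = spikes)
  }

  types <- c(
    stats::setNames(list(check_type(n_terms, term_size, spikes)),
                    annotation_type),
    lapply(extra_types, function(ty) {
      check_type(ty$n_terms, ty$term_size %||% 10L, ty$spikes)
    }))
  if (anyDuplicated(names(types))) {
    config_error("duplicate annotation-type names in fixture spec")
  }
  structure(
    list(n_rows = as.integer(n_rows),
         value_distribution = value_distribution,
         dist_params = dist_params, types = types,
         # flat fields kept for the single-type view
         n_terms = types[[1]]$n_terms, term_size = types[[1]]$term_size,
         annotation_type = annotation_type, spikes = types[[1]]$spikes),
    class = "resa_fixture_spec")
}

draw_values <- function(spec, n) {
  p <- spec$dist_params
  switch(spec$value_distribution,
    normal = stats::rnorm(n, p$mean, p$sd),
    logit_normal = stats::plogis(stats::rnorm(n, p$mean, p$sd)),
    uniform = stats::runif(n, p$min, p$max))
}

#' Generate a synthetic annotated dataset with known ground truth
#'
#' Draws row values from the specified value distribution, assigns each term a
#' uniformly random set of member rows of the requested size (rows may carry
#' several terms), then applies the spikes: a `mean_shift` spike redraws the
#' term's member values with the population mean shifted by
#' `value * population SD`; a `scale_factor` spike redraws them around a
#' center drawn once from the value distribution, with the population SD
#' multiplied by kappa. For the logit-normal preset both act on the latent
#' normal scale, keeping values inside (0, 1). Deterministic given `seed`.
#'
#' Rows carry synthetic accession-style (`SYN00001`, ...) and gene-symbol
#' (`GENE1`, ...) identifiers usable with [generate_gaf()].
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return List with elements `dataset` (a [resa_dataset()]) and `truth`
#'   (data frame of non-null terms: `annotation_type`, `term`, `effect`,
#'   `value`); a spec without spikes yields an empty `truth`.
#' @export
generate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "resa_fixture_spec"))
  for (ty in spec$types) {
    if (ty$term_size[2] > spec$n_rows) {
      config_error("term size exceeds number of rows")
    }
  }
  with_seed(seed, {
    n <- spec$n_rows
    latent_normal <- spec$value_distribution %in% c("normal", "logit_normal")
    p <- spec$dist_params
    # latent values: for logit_normal spikes act before the logistic map
    latent <- if (latent_normal) stats::rnorm(n, p$mean, p$sd)
              else draw_values(spec, n)
    pop_sd <- if (latent_normal) p$sd else stats::sd(latent)
    pop_mean <- if (latent_normal) p$mean else mean(latent)

    terms <- list()
    truth_rows <- list()
    for (type_name in names(spec$types)) {
      ty <- spec$types[[type_name]]
      term_names <- sprintf("T%03d", seq_len(ty$n_terms))
      sizes <- if (ty$term_size[1] == ty$term_size[2]) {
        rep(ty$term_size[1], ty$n_terms)
      } else {
        sample(seq(ty$term_size[1], ty$term_size[2]), ty$n_terms,
               replace = TRUE)
      }
      members <- lapply(sizes, function(s) sort(sample.int(n, s)))

      if (!is.null(ty$spikes)) {
        for (i in seq_len(nrow(ty$spikes))) {
          sp <- ty$spikes[i, ]
          rows <- members[[match(sp$term, term_names)]]
          latent[rows] <- switch(as.character(sp$effect),
            mean_shift = stats::rnorm(length(rows),
                                      pop_mean + sp$value * pop_sd, pop_sd),
            scale_factor = {
              center <- stats::rnorm(1L, pop_mean, pop_sd)
              stats::rnorm(length(rows), center, sp$value * pop_sd)
            })
        }
        truth_rows[[type_name]] <- data.frame(
          annotation_type = type_name,
          term = as.character(ty$spikes$term),
          effect = as.character(ty$spikes$effect),
          value = ty$spikes$value)
      }

      per_row <- rep(list(character(0)), n)
      for (t in seq_along(term_names)) {
        for (r in members[[t]]) {
          per_row[[r]] <- c(per_row[[r]], term_names[t])
        }
      }
      terms[[type_name]] <- per_row
    }
    values <- if (spec$value_distribution == "logit_normal")
      stats::plogis(latent) else latent

    identifiers <- lapply(seq_len(n), function(i) {
      c(sprintf("SYN%05d", i), sprintf("GENE%d", i))
    })
    truth <- if (length(truth_rows)) do.call(rbind, c(truth_rows,
                                                      make.row.names = FALSE))
      else data.frame(annotation_type = character(0), term = character(0),
                      effect = character(0), value = numeric(0))
    list(dataset = resa_dataset(values, identifiers, terms), truth = truth)
  })
}

#' Generate a syntactically valid synthetic GAF 2.2 file
#'
#' Produces annotation records over the given identifier universe with a
#' seed-controlled mix of experimental (IDA) and electronic (IEA) evidence
#' codes and at least one NOT-qualified record, exercising all of
#' [read_gaf()]'s filters. With `n_terms = 0` only the header comments are
#' emitted (a valid GAF that triggers the zero-usable-records error).
#'
#' @param ids Character vector of DB object IDs (accessions); symbols are
#'   derived as `SYM_<id>`.
#' @param n_terms Number of distinct GO terms to draw annotations from.
#' @param seed Integer seed.
#' @param n_records Number of annotation records (default `5 * n_terms`).
#' @param experimental_fraction Fraction of records with evidence IDA, the
#'   rest IEA (default 0.5).
#' @return Character vector of GAF lines.
#' @export
generate_gaf <- function(ids, n_terms, seed = 1L, n_records = 5L * n_terms,
                         experimental_fraction = 0.5) {
  if (length(ids) == 0L) config_error("identifier universe is empty")
  header <- c("!gaf-version: 2.2", "!generated-by: resanno (synthetic)")
  if (n_terms == 0L) return(header)
  with_seed(seed, {
    go_ids <- sprintf("GO:%07d", sample.int(9999999L, n_terms))
    n_exp <- round(experimental_fraction * n_records)
    evidence <- sample(c(rep("IDA", n_exp), rep("IEA", n_records - n_exp)))
    rec <- function(id, qualifier, go, ev) {
      paste("UniProtKB", id, paste0("SYM_", id), qualifier, go, "GO_REF:0000001",
            ev, "", "C", "", "", "protein", "taxon:10090", "20260101",
            "SYNTH", "", "", sep = "\t")
    }
    lines <- vapply(seq_len(n_records), function(i) {
      rec(sample(ids, 1L), "located_in", sample(go_ids, 1L), evidence[i])
    }, "")
    not_line <- rec(sample(ids, 1L), "NOT|located_in", sample(go_ids, 1L),
                    "IDA")
    c(header, lines, not_line)
  })
}
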