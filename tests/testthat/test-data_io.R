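test_that("parse_dataset reads the tab-separated dialect with semicolon cells", {
  ds <- toy_dataset()
  expect_s3_class(ds, "resa_dataset")
  expect_equal(ds$n, 5L)
  expect_equal(ds$annotation_types, c("KEGG", "Pfam"))
  expect_equal(ds$values[1], 0.55)
  expect_setequal(ds$terms$KEGG[[1]], c("hsa04310", "hsa04390"))
  expect_equal(ds$identifiers[[2]], "Lamc1")
  # empty annotation cell: empty term set, row still counted
  expect_length(ds$terms$Pfam[[3]], 0)
  expect_length(ds$terms$KEGG[[5]], 0)
})

test_that("parse_dataset rejects malformed input with line numbers", {
  bad_value <- c("Ratio\tKEGG", "abc\thsa04310")
  expect_error(parse_dataset(bad_value, 1L), "line 2", class = "resa_parse_error")
  ragged <- c("Ratio\tKEGG", "0.5\thsa04310", "0.2\tx\ty\tz")
  expect_error(parse_dataset(ragged, 1L), "line 3", class = "resa_parse_error")
  dup <- c("Ratio\tKEGG\tKEGG", "0.5\ta\tb")
  expect_error(parse_dataset(dup, 2L), "duplicate", class = "resa_parse_error")
  expect_error(parse_dataset(c("Ratio\tKEGG", "\thsa1"), 1L),
               class = "resa_parse_error")
})

test_that("duplicate terms within one cell collapse to a single membership", {
  ds <- parse_dataset(c("V\tA", "1.0\tT;T; T ;U"), 1L)
  expect_setequal(ds$terms$A[[1]], c("T", "U"))
  samples <- build_term_samples(ds, min_size = 1L)
  m_of <- vapply(samples, `[[`, 1L, "m")
  expect_equal(sort(m_of), c(1L, 1L))
})

test_that("datasets round-trip through the tab-separated format", {
  ds <- toy_dataset()
  lines <- write_dataset(ds)
  ds2 <- parse_dataset(lines, n_annotation_cols = 2L, id_cols = 1L)
  expect_equal(ds2$values, ds$values)
  expect_equal(ds2$annotation_types, ds$annotation_types)
  for (ty in ds$annotation_types) {
    for (i in seq_len(ds$n)) {
      expect_setequal(ds2$terms[[ty]][[i]], ds$terms[[ty]][[i]])
    }
  }
  # also via a file on disk
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f)
  ds3 <- parse_dataset(f, n_annotation_cols = 2L, id_cols = 1L)
  expect_equal(ds3$values, ds$values)
})

test_that("build_term_samples applies the size cutoff and counts each incidence once", {
  ds <- toy_dataset()
  # hsa04310 has 3 members; cutoff 5 excludes everything
  expect_length(build_term_samples(ds, min_size = 5L), 0)
  samples <- build_term_samples(ds, min_size = 3L)
  expect_length(samples, 1L)
  expect_equal(samples[[1]]$term, "hsa04310")
  expect_equal(samples[[1]]$values, c(0.55, -0.20, 0.07))

  # min_size = 1: total membership equals a brute-force (row, term) scan
  all_samples <- build_term_samples(ds, min_size = 1L)
  total_m <- sum(vapply(all_samples, `[[`, 1L, "m"))
  brute <- 0L
  for (ty in ds$annotation_types) {
    for (i in seq_len(ds$n)) brute <- brute + length(ds$terms[[ty]][[i]])
  }
  expect_equal(total_m, brute)
})

test_that("a term carried by many rows yields one sample in row order", {
  vals <- round(rnorm(10), 3)
  lines <- c("V\tA", sprintf("%g\tT", vals))
  ds <- parse_dataset(lines, 1L)
  samples <- build_term_samples(ds, min_size = 1L)
  expect_length(samples, 1L)
  expect_equal(samples[[1]]$m, 10L)
  expect_equal(samples[[1]]$values, vals)
})

gaf_line <- function(id, sym, qualifier, go, evidence) {
  paste("UniProtKB", id, sym, qualifier, go, "GO_REF:0000001", evidence, "",
        "C", "", "", "protein", "taxon:10090", "20260101", "SYNTH",
        sep = "\t")
}

test_that("read_gaf filters by evidence mode and drops NOT qualifiers", {
  lines <- c(
    "!gaf-version: 2.2",
    gaf_line("P12345", "Rpl1", "located_in", "GO:0005840", "IDA"),
    gaf_line("Q99999", "Actb", "located_in", "GO:0005840", "IEA"),
    gaf_line("Q99999", "Actb", "located_in", "GO:0005737", "IMP"),
    gaf_line("P55555", "Gsk3b", "NOT|located_in", "GO:0016055", "IDA"))
  full <- read_gaf(lines, "full")
  exp <- read_gaf(lines, "experimental")
  expect_setequal(lookup_ids(full, "Q99999"), c("GO:0005840", "GO:0005737"))
  # IEA record dropped in experimental mode, IMP kept
  expect_setequal(lookup_ids(exp, "Q99999"), "GO:0005737")
  expect_setequal(lookup_ids(exp, "P12345"), "GO:0005840")
  # NOT-qualified record is never mapped
  expect_length(lookup_ids(full, "P55555"), 0)
  expect_length(lookup_ids(full, "Gsk3b"), 0)
})

test_that("read_gaf matches accessions case-sensitively, symbols case-insensitively", {
  lines <- c("!gaf-version: 2.2",
             gaf_line("P12345", "Rpl1", "located_in", "GO:0005840", "IDA"))
  map <- read_gaf(lines, "full")
  expect_setequal(lookup_ids(map, "RPL1"), "GO:0005840")
  expect_setequal(lookup_ids(map, "rpl1"), "GO:0005840")
  expect_length(lookup_ids(map, "p12345"), 0)
})

test_that("read_gaf warns on malformed lines and errors with zero records", {
  lines <- c("!gaf-version: 2.2",
             "UniProtKB\tP1\tX",  # too few columns
             gaf_line("P12345", "Rpl1", "located_in", "GO:0005840", "IDA"))
  expect_warning(map <- read_gaf(lines, "full"), "1 malformed")
  expect_equal(map$n_records, 1L)
  expect_error(suppressWarnings(read_gaf("!gaf-version: 2.2", "full")),
               "no usable", class = "resa_parse_error")
})

test_that("annotate_go attaches the union of terms over a row's identifiers", {
  lines <- c("!gaf-version: 2.2",
             gaf_line("P12345", "GeneA", "located_in", "GO:0005840", "IDA"),
             gaf_line("Q99999", "GeneB", "located_in", "GO:0005840", "IDA"),
             gaf_line("Q99999", "GeneB", "located_in", "GO:0005737", "IDA"))
  map <- read_gaf(lines, "full")
  ds <- parse_dataset(c("V\tIds", "0.1\tP12345;Q99999", "0.2\tZZZZ"), 0L,
                      id_cols = 1L)
  ann <- annotate_go(ds, map, "GO")
  expect_setequal(ann$terms$GO[[1]], c("GO:0005840", "GO:0005737"))
  # unmapped identifier: empty set, row retained
  expect_length(ann$terms$GO[[2]], 0)
  expect_equal(ann$n, 2L)
  # a second call with the same title errors instead of duplicating
  expect_error(annotate_go(ann, map, "GO"), "already exists",
               class = "resa_config_error")
})

test_that("slim mapping replaces terms before the union", {
  lines <- c("!gaf-version: 2.2",
             gaf_line("P12345", "GeneA", "located_in", "GO:0005840", "IDA"),
             gaf_line("P12345", "GeneA", "located_in", "GO:0005737", "IDA"))
  slim <- read_slim_map(c("GO:0005840\tGO:0005575", "GO:0005737\tGO:0005575"))
  map <- read_gaf(lines, "full", slim_map = slim)
  ds <- parse_dataset(c("V\tIds", "0.1\tP12345"), 0L, id_cols = 1L)
  ann <- annotate_go(ds, map, "GO")
  expect_equal(ann$terms$GO[[1]], "GO:0005575")
})
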