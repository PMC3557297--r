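Package: resanno
Title: Resampling Significance Analysis of Annotation Terms in Omics Datasets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests, for every annotation term (KEGG, Pfam, Gene Ontology or any
    custom classification) attached to an omics dataset, whether a chosen
    estimator statistic of the term's experimental values - standard deviation,
    coefficient of variation, mean, mean over SD, deviation of the mean, or the
    width of the 10th-to-90th percentile interval - is significantly extreme
    relative to random same-size samples drawn with replacement from the whole
    dataset. Empirical p-values use linear rank interpolation and are refined in
    the distribution tails by maximum-likelihood generalized Pareto fits; false
    discovery rates are estimated empirically from permutations of the dataset
    by the rank-ratio method. Includes parsers for the tab-separated input
    dialect and GAF 2.x gene-association files, a synthetic-data generator with
    controlled spiked effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
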