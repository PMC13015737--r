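#' Bundled reference evaluation tables
#'
#' Two small reference tables from published cross-scanner and cross-center
#' evaluations of grayscale-trained versus RGB-trained classifiers ship with
#' the package as worked-example inputs for the statistics layer:
#'
#' * `reference_mcnemar_tables()`: paired-outcome contingency tables (both
#'   correct / only RGB correct / only grayscale correct / both incorrect)
#'   for each champion comparison, with the significance call reported
#'   alongside each table (`reported_significant`, i.e. p < 0.05) and, for
#'   the per-class cross-scanner rows, the class test-set size the four
#'   cells must sum to (38, 60 and 22 samples for classes 0-2).
#' * `reference_f1_rows()`: printed precision/recall/F1 triples for the
#'   champion classifier rows; recomputing F1 as the harmonic mean of the
#'   printed precision and recall reproduces the printed F1 at two decimals.
#'
#' @return A data frame.
#' @examples
#' tab <- reference_mcnemar_tables()
#' mcnemar_test(contingency_table(tab$n11[1], tab$n10[1],
#'                                tab$n01[1], tab$n00[1]))$p.value
#' @export
reference_mcnemar_tables <- function() {
  read.csv(system.file("extdata", "reference_mcnemar_tables.csv",
                       package = "histogray"), stringsAsFactors = FALSE)
}

#' @rdname reference_mcnemar_tables
#' @export
reference_f1_rows <- function() {
  read.csv(system.file("extdata", "reference_f1_rows.csv",
                       package = "histogray"), stringsAsFactors = FALSE)
}
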