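#' Unordered pairs of intestinal segments
#'
#' Enumerates the cross-segment comparisons the stability analysis runs:
#' every unordered pair of distinct segments (10 pairs for the five
#' standard segments).
#'
#' @param segments Character vector of segment labels.
#' @return data.frame with columns `segment1`, `segment2`.
#' @export
segment_pairs <- function(segments = c("duodenum", "jejunum", "ileum", "ceca",
                                       "feces")) {
  stopifnot(!anyDuplicated(segments), length(segments) >= 2)
  cmb <- utils::combn(segments, 2)
  data.frame(segment1 = cmb[1, ], segment2 = cmb[2, ])
}

#' Published pairwise stability percentages (printed input)
#'
#' The per-factor pairwise nDFO percentages for ileum and ceca as printed
#' in the published comparison tables (bird type, housing, continent, age
#' group), transcribed into a tidy TSV shipped with the package. Cells
#' the publication reports as not available are `NA`.
#'
#' @return data.frame with columns `factor`, `level1`, `level2`, `tissue`,
#'   `pct_ndfo`.
#' @export
printed_stability_tables <- function() {
  path <- system.file("extdata", "stability_tables_printed.tsv",
                      package = "gutcore")
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Count available pairwise comparisons per tissue
#'
#' @param tables A data.frame as returned by [printed_stability_tables()].
#' @param tissue Tissue to count (`"ileum"` or `"ceca"`).
#' @return Integer: number of non-NA pairwise comparisons.
#' @export
count_available_comparisons <- function(tables, tissue) {
  sum(!is.na(tables$pct_ndfo[tables$tissue == tissue]))
}
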