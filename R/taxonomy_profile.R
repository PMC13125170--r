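#' Dataset-level mean relative abundances
#'
#' Normalizes each sample's counts to proportions, then averages the
#' proportions within each dataset with equal weight per sample. The
#' dataset (one BioProject x segment combination) is the unit over which
#' abundances are summarized, so that downstream corpus-level means are
#' not biased by datasets with many samples.
#'
#' @param table A `feature_table` (any rank; usually genus-collapsed).
#' @param meta A `sample_metadata` covering every sample in `table`.
#' @return An object of class `dataset_profiles`: list with `abund`, a
#'   taxon x dataset matrix of mean relative abundances (columns sum to 1),
#'   and `n_samples`, a named integer vector of per-dataset sample counts.
#' @export
dataset_mean_relabund <- function(table, meta) {
  meta <- match_metadata(table, meta)
  depths <- colSums(table$counts)
  if (any(depths == 0))
    stop("sample with zero depth: ",
         colnames(table$counts)[which(depths == 0)[1]],
         " (filter before profiling)")
  props <- sweep(table$counts, 2, depths, "/")
  ds <- factor(meta$dataset_id)
  abund <- t(rowsum(t(props), group = ds, reorder = TRUE)) /
    rep(table(ds)[levels(ds)], each = nrow(props))
  structure(list(abund = abund,
                 n_samples = stats::setNames(as.integer(table(ds)[levels(ds)]),
                                             levels(ds))),
            class = "dataset_profiles")
}

#' @export
print.dataset_profiles <- function(x, ...) {
  cat(sprintf("dataset_profiles: %d taxa x %d datasets (%d samples)\n",
              nrow(x$abund), ncol(x$abund), sum(x$n_samples)))
  invisible(x)
}

#' Grand mean relative abundance across datasets
#'
#' The unweighted mean over datasets of the dataset-mean relative
#' abundances (never weighted by sample count, so a 100-sample dataset
#' counts the same as a 10-sample one). Taxa absent from a dataset
#' contribute 0 for that dataset.
#'
#' @param profiles A `dataset_profiles`.
#' @return Named numeric vector, one value per taxon, summing to 1.
#' @export
grand_mean_relabund <- function(profiles) {
  stopifnot(inherits(profiles, "dataset_profiles"), ncol(profiles$abund) >= 1)
  rowMeans(profiles$abund)
}

#' Count distinct taxa at a rank
#'
#' Number of distinct non-empty labels at `rank` among features with
#' nonzero total count. Synthetic `unclassified:*` placeholder labels
#' (produced by [collapse_to_rank()]) are excluded by default, since
#' corpus summaries conventionally count named taxa.
#'
#' @param table A taxon `feature_table` (bacteria-filtered and pruned).
#' @param tax A `taxonomy_table`.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @param include_unclassified Count `unclassified:*` groups as labels?
#' @return Integer count.
#' @export
unique_taxon_counts <- function(table, tax, rank = "genus",
                                include_unclassified = FALSE) {
  rank <- match.arg(rank, .tax_ranks)
  tab <- prune_zero_features(table)
  ids <- feature_ids(tab)
  idx <- match(ids, tax$feature_id)
  labels <- as.data.frame(tax)[[rank]][idx]
  labels <- labels[!is.na(labels) & labels != ""]
  if (!include_unclassified)
    labels <- labels[!startsWith(labels, "unclassified:")]
  length(unique(labels))
}

#' Per-segment corpus summary
#'
#' The descriptive table of a multi-dataset corpus: per intestinal
#' segment, the number of datasets, samples, distinct phyla, classes and
#' genera, and (when an FO table is supplied) distinct FOs detected.
#'
#' @param table Genus-level or ASV-level taxon `feature_table`, filtered.
#' @param tax A `taxonomy_table`.
#' @param meta A `sample_metadata`.
#' @param fo_table Optional FO `feature_table` on the same samples.
#' @return data.frame with one row per segment present.
#' @export
corpus_summary <- function(table, tax, meta, fo_table = NULL) {
  meta <- match_metadata(table, meta)
  segs <- levels(droplevels(meta$segment))
  rows <- lapply(segs, function(s) {
    sel <- meta$sample_id[meta$segment == s]
    sub <- prune_zero_features(subset_feature_table(table, samples = sel))
    n_fo <- NA_integer_
    if (!is.null(fo_table)) {
      fsel <- intersect(sel, sample_ids(fo_table))
      n_fo <- sum(rowSums(subset_feature_table(fo_table, samples = fsel)$counts) > 0)
    }
    data.frame(segment = s,
               datasets = length(unique(meta$dataset_id[meta$segment == s])),
               samples = length(sel),
               phyla = unique_taxon_counts(sub, tax, "phylum"),
               classes = unique_taxon_counts(sub, tax, "class"),
               genera = unique_taxon_counts(sub, tax, "genus"),
               fos = n_fo)
  })
  do.call(rbind, rows)
}

#' Write dataset profiles as tidy TSV (dataset_id, taxon, mean_relabund)
#' @param profiles A `dataset_profiles`.
#' @param path Output path.
#' @export
write_dataset_profiles <- function(profiles, path) {
  df <- data.frame(dataset_id = rep(colnames(profiles$abund),
                                    each = nrow(profiles$abund)),
                   taxon = rep(rownames(profiles$abund),
                               times = ncol(profiles$abund)),
                   mean_relabund = as.vector(profiles$abund))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
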