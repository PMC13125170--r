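#' Construct a feature table
#'
#' A feature table holds a non-negative integer count matrix (features in
#' rows, samples in columns) together with the kind of feature it carries:
#' taxa (ASVs or genera) or predicted functional orthologs (FOs).
#'
#' @param counts Integer matrix, features x samples, with unique rownames
#'   (feature ids) and unique colnames (sample ids).
#' @param feature_kind Either `"taxon"` or `"functional_ortholog"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, feature_kind = c("taxon", "functional_ortholog")) {
  feature_kind <- match.arg(feature_kind)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"  # doubles avoid integer overflow on sums
  structure(list(counts = counts, feature_kind = feature_kind),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples, total reads %s\n",
              x$feature_kind, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Feature and sample ids of a feature table
#' @param x A `feature_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Subset a feature table by features and/or samples
#' @param x A `feature_table`.
#' @param features,samples Character vectors of ids (or indices) to keep,
#'   in the requested order; `NULL` keeps everything.
#' @return The subsetted `feature_table`.
#' @export
subset_feature_table <- function(x, features = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(features)) counts <- counts[features, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  structure(list(counts = counts, feature_kind = x$feature_kind),
            class = "feature_table")
}

#' Read a feature table from TSV
#'
#' Expects a tab-separated file whose header row carries sample ids (first
#' header cell `feature_id`) and whose first column carries feature ids.
#' Lines starting with `#` are treated as comments.
#'
#' @param path Path to the TSV file.
#' @param feature_kind Feature kind to stamp on the table.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, feature_kind = c("taxon", "functional_ortholog")) {
  feature_kind <- match.arg(feature_kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("feature table TSV needs a feature_id column plus samples")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count '%s' at feature '%s', sample '%s' in %s",
                 m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(m)[bad[1, 2]], path))
  rownames(num) <- ids
  feature_table(num, feature_kind)
}

#' Write a feature table to TSV
#'
#' Emits the canonical dialect: UTF-8, tab-separated, header starting with
#' the literal cell `feature_id`. Round-trips through [read_feature_table()].
#'
#' @param x A `feature_table`.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`), used by the pipeline for provenance.
#' @export
write_feature_table <- function(x, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("feature_id", colnames(x$counts)), collapse = "\t"), con)
  body <- apply(x$counts, 1, function(r) paste(format(r, scientific = FALSE, trim = TRUE),
                                               collapse = "\t"))
  writeLines(paste(rownames(x$counts), body, sep = "\t"), con)
  invisible(path)
}

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a taxonomy table
#'
#' Maps feature ids to six-rank lineages (domain, phylum, class, order,
#' family, genus). Empty strings mark unassigned ranks.
#'
#' @param feature_id Character vector of unique feature ids.
#' @param lineage Either a character matrix/data.frame with 6 columns or a
#'   character vector of semicolon-joined lineages (Silva style, `d__`-like
#'   prefixes tolerated and stripped).
#' @return An object of class `taxonomy_table` (a data.frame with columns
#'   `feature_id` and the six ranks).
#' @export
taxonomy_table <- function(feature_id, lineage) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop("duplicate feature ids in taxonomy")
  if (is.character(lineage) && is.null(dim(lineage))) {
    parts <- strsplit(lineage, ";", fixed = TRUE)
    lineage <- t(vapply(parts, function(p) {
      p <- trimws(p)
      p <- sub("^[a-z]__", "", p)
      length(p) <- 6L
      p[is.na(p)] <- ""
      p
    }, character(6)))
  }
  lineage <- as.matrix(lineage)
  if (ncol(lineage) != 6)
    stop("every lineage must have exactly 6 rank slots")
  lineage[is.na(lineage)] <- ""
  df <- data.frame(feature_id = feature_id, lineage, stringsAsFactors = FALSE)
  names(df) <- c("feature_id", .tax_ranks)
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read a taxonomy table from TSV
#'
#' Accepts either a two-column layout (`feature_id`, semicolon-joined
#' lineage) or a seven-column layout (`feature_id` plus one column per rank).
#'
#' @param path Path to the TSV file.
#' @return A `taxonomy_table`.
#' @export
read_taxonomy_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) == 2) {
    taxonomy_table(df[[1]], df[[2]])
  } else if (ncol(df) == 7) {
    taxonomy_table(df[[1]], as.matrix(df[, -1]))
  } else {
    stop("taxonomy TSV must have 2 (lineage string) or 7 (per-rank) columns")
  }
}

#' Write a taxonomy table to TSV (per-rank columns)
#' @param tax A `taxonomy_table`.
#' @param path Output path.
#' @export
write_taxonomy_table <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.segments <- c("duodenum", "jejunum", "ileum", "ceca", "feces")
.bird_types <- c("broiler", "layer", "other", "unspecified")
.continents <- c("Asia", "Europe", "NorthAmerica", "Africa", "Hawaii", "other")
.housings <- c("cages", "floor_pens", "mixed", "unspecified")

#' Construct per-sample metadata
#'
#' One row per sample, with the design factors of the meta-analysis. The
#' dataset id is always the combination of BioProject and intestinal
#' segment: a study contributes one dataset per segment it sampled.
#'
#' @param sample_id,bioproject_id Character vectors.
#' @param segment One of duodenum, jejunum, ileum, ceca, feces.
#' @param bird_type One of broiler, layer, other, unspecified.
#' @param continent One of Asia, Europe, NorthAmerica, Africa, Hawaii, other.
#' @param housing One of cages, floor_pens, mixed, unspecified.
#' @param doa Days of age (non-negative integer).
#' @param hv_region Sequenced hypervariable region label (e.g. "V3-V4").
#' @return An object of class `sample_metadata` (a data.frame keyed by
#'   `sample_id`, with a derived `dataset_id` column).
#' @export
sample_metadata <- function(sample_id, bioproject_id, segment, bird_type = "unspecified",
                            continent = "other", housing = "unspecified",
                            doa = 0L, hv_region = "unspecified") {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  segment <- match.arg(segment, .segments, several.ok = TRUE)
  df <- data.frame(sample_id = as.character(sample_id),
                   bioproject_id = rep_len(as.character(bioproject_id), n),
                   segment = factor(rep_len(segment, n), levels = .segments),
                   bird_type = factor(rep_len(bird_type, n), levels = .bird_types),
                   continent = factor(rep_len(continent, n), levels = .continents),
                   housing = factor(rep_len(housing, n), levels = .housings),
                   doa = rep_len(as.integer(doa), n),
                   hv_region = rep_len(as.character(hv_region), n),
                   stringsAsFactors = FALSE)
  if (anyNA(df$segment)) stop("unknown intestinal segment")
  if (anyNA(df$bird_type) || anyNA(df$continent) || anyNA(df$housing))
    stop("unknown factor level in metadata")
  if (any(df$doa < 0)) stop("doa must be >= 0")
  if (any(df$doa > 371))
    warning("doa above 371 days; outside the range of realistic corpora")
  df$dataset_id <- paste(df$bioproject_id, df$segment, sep = ".")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path Path to TSV with columns sample_id, bioproject_id, segment,
#'   bird_type, continent, housing, doa, hv_region.
#' @return A `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "bioproject_id", "segment", "bird_type", "continent",
            "housing", "doa", "hv_region")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("metadata TSV missing columns: ", paste(miss, collapse = ", "))
  sample_metadata(df$sample_id, df$bioproject_id, df$segment, df$bird_type,
                  df$continent, df$housing, as.integer(df$doa), df$hv_region)
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata`.
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  df <- as.data.frame(meta)
  df <- df[, c("sample_id", "bioproject_id", "segment", "bird_type", "continent",
               "housing", "doa", "hv_region", "dataset_id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

match_metadata <- function(table, meta) {
  idx <- match(sample_ids(table), meta$sample_id)
  if (anyNA(idx))
    stop("samples without metadata record: ",
         paste(sample_ids(table)[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
  meta[idx, , drop = FALSE]
}

#' Retain bacterial, non-organelle features
#'
#' Keeps features whose domain is `Bacteria` and whose lineage contains
#' neither `Mitochondria` nor `Chloroplast` at any rank (case-insensitive
#' substring match: Silva places mitochondria at family rank and
#' chloroplasts at order rank). Features without a taxonomy record are
#' dropped with a warning.
#'
#' @param table A taxon `feature_table`.
#' @param tax A `taxonomy_table`.
#' @return The filtered `feature_table`.
#' @export
filter_nonbacterial <- function(table, tax) {
  ids <- feature_ids(table)
  idx <- match(ids, tax$feature_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " features without a lineage were dropped")
  }
  keep <- !is.na(idx)
  lin <- as.matrix(as.data.frame(tax)[idx[keep], .tax_ranks, drop = FALSE])
  is_bact <- tolower(lin[, "domain"]) == "bacteria"
  contam <- apply(lin, 1, function(r) any(grepl("mitochondria|chloroplast", r,
                                                ignore.case = TRUE)))
  sel <- ids[keep][is_bact & !contam]
  if (length(sel) == 0) message("no bacterial features remain after filtering")
  subset_feature_table(table, features = sel)
}

#' Drop low-depth samples
#'
#' Removes samples whose total read count is strictly below `min_reads`
#' (the standard pruning rule: samples with less than 10,000 reads are
#' discarded; a sample with exactly `min_reads` reads is kept).
#'
#' @param table A `feature_table`.
#' @param min_reads Depth floor (default 10000).
#' @return The filtered `feature_table`.
#' @export
filter_low_depth <- function(table, min_reads = 10000) {
  stopifnot(min_reads >= 0)
  keep <- colSums(table$counts) >= min_reads
  subset_feature_table(table, samples = colnames(table$counts)[keep])
}

#' Drop features with zero total count
#' @param table A `feature_table`.
#' @return The filtered `feature_table`.
#' @export
prune_zero_features <- function(table) {
  keep <- rowSums(table$counts) > 0
  subset_feature_table(table, features = rownames(table$counts)[keep])
}

#' Collapse a feature table to a taxonomic rank
#'
#' Features sharing the same non-empty label at `rank` are summed.
#' Features with an empty label at `rank` are grouped under a synthetic
#' `unclassified:<lowest non-empty higher-rank label>` feature so that
#' per-sample column sums are conserved exactly.
#'
#' @param table A taxon `feature_table`.
#' @param tax A `taxonomy_table` covering every feature in `table`.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @return A `feature_table` with one row per collapsed label.
#' @export
collapse_to_rank <- function(table, tax, rank = "genus") {
  rank <- match.arg(rank, .tax_ranks)
  ids <- feature_ids(table)
  idx <- match(ids, tax$feature_id)
  if (anyNA(idx)) stop("features without a lineage cannot be collapsed")
  lin <- as.data.frame(tax)[idx, .tax_ranks, drop = FALSE]
  k <- match(rank, .tax_ranks)
  label <- lin[[rank]]
  empty <- is.na(label) | label == ""
  if (any(empty)) {
    parent <- apply(lin[empty, seq_len(k), drop = FALSE], 1, function(r) {
      r <- r[!is.na(r) & r != ""]
      if (length(r) == 0) "root" else r[length(r)]
    })
    label[empty] <- paste0("unclassified:", parent)
  }
  collapsed <- rowsum(table$counts, group = label, reorder = TRUE)
  feature_table(collapsed, table$feature_kind)
}
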