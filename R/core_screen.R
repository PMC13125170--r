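#' Per-dataset prevalence of each genus
#'
#' Prevalence is the fraction of a dataset's samples in which the genus is
#' detected (count > 0). No relative-abundance floor is applied: presence
#' means detection.
#'
#' @param table Genus-level `feature_table` (filtered).
#' @param meta A `sample_metadata` covering the table's samples.
#' @return An object of class `prevalence_matrix`: list with `prev`
#'   (genus x dataset matrix in [0,1]) and `n_samples` (named integer
#'   vector per dataset). Datasets with zero samples are excluded.
#' @export
prevalence_by_dataset <- function(table, meta) {
  meta <- match_metadata(table, meta)
  ds <- factor(meta$dataset_id)
  present <- table$counts > 0
  n <- table(ds)[levels(ds)]
  prev <- t(rowsum(t(present * 1), group = ds, reorder = TRUE)) /
    rep(as.integer(n), each = nrow(present))
  structure(list(prev = prev,
                 n_samples = stats::setNames(as.integer(n), levels(ds))),
            class = "prevalence_matrix")
}

#' @export
print.prevalence_matrix <- function(x, ...) {
  cat(sprintf("prevalence_matrix: %d genera x %d datasets\n",
              nrow(x$prev), ncol(x$prev)))
  invisible(x)
}

#' Dual-threshold core genus screen
#'
#' A genus is core when its prevalence exceeds `t1` percent in more than
#' `t2` percent of datasets. Both inequalities are strict ("more than"):
#' a genus present in exactly `t1`% of a dataset's samples does not pass
#' threshold 1 in that dataset, and a genus passing threshold 1 in exactly
#' `t2`% of datasets is not core.
#'
#' @param prev A `prevalence_matrix`.
#' @param t1 Threshold 1, percent prevalence within a dataset (0-100).
#' @param t2 Threshold 2, percent of datasets exceeding threshold 1.
#' @return Character vector of core genus ids.
#' @export
core_genera <- function(prev, t1 = 80, t2 = 50) {
  stopifnot(inherits(prev, "prevalence_matrix"),
            t1 > 0, t1 < 100, t2 > 0, t2 < 100)
  nd <- ncol(prev$prev)
  frac <- rowSums(prev$prev > t1 / 100) / nd
  rownames(prev$prev)[frac > t2 / 100]
}

#' Summary statistics for a core set
#'
#' @param core Character vector of core genus ids.
#' @param profiles A `dataset_profiles` over the same scope (for cumulative
#'   relative abundance via [grand_mean_relabund()]).
#' @param all_genera Character vector of all genera detected in scope.
#' @return data.frame with `n_core`, `cum_pct` (percent of all genera) and
#'   `cum_relabund` (summed grand-mean relative abundance).
#' @export
core_summary <- function(core, profiles, all_genera) {
  stopifnot(all(core %in% all_genera))
  gm <- grand_mean_relabund(profiles)
  data.frame(n_core = length(core),
             cum_pct = if (length(all_genera) > 0)
               100 * length(core) / length(all_genera) else 0,
             cum_relabund = sum(gm[intersect(core, names(gm))]))
}

#' Core screen over a threshold grid
#'
#' Evaluates [core_genera()] at every pair of threshold values (25 cells
#' for the default grid of 50/60/70/80/90 percent on both axes) and, when
#' profiles are supplied, attaches the summary statistics.
#'
#' @param prev A `prevalence_matrix`.
#' @param thresholds Percent values tested for both thresholds.
#' @param profiles Optional `dataset_profiles` for cumulative abundances.
#' @param label Optional scope label (e.g. segment name) carried through.
#' @return data.frame with one row per (t1, t2) cell: `t1`, `t2`, `label`,
#'   `n_core`, `cum_pct`, `cum_relabund`, and a list-column `core_set`.
#' @export
core_screen_grid <- function(prev, thresholds = c(50, 60, 70, 80, 90),
                             profiles = NULL, label = "all") {
  stopifnot(!is.unsorted(thresholds), !anyDuplicated(thresholds))
  all_genera <- rownames(prev$prev)
  cells <- expand.grid(t1 = thresholds, t2 = thresholds)
  sets <- lapply(seq_len(nrow(cells)),
                 function(i) core_genera(prev, cells$t1[i], cells$t2[i]))
  out <- data.frame(t1 = cells$t1, t2 = cells$t2, label = label,
                    n_core = lengths(sets),
                    cum_pct = 100 * lengths(sets) / max(1, length(all_genera)),
                    cum_relabund = NA_real_)
  if (!is.null(profiles)) {
    gm <- grand_mean_relabund(profiles)
    out$cum_relabund <- vapply(sets, function(s) sum(gm[intersect(s, names(gm))]),
                               numeric(1))
  }
  out$core_set <- sets
  out
}

#' Write a core screen grid as TSV (without the list column)
#' @param grid Output of [core_screen_grid()].
#' @param path Output path.
#' @export
write_core_grid <- function(grid, path) {
  utils::write.table(grid[, setdiff(names(grid), "core_set")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
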