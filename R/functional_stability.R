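#' Median-of-ratios size factors
#'
#' Per-feature geometric means are computed over samples (features with
#' any zero count are excluded from the reference), and each sample's
#' size factor is the median over features of count / geometric mean.
#' When no feature is positive in every sample, the ratios fall back to
#' each sample's positive entries, with a warning.
#'
#' @param table A `feature_table`.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(table) {
  m <- table$counts
  log_m <- log(m)
  log_geo <- rowMeans(log_m)                     # -Inf where any zero
  use <- is.finite(log_geo)
  if (any(use)) {
    sf <- apply(log_m[use, , drop = FALSE], 2,
                function(col) exp(stats::median(col - log_geo[use])))
  } else {
    warning("no feature positive in all samples; using per-sample positive ratios")
    log_geo_pos <- apply(log_m, 1, function(r) mean(r[is.finite(r)]))
    sf <- apply(log_m, 2, function(col) {
      ok <- is.finite(col) & is.finite(log_geo_pos)
      if (!any(ok)) stop("sample with no positive counts")
      exp(stats::median(col[ok] - log_geo_pos[ok]))
    })
  }
  stats::setNames(sf, colnames(m))
}

#' Per-feature negative-binomial dispersion
#'
#' A transparent two-step estimator: a method-of-moments estimate on
#' size-factor-normalized counts pooled within condition levels,
#' alpha = max(0, (s^2 - mu) / mu^2), followed by shrinkage toward a
#' fitted mean-dispersion trend alpha_tr(mu) = a0 + a1/mu on the log
#' scale with weight n / (n + 20). Features whose moment estimate hits
#' zero (at or under-dispersed) are floored at 1e-8 rather than shrunk.
#'
#' @param table An FO `feature_table`.
#' @param condition Two-level factor, one level per sample, >= 2 samples
#'   per level.
#' @param sf Optional precomputed size factors.
#' @return Named numeric vector of dispersions (floor 1e-8).
#' @export
estimate_dispersion <- function(table, condition, sf = NULL) {
  condition <- droplevels(factor(condition))
  stopifnot(nlevels(condition) == 2, all(table(condition) >= 2))
  if (is.null(sf)) sf <- size_factors(table)
  norm <- sweep(table$counts, 2, sf, "/")
  floor_a <- 1e-8
  n <- ncol(norm)
  lev <- levels(condition)
  mom_level <- function(sub) {
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, stats::var)
    a <- (s2 - mu) / mu^2
    a[!is.finite(a)] <- 0
    pmax(a, 0)
  }
  w_lev <- as.integer(table(condition)[lev]) - 1L
  a_mom <- (mom_level(norm[, condition == lev[1], drop = FALSE]) * w_lev[1] +
            mom_level(norm[, condition == lev[2], drop = FALSE]) * w_lev[2]) /
    sum(w_lev)
  mu_all <- rowMeans(norm)
  # parametric trend a0 + a1/mu, fitted on features with a usable estimate
  ok <- a_mom > floor_a & mu_all > 0
  trend <- rep(floor_a, length(a_mom))
  if (sum(ok) >= 10) {
    co <- stats::coef(stats::lm(a_mom[ok] ~ I(1 / mu_all[ok])))
    trend <- pmax(co[1] + co[2] / mu_all, floor_a)
  } else if (any(ok)) {
    trend <- rep(max(stats::median(a_mom[ok]), floor_a), length(a_mom))
  }
  w <- n / (n + 20)
  out <- ifelse(a_mom <= floor_a, floor_a,
                exp(w * log(a_mom) + (1 - w) * log(trend)))
  stats::setNames(pmax(out, floor_a), rownames(norm))
}

#' Negative-binomial Wald test per functional ortholog
#'
#' For each FO, fits a negative-binomial GLM with log link,
#' log size factor offset and the two-level condition as the single
#' covariate, with the dispersion fixed at the [estimate_dispersion()]
#' value. The Wald statistic is the condition coefficient over its
#' standard error, with a two-sided normal p-value, BH-adjusted across
#' tested FOs. An FO is flagged non-differential (nDFO) when its adjusted
#' p-value is present and at or above `alpha`. Non-convergent fits get
#' missing p-values and are excluded from the BH universe.
#'
#' @param table An FO `feature_table` containing both groups' samples.
#' @param condition Two-level factor over the table's samples.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return data.frame of class `differential_result`: `fo_id`,
#'   `base_mean`, `log2fc`, `se`, `wald`, `p`, `padj`, `is_ndfo`.
#' @export
nb_wald_test <- function(table, condition, alpha = 0.05) {
  condition <- droplevels(factor(condition))
  stopifnot(nlevels(condition) == 2)
  sf <- size_factors(table)
  disp <- estimate_dispersion(table, condition, sf = sf)
  off <- log(sf)
  m <- table$counts
  nfo <- nrow(m)
  out <- data.frame(fo_id = rownames(m),
                    base_mean = rowMeans(sweep(m, 2, sf, "/")),
                    log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                    p = NA_real_, padj = NA_real_, is_ndfo = NA)
  x <- condition
  for (i in seq_len(nfo)) {
    theta <- 1 / max(disp[i], 1e-8)
    fit <- tryCatch(
      suppressWarnings(stats::glm(m[i, ] ~ x + offset(off),
                                  family = MASS::negative.binomial(theta))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    sm <- summary(fit, dispersion = 1)$coefficients
    if (nrow(sm) < 2 || !is.finite(sm[2, 2]) || sm[2, 2] <= 0) next
    beta <- sm[2, 1]; se <- sm[2, 2]
    out$log2fc[i] <- beta / log(2)
    out$se[i] <- se / log(2)
    out$wald[i] <- beta / se
    out$p[i] <- 2 * stats::pnorm(-abs(beta / se))
  }
  tested <- !is.na(out$p)
  out$padj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$is_ndfo <- !is.na(out$padj) & out$padj >= alpha
  out$is_ndfo[!tested] <- NA
  attr(out, "alpha") <- alpha
  attr(out, "condition_levels") <- levels(condition)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Non-differential FO set from a comparison
#'
#' FOs whose adjusted p-value is present and at or above `alpha`. FOs
#' with a missing adjusted p (untestable) belong to neither the nDFO set
#' nor the comparison's universe.
#'
#' @param results A `differential_result`.
#' @param alpha Threshold (default 0.05).
#' @return Character vector of nDFO ids; attribute `universe` carries the
#'   tested FO ids.
#' @export
classify_ndfo <- function(results, alpha = 0.05) {
  tested <- results$fo_id[!is.na(results$padj)]
  nd <- results$fo_id[!is.na(results$padj) & results$padj >= alpha]
  attr(nd, "universe") <- tested
  nd
}

#' Pairwise stability matrix
#'
#' For every unordered pair of group levels, runs the NB Wald test on the
#' two groups' samples restricted to FOs detected (nonzero total) in both
#' groups, and records the nDFO count and its percentage of that pair's
#' tested universe. Pairs where a group has fewer than 2 samples are
#' reported as not available.
#'
#' @param table An FO `feature_table`.
#' @param groups Factor of group labels over the table's samples (>= 2
#'   levels).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param universe `"intersection"` (FOs detected in both groups, default)
#'   or `"union"` (detected in either).
#' @return An object of class `stability_matrix`: list with `labels`,
#'   `pairs` (data.frame: group1, group2, n_ndfo, n_universe, pct_ndfo),
#'   and `ndfo_sets` (named list of nDFO id vectors per pair).
#' @export
pairwise_stability <- function(table, groups, alpha = 0.05,
                               universe = c("intersection", "union")) {
  universe <- match.arg(universe)
  groups <- droplevels(factor(groups))
  stopifnot(length(groups) == ncol(table$counts), nlevels(groups) >= 2)
  lev <- levels(groups)
  combos <- utils::combn(lev, 2)
  rows <- list(); sets <- list(); unis <- list()
  for (k in seq_len(ncol(combos))) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    key <- paste(g1, g2, sep = " vs ")
    s1 <- which(groups == g1); s2 <- which(groups == g2)
    if (length(s1) < 2 || length(s2) < 2) {
      rows[[k]] <- data.frame(group1 = g1, group2 = g2, n_ndfo = NA_integer_,
                              n_universe = NA_integer_, pct_ndfo = NA_real_)
      sets[[key]] <- NULL
      next
    }
    sub <- subset_feature_table(table, samples = colnames(table$counts)[c(s1, s2)])
    det1 <- rowSums(table$counts[, s1, drop = FALSE]) > 0
    det2 <- rowSums(table$counts[, s2, drop = FALSE]) > 0
    keep <- if (universe == "intersection") det1 & det2 else det1 | det2
    sub <- subset_feature_table(sub, features = rownames(sub$counts)[keep])
    cond <- factor(c(rep(g1, length(s1)), rep(g2, length(s2))), levels = c(g1, g2))
    res <- nb_wald_test(sub, cond, alpha = alpha)
    nd <- classify_ndfo(res, alpha = alpha)
    uni <- attr(nd, "universe")
    rows[[k]] <- data.frame(group1 = g1, group2 = g2,
                            n_ndfo = length(nd), n_universe = length(uni),
                            pct_ndfo = if (length(uni) > 0)
                              100 * length(nd) / length(uni) else NA_real_)
    sets[[key]] <- as.character(nd)
    unis[[key]] <- as.character(uni)
  }
  structure(list(labels = lev, pairs = do.call(rbind, rows), ndfo_sets = sets,
                 universes = unis, alpha = alpha, universe = universe),
            class = "stability_matrix")
}

#' Square layout of a stability matrix
#'
#' Percentages above the diagonal, absolute nDFO counts below, matching
#' the conventional presentation of pairwise stability tables.
#'
#' @param x A `stability_matrix`.
#' @return Numeric matrix with group labels as dimnames.
#' @export
stability_square <- function(x) {
  lev <- x$labels
  m <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(x$pairs))) {
    g1 <- x$pairs$group1[i]; g2 <- x$pairs$group2[i]
    m[g1, g2] <- x$pairs$pct_ndfo[i]   # upper triangle: percentage
    m[g2, g1] <- x$pairs$n_ndfo[i]     # lower triangle: count
  }
  m
}

#' @export
print.stability_matrix <- function(x, ...) {
  cat(sprintf("stability_matrix over %d groups (alpha = %g, %s universe)\n",
              length(x$labels), x$alpha, x$universe))
  print(round(stability_square(x), 1))
  invisible(x)
}

#' Intersections of nDFO sets (upset semantics)
#'
#' Builds the membership matrix of FOs across comparisons, counts every
#' exclusive membership combination (the bars of an upset plot), and
#' extracts the conserved set: FOs non-differential in every comparison.
#'
#' @param sets Named list of >= 2 FO id vectors.
#' @return An object of class `intersection_set`: `membership` (logical
#'   FO x comparison matrix), `combination_counts` (data.frame: pattern,
#'   degree, count), and `conserved` (character vector).
#' @export
intersect_ndfo <- function(sets) {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("cmp", seq_along(sets))
  ids <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(ids, names(sets)))
  rownames(memb) <- ids
  pattern <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  counts <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(counts) <- c("pattern", "count")
  counts$degree <- lengths(strsplit(counts$pattern, "&", fixed = TRUE))
  counts <- counts[order(-counts$degree, -counts$count), c("pattern", "degree", "count")]
  rownames(counts) <- NULL
  structure(list(membership = memb, combination_counts = counts,
                 conserved = ids[rowSums(memb) == length(sets)]),
            class = "intersection_set")
}

#' @export
print.intersection_set <- function(x, ...) {
  cat(sprintf("intersection_set: %d FOs over %d comparisons; %d conserved\n",
              nrow(x$membership), ncol(x$membership), length(x$conserved)))
  invisible(x)
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap k when n query FOs are drawn from a
#' universe of N FOs containing K pathway members:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n). Gene ratio is k/n.
#' P-values are BH-adjusted across pathways.
#'
#' @param query FO id set of interest (e.g. conserved nDFOs), subset of
#'   `universe`.
#' @param pathways Named list mapping pathway id to FO id vectors;
#'   memberships are intersected with the universe.
#' @param universe FO id universe the query was drawn from.
#' @return data.frame of class `enrichment_result`: `pathway_id`, `k`,
#'   `K`, `n`, `N`, `gene_ratio`, `p`, `padj`, ordered by `padj`.
#' @export
enrich_pathways <- function(query, pathways, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(universe) == 0 || length(query) == 0)
    stop("query and universe must be non-empty")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(pathways), function(pid) {
    memb <- intersect(pathways[[pid]], universe)
    K <- length(memb)
    k <- length(intersect(memb, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, k = k, K = K, n = n, N = N,
               gene_ratio = k / n, p = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$padj, out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write differential results / stability / enrichment tables as TSV
#' @param x The result object.
#' @param path Output path.
#' @name stability_io
#' @export
write_differential_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname stability_io
#' @export
write_stability_matrix <- function(x, path) {
  sq <- stability_square(x)
  df <- data.frame(group = rownames(sq), sq, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
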