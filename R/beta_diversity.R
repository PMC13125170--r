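#' Bray-Curtis dissimilarity matrix
#'
#' BC(j,k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik), computed on raw
#' counts by default (no rarefaction or transform). Set
#' `proportions = TRUE` to normalize each sample to proportions first.
#'
#' @param table A `feature_table` (usually genus-collapsed) with positive
#'   column sums.
#' @param proportions Normalize samples to proportions before computing?
#' @return An object of class `distance_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal, entries in [0,1]) and `sample_ids`.
#' @export
bray_curtis <- function(table, proportions = FALSE) {
  m <- table$counts
  tot <- colSums(m)
  if (any(tot == 0))
    stop("zero-depth sample: ", colnames(m)[which(tot == 0)[1]])
  if (proportions) m <- sweep(m, 2, tot, "/")
  tot <- colSums(m)
  num <- as.matrix(stats::dist(t(m), method = "manhattan"))
  den <- outer(tot, tot, "+")
  d <- num / den
  diag(d) <- 0
  distance_matrix(d)
}

#' Construct a distance matrix object
#' @param d Symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @return A `distance_matrix`.
#' @export
distance_matrix <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("distance matrix must have zero diagonal")
  structure(list(d = (d + t(d)) / 2, sample_ids = rownames(d)),
            class = "distance_matrix")
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Coordinates are returned for positive eigenvalues (eigenvector scaled
#' by the square root of its eigenvalue); negative eigenvalues are
#' reported but contribute no axis.
#'
#' @param d A `distance_matrix`.
#' @param eps Eigenvalues within `eps * max(|eigenvalue|)` of zero are
#'   treated as zero.
#' @return An object of class `pcoa_result`: `coordinates` (samples x
#'   positive axes), `eigenvalues` (all, descending), and
#'   `proportion_explained` over positive eigenvalues.
#' @export
pcoa <- function(d, eps = 1e-9) {
  D <- d$d
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values
  tol <- eps * max(abs(lam), 1)
  pos <- which(lam > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]), length(pos))
  rownames(coords) <- d$sample_ids
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = lam,
                 proportion_explained = if (length(pos) > 0)
                   lam[pos] / sum(lam[pos]) else numeric(0),
                 negative_axes = e$vectors[, lam < -tol, drop = FALSE] %*%
                   diag(sqrt(abs(lam[lam < -tol])), sum(lam < -tol))),
            class = "pcoa_result")
}

permanova_stats <- function(D2, group_idx, n_per_group, n, a) {
  # group_idx: list of integer index vectors per group
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in seq_along(group_idx)) {
    idx <- group_idx[[g]]
    ss_within <- ss_within + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) /
      n_per_group[g]
  }
  ss_between <- ss_total - ss_within
  eps <- 1e-12 * max(ss_total, 1e-300)
  f <- if (ss_within <= eps) {
    if (ss_between <= eps) 0 else Inf
  } else (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = if (ss_total > eps) ss_between / ss_total else 0)
}

#' One-factor PERMANOVA
#'
#' Partitions squared dissimilarities among groups and tests the pseudo-F
#' by random relabeling. The p-value includes the observed statistic:
#' p = (1 + #\{permuted F >= observed\}) / (1 + n_perm). With all samples
#' identical (total sum of squares zero) F is defined as 0 and p as 1.
#'
#' @param d A `distance_matrix`.
#' @param groups Factor (or coercible) of group labels, one per sample;
#'   >= 2 groups with >= 1 sample each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param factor_name Label carried into the result row.
#' @param strata Optional factor (e.g. BioProject); when given, labels are
#'   permuted only within strata, respecting the nesting of samples in
#'   studies.
#' @return data.frame of class `permanova_result` with `factor_name`,
#'   `pseudo_f`, `r2`, `p`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1,
                      factor_name = "groups", strata = NULL) {
  groups <- droplevels(factor(groups))
  n <- nrow(d$d)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 1)) stop("empty group")
  D2 <- d$d^2
  a <- nlevels(groups)
  split_idx <- function(g) split(seq_len(n), g)
  idx <- split_idx(groups)
  npg <- as.integer(table(groups)[names(idx)])
  obs <- permanova_stats(D2, idx, npg, n, a)
  if (obs["f"] == 0 && obs["r2"] == 0 && sum(D2) == 0) {
    res <- data.frame(factor_name = factor_name, pseudo_f = 0, r2 = 0, p = 1,
                      n_permutations = n_perm)
    class(res) <- c("permanova_result", "data.frame")
    return(res)
  }
  if (!is.null(strata)) {
    strata <- factor(strata)
    stopifnot(length(strata) == n)
    str_idx <- split(seq_len(n), strata)
    permute_groups <- function() {
      out <- groups
      for (ii in str_idx) out[ii] <- groups[ii][sample.int(length(ii))]
      out
    }
  } else {
    permute_groups <- function() sample(groups)
  }
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    pidx <- split_idx(permute_groups())
    fperm <- permanova_stats(D2, pidx, as.integer(table(groups)[names(pidx)]),
                             n, a)["f"]
    if (fperm >= obs["f"]) ge <- ge + 1L
  }
  res <- data.frame(factor_name = factor_name,
                    pseudo_f = unname(obs["f"]), r2 = unname(obs["r2"]),
                    p = (1 + ge) / (1 + n_perm), n_permutations = n_perm)
  class(res) <- c("permanova_result", "data.frame")
  res
}

#' Distances to group centers in principal-coordinate space
#'
#' Embeds the distance matrix by PCoA, keeping negative-eigenvalue axes
#' with their sign: the squared distance of a sample to its group center
#' is the positive-axis squared distance minus the negative-axis squared
#' distance (truncated at zero before the square root), the standard
#' sign-handled construction for semi-metric dissimilarities.
#'
#' @param d A `distance_matrix`.
#' @param groups Factor of group labels.
#' @param center `"centroid"` (mean in the embedded space, default) or
#'   `"median"` (coordinate-wise median).
#' @return Numeric vector of distances to own-group center.
#' @keywords internal
group_center_distances <- function(d, groups, center = c("centroid", "median")) {
  center <- match.arg(center)
  pc <- pcoa(d)
  pos <- pc$coordinates
  neg <- pc$negative_axes
  cen_fun <- if (center == "centroid") colMeans else
    function(m) apply(m, 2, stats::median)
  out <- numeric(nrow(pos))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    cp <- cen_fun(pos[idx, , drop = FALSE])
    d2 <- rowSums(sweep(pos[idx, , drop = FALSE], 2, cp)^2)
    if (!is.null(neg) && ncol(neg) > 0) {
      cn <- cen_fun(neg[idx, , drop = FALSE])
      d2 <- d2 - rowSums(sweep(neg[idx, , drop = FALSE], 2, cn)^2)
    }
    out[idx] <- sqrt(pmax(d2, 0))
  }
  out
}

#' Homogeneity-of-dispersion test
#'
#' Computes each sample's distance to its group center in the
#' PCoA-embedded space, then tests equality of mean distances across
#' groups with a one-way ANOVA F plus a permutation p-value for the same
#' F (group labels permuted). Groups of a single sample are excluded with
#' a warning.
#'
#' @param d A `distance_matrix`.
#' @param groups Factor of group labels; >= 2 groups of >= 2 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param center Group center type, `"centroid"` or `"median"`.
#' @return An object of class `dispersion_result`: list with `distances`
#'   (per retained sample), `groups`, `f`, `p_anova`, `p_perm`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = 1,
                            center = c("centroid", "median")) {
  center <- match.arg(center)
  groups <- droplevels(factor(groups))
  stopifnot(length(groups) == nrow(d$d))
  small <- names(which(table(groups) < 2))
  if (length(small) > 0) {
    warning("excluding single-sample groups: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    d <- distance_matrix(d$d[keep, keep, drop = FALSE])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups of >= 2 samples")
  dist_c <- group_center_distances(d, groups, center)
  f_stat <- function(y, g) {
    m <- tapply(y, g, mean)
    ng <- tapply(y, g, length)
    a <- nlevels(g); n <- length(y)
    ssb <- sum(ng * (m - mean(y))^2)
    ssw <- sum((y - m[g])^2)
    eps <- 1e-12 * max(ssb + ssw, sum(y^2), 1e-300)
    if (ssw <= eps) { if (ssb <= eps) 0 else Inf }
    else (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(dist_c, groups)
  p_anova <- if (f_obs == 0) 1 else
    stats::pf(f_obs, nlevels(groups) - 1, length(dist_c) - nlevels(groups),
              lower.tail = FALSE)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (f_stat(dist_c, sample(groups)) >= f_obs) ge <- ge + 1L
  }
  structure(list(distances = dist_c, groups = groups, f = f_obs,
                 p_anova = p_anova, p_perm = (1 + ge) / (1 + n_perm),
                 n_permutations = n_perm, center = center),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity (%s): F = %.4g, ANOVA p = %.4g, permutation p = %.4g\n",
              x$center, x$f, x$p_anova, x$p_perm))
  invisible(x)
}

#' Categorize days of age
#'
#' Bins: less than 5, 5 to 9, 10 to 19, 20 to 49, and 50 days or older
#' (age exactly 50 belongs to the oldest bin).
#'
#' @param doa Integer vector of days of age, >= 0.
#' @return Factor with levels `<5`, `5-9`, `10-19`, `20-49`, `>=50`.
#' @export
age_categorize <- function(doa) {
  if (any(doa < 0)) stop("doa must be >= 0")
  cut(doa, breaks = c(-Inf, 4, 9, 19, 49, Inf),
      labels = c("<5", "5-9", "10-19", "20-49", ">=50"))
}

#' Write a distance matrix as square TSV with header
#' @param d A `distance_matrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = d$sample_ids, d$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
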