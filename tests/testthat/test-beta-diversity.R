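test_that("Bray-Curtis matches hand evaluation and the bounds", {
  m <- cbind(s1 = c(6, 2, 0), s2 = c(2, 2, 0), s3 = c(6, 2, 0), s4 = c(0, 0, 9))
  rownames(m) <- c("g1", "g2", "g3")
  d <- bray_curtis(feature_table(m))
  expect_equal(d$d["s1", "s2"], 4 / 12)
  expect_equal(d$d["s1", "s3"], 0)          # identical columns
  expect_equal(d$d["s1", "s4"], 1)          # disjoint supports
  expect_true(all(d$d >= 0 & d$d <= 1))
  expect_equal(d$d, t(d$d))
})

test_that("Bray-Curtis agrees with vegan on a random table", {
  skip_if_not_installed("vegan")
  tab <- random_table(nf = 15, ns = 8, seed = 5)
  d <- bray_curtis(tab)
  ref <- as.matrix(vegan::vegdist(t(tab$counts), method = "bray"))
  expect_equal(unname(d$d), unname(ref), tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  x <- c(0, 1, 3.5)  # collinear points
  d <- distance_matrix(as.matrix(dist(x)))
  pc <- pcoa(d)
  expect_identical(ncol(pc$coordinates), 1L)
  rec <- as.matrix(dist(pc$coordinates))
  expect_equal(unname(rec), unname(d$d), tolerance = 1e-9)
  # eigenvalues sorted descending
  expect_true(!is.unsorted(rev(pc$eigenvalues)))
})

test_that("a regular simplex gives equal positive eigenvalues", {
  n <- 5
  m <- matrix(1, n, n) - diag(n)
  rownames(m) <- colnames(m) <- paste0("s", 1:n)
  pc <- pcoa(distance_matrix(m))
  pos <- pc$eigenvalues[pc$eigenvalues > 1e-9]
  expect_length(pos, n - 1)
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-9)
  # duplicating a point adds a zero eigenvalue, not a positive one
  m2 <- rbind(cbind(m, m[, 1]), c(m[1, ], 0))
  rownames(m2) <- colnames(m2) <- paste0("s", 1:(n + 1))
  pc2 <- pcoa(distance_matrix(m2))
  expect_length(pc2$eigenvalues[pc2$eigenvalues > 1e-9], n - 1)
})

test_that("PCoA agrees with ape on a Bray-Curtis matrix", {
  skip_if_not_installed("ape")
  tab <- random_table(nf = 12, ns = 7, seed = 8)
  d <- bray_curtis(tab)
  pc <- pcoa(d)
  ref <- ape::pcoa(as.dist(d$d))
  k <- min(ncol(pc$coordinates), ncol(ref$vectors))
  expect_equal(abs(pc$coordinates[, 1:k]), abs(ref$vectors[, 1:k]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PERMANOVA matches vegan's statistic on a fixture", {
  skip_if_not_installed("vegan")
  tab <- random_table(nf = 15, ns = 12, seed = 12)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  d <- bray_curtis(tab)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d$d) ~ g, permutations = 99)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA handles degenerate and permuted inputs consistently", {
  m <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  d <- bray_curtis(feature_table(m))
  res <- permanova(d, rep(c("a", "b"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res$pseudo_f, 0)
  expect_equal(res$p, 1)
  # relabeling rows/columns together with labels leaves p unchanged
  tab <- random_table(nf = 10, ns = 8, seed = 14)
  g <- factor(rep(c("a", "b"), each = 4))
  d1 <- bray_curtis(tab)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  d2 <- distance_matrix(d1$d[perm, perm])
  r1 <- permanova(d1, g, n_perm = 199, seed = 5)
  r2 <- permanova(d2, g[perm], n_perm = 199, seed = 5)
  expect_equal(r1$pseudo_f, r2$pseudo_f)
  # fixed seed means bit-reproducible p
  expect_identical(permanova(d1, g, n_perm = 99, seed = 9)$p,
                   permanova(d1, g, n_perm = 99, seed = 9)$p)
})

test_that("stratified permutations respect study nesting", {
  tab <- random_table(nf = 10, ns = 8, seed = 20)
  d <- bray_curtis(tab)
  g <- factor(rep(c("a", "b"), each = 4))
  # groups constant within strata: within-stratum shuffles change nothing
  res <- permanova(d, g, n_perm = 49, seed = 2, strata = g)
  expect_equal(res$p, 1)
  # strata finer than groups still permit a real test
  strata <- factor(rep(1:4, each = 2))
  res2 <- permanova(d, g, n_perm = 49, seed = 2, strata = strata)
  expect_gte(res2$p, 1 / 50)
})

test_that("dispersion distances agree with vegan's centroid betadisper", {
  skip_if_not_installed("vegan")
  tab <- random_table(nf = 15, ns = 12, seed = 16)
  g <- factor(rep(c("a", "b"), each = 6))
  d <- bray_curtis(tab)
  res <- dispersion_test(d, g, n_perm = 99, seed = 1)
  ref <- vegan::betadisper(as.dist(d$d), g, type = "centroid")
  expect_equal(unname(res$distances), unname(ref$distances), tolerance = 1e-8)
})

test_that("dispersion test flags identical distance multisets as null", {
  # two congruent triangles in 3-space: identical within-group geometry
  tri <- cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2), 0)
  pts <- rbind(tri, sweep(tri, 2, c(0, 0, 10), "+"))
  rownames(pts) <- paste0("s", 1:6)
  res <- dispersion_test(distance_matrix(as.matrix(dist(pts))),
                         rep(c("a", "b"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res$f, 0)
  expect_equal(res$p_perm, 1)
  expect_equal(res$p_anova, 1)
})

test_that("single-sample groups are excluded with a warning", {
  tab <- random_table(nf = 10, ns = 7, seed = 18)
  g <- factor(c(rep("a", 3), rep("b", 3), "c"))
  d <- bray_curtis(tab)
  expect_warning(res <- dispersion_test(d, g, n_perm = 49, seed = 1),
                 "single-sample")
  expect_length(res$distances, 6)
})

test_that("age categories follow the published bins with 50 in the oldest", {
  expect_equal(as.character(age_categorize(c(0, 4, 5, 9, 10, 19, 20, 49, 50, 120))),
               c("<5", "<5", "5-9", "5-9", "10-19", "10-19",
                 "20-49", "20-49", ">=50", ">=50"))
  expect_error(age_categorize(-1), ">= 0")
})
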