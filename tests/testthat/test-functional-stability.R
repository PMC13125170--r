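test_that("size factors follow the median-of-ratios closed form", {
  m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  rownames(m) <- paste0("f", 1:3)
  sf <- size_factors(feature_table(m, "functional_ortholog"))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(sf[["B"]] / sf[["A"]], 2)
  # identical samples -> equal factors
  m2 <- cbind(A = c(5, 9), B = c(5, 9), C = c(5, 9))
  rownames(m2) <- c("f1", "f2")
  expect_equal(unname(size_factors(feature_table(m2, "functional_ortholog"))),
               rep(1, 3))
  # scaling one sample by c multiplies its factor by c, relative to the rest
  # (the absolute factors shift together through the geometric-mean reference)
  m3 <- m; m3[, "B"] <- m3[, "B"] * 3
  sf3 <- size_factors(feature_table(m3, "functional_ortholog"))
  expect_equal(sf3[["B"]] / sf3[["A"]], 3 * sf[["B"]] / sf[["A"]])
})

test_that("size factors fall back to positive entries when needed", {
  m <- cbind(A = c(10, 0), B = c(0, 10))
  rownames(m) <- c("f1", "f2")
  expect_warning(sf <- size_factors(feature_table(m, "functional_ortholog")),
                 "positive ratios")
  expect_true(all(sf > 0))
})

test_that("dispersion estimates track the generating model", {
  set.seed(7)
  n <- 50
  cond <- factor(rep(c("a", "b"), each = n / 2))
  mu <- exp(rnorm(200, 4, 0.5))
  pois <- matrix(rpois(200 * n, mu), 200, n,
                 dimnames = list(sprintf("f%03d", 1:200), sprintf("s%02d", 1:n)))
  d_pois <- estimate_dispersion(feature_table(pois, "functional_ortholog"), cond)
  expect_lt(median(d_pois), 0.05)
  nb <- matrix(rnbinom(200 * n, mu = mu, size = 2), 200, n,
               dimnames = dimnames(pois))
  d_nb <- estimate_dispersion(feature_table(nb, "functional_ortholog"), cond)
  expect_gt(median(d_nb), 0.3)
  expect_lt(median(d_nb), 0.7)
  # constant feature sits at the floor
  const <- rbind(pois, fconst = rep(50, n))
  d_c <- estimate_dispersion(feature_table(const, "functional_ortholog"), cond)
  expect_equal(unname(d_c["fconst"]), 1e-8)
})

test_that("identical groups give zero fold change and p near 1", {
  half <- matrix(rpois(80, 20), 20, 4,
                 dimnames = list(sprintf("f%02d", 1:20), paste0("a", 1:4)))
  m <- cbind(half, half)
  colnames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  res <- nb_wald_test(feature_table(m, "functional_ortholog"),
                      factor(rep(c("a", "b"), each = 4)))
  expect_equal(res$log2fc, rep(0, 20), tolerance = 1e-6)
  expect_equal(res$p, rep(1, 20), tolerance = 1e-6)
  expect_true(all(res$is_ndfo))
})

test_that("swapping condition labels flips the sign of log2FC only", {
  co <- generate_corpus(small_corpus_spec(seed = 41))
  cond <- droplevels(co$metadata$segment)
  r1 <- nb_wald_test(co$fo_table, cond)
  r2 <- nb_wald_test(co$fo_table, factor(cond, levels = rev(levels(cond))))
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("nDFO classification applies the threshold over tested FOs only", {
  res <- data.frame(fo_id = c("k1", "k2", "k3"),
                    padj = c(0.01, 0.20, NA))
  nd <- classify_ndfo(res, alpha = 0.05)
  expect_identical(as.character(nd), "k2")
  expect_setequal(attr(nd, "universe"), c("k1", "k2"))
  # boundary: padj exactly at alpha is NOT differential (the cut is padj < alpha)
  bound <- classify_ndfo(data.frame(fo_id = c("k1", "k2"),
                                    padj = c(0.05, 0.04999)), alpha = 0.05)
  expect_identical(as.character(bound), "k1")
  # random vector equals a brute-force filter
  set.seed(3)
  rnd <- data.frame(fo_id = sprintf("k%02d", 1:50),
                    padj = replace(runif(50), sample(50, 5), NA))
  nd_rnd <- classify_ndfo(rnd, 0.05)
  expect_setequal(nd_rnd, rnd$fo_id[which(rnd$padj >= 0.05)])
})

test_that("pairwise stability evaluates every unordered pair", {
  co <- generate_corpus(corpus_spec(n_datasets = 5, samples_per_dataset = 6,
                                    n_genera = 30, n_fos = 40, n_core = 3,
                                    n_differential_fos = 20, seed = 43))
  stab <- pairwise_stability(co$fo_table, co$metadata$segment)
  expect_identical(nrow(stab$pairs), 10L)
  ok <- !is.na(stab$pairs$n_ndfo)
  expect_equal(stab$pairs$pct_ndfo[ok],
               100 * stab$pairs$n_ndfo[ok] / stab$pairs$n_universe[ok])
  sq <- stability_square(stab)
  expect_identical(dim(sq), c(5L, 5L))
  expect_equal(sq["duodenum", "jejunum"],
               stab$pairs$pct_ndfo[stab$pairs$group1 == "duodenum" &
                                     stab$pairs$group2 == "jejunum"])
})

test_that("pairs with under two samples per group are reported as NA", {
  m <- matrix(rpois(50, 10), 10, 5,
              dimnames = list(sprintf("f%02d", 1:10), paste0("s", 1:5)))
  g <- factor(c("a", "a", "b", "b", "c"))
  stab <- pairwise_stability(feature_table(m, "functional_ortholog"), g)
  pc <- stab$pairs
  expect_true(is.na(pc$n_ndfo[pc$group1 == "a" & pc$group2 == "c"]))
  expect_false(is.na(pc$n_ndfo[pc$group1 == "a" & pc$group2 == "b"]))
})

test_that("the pair universe is the intersection of detected FOs", {
  m <- rbind(f1 = c(5, 6, 0, 0), f2 = c(4, 5, 7, 8), f3 = c(0, 0, 3, 4))
  colnames(m) <- paste0("s", 1:4)
  g <- factor(rep(c("a", "b"), each = 2))
  stab <- pairwise_stability(feature_table(m, "functional_ortholog"), g)
  expect_identical(stab$pairs$n_universe, 1L)  # only f2 detected in both
  stab_u <- pairwise_stability(feature_table(m, "functional_ortholog"), g,
                               universe = "union")
  expect_identical(stab_u$pairs$n_universe, 3L)
})

test_that("upset intersections match a power-set oracle", {
  sets <- list(A = c("a", "b", "c"), B = c("a", "b"), C = c("a"))
  inter <- intersect_ndfo(sets)
  expect_identical(inter$conserved, "a")
  expect_identical(intersect_ndfo(list(X = "x", Y = "y"))$conserved,
                   character(0))
  set.seed(5)
  rsets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(rsets) <- paste0("cmp", 1:4)
  ri <- intersect_ndfo(rsets)
  expect_equal(sum(ri$combination_counts$count), length(unique(unlist(rsets))))
  # brute-force enumeration over all membership patterns
  for (el in rownames(ri$membership)) {
    pat <- paste(names(rsets)[vapply(rsets, function(s) el %in% s, logical(1))],
                 collapse = "&")
    expect_true(pat %in% ri$combination_counts$pattern)
  }
  expect_setequal(ri$conserved, Reduce(intersect, rsets))
})

test_that("conserved nDFO sets shrink as comparisons are added", {
  set.seed(9)
  sets <- lapply(1:5, function(i) sample(sprintf("k%02d", 1:30), 20))
  names(sets) <- paste0("c", 1:5)
  prev <- intersect_ndfo(sets[1:2])$conserved
  for (k in 3:5) {
    cur <- intersect_ndfo(sets[1:k])$conserved
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  res <- enrich_pathways(query = c("f1", "f2", "f3", "f4", "f10"),
                         pathways = list(p1 = c("f1", "f2", "f3", "f4")),
                         universe = sprintf("f%d", 1:10))
  # N=10, K=4, n=5, k=4: C(4,4)C(6,1)/C(10,5) = 6/252
  expect_equal(res$p, 6 / 252)
  expect_equal(res$gene_ratio, 0.8)
  # k = 0 and saturated queries are certain events
  res0 <- enrich_pathways("f9", list(p1 = c("f1", "f2")), sprintf("f%d", 1:10))
  expect_equal(res0$p, 1)
  uni <- sprintf("f%d", 1:8)
  res_sat <- enrich_pathways(uni, list(p1 = c("f1", "f2", "f3")), uni)
  expect_equal(res_sat$p, 1)
  expect_equal(res_sat$k, res_sat$K)
  expect_error(enrich_pathways(character(0), list(p1 = "f1"), uni))
  expect_error(enrich_pathways("zz", list(p1 = "f1"), uni), "subset")
})

test_that("BH adjustment matches a brute-force step-up on random vectors", {
  brute_bh <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), brute_bh(p))
  }
  # monotone and >= raw p, as used downstream
  p <- runif(30)
  adj <- p.adjust(p, "BH")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})
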