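test_that("feature table round-trips through the TSV dialect", {
  tab <- random_table(nf = 7, ns = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  expect_identical(readLines(path, n = 1),
                   paste(c("feature_id", sample_ids(tab)), collapse = "\t"))
  back <- read_feature_table(path)
  expect_identical(back$counts, tab$counts)
  expect_identical(feature_ids(back), feature_ids(tab))
})

test_that("invalid cells and duplicate ids are rejected with names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "fA\t3\t-1", "fB\t0\t2"), path)
  expect_error(read_feature_table(path), "fA")
  writeLines(c("feature_id\ts1", "fA\t1", "fA\t2"), path)
  expect_error(read_feature_table(path), "duplicate feature ids")
  m <- tiny_counts()
  m[1, 1] <- 2.5
  expect_error(feature_table(m), "non-integer")
})

test_that("non-bacterial and organelle features are removed", {
  counts <- matrix(1, 5, 2, dimnames = list(paste0("f", 1:5), c("s1", "s2")))
  tab <- feature_table(counts)
  tax <- tiny_taxonomy()
  out <- filter_nonbacterial(tab, tax)
  # brute-force scan: domain Bacteria and no organelle string anywhere
  lin <- as.data.frame(tax)
  keep <- vapply(seq_len(nrow(lin)), function(i) {
    r <- unlist(lin[i, -1])
    lin$domain[i] == "Bacteria" &&
      !any(grepl("mitochondria|chloroplast", r, ignore.case = TRUE))
  }, logical(1))
  expect_setequal(feature_ids(out), lin$feature_id[keep])
  expect_identical(feature_ids(out), c("f1", "f2"))
})

test_that("features without a lineage are dropped with a warning", {
  tab <- feature_table(matrix(1, 2, 1, dimnames = list(c("f1", "known"), "s1")))
  tax <- taxonomy_table("known", matrix(c("Bacteria", rep("", 5)), 1))
  expect_warning(out <- filter_nonbacterial(tab, tax), "without a lineage")
  expect_identical(feature_ids(out), "known")
})

test_that("depth filter is strict at the threshold", {
  m <- matrix(c(9999, 10000, 10500), 1, dimnames = list("f1", c("a", "b", "c")))
  tab <- feature_table(m)
  out <- filter_low_depth(tab, 10000)
  expect_identical(sample_ids(out), c("b", "c"))
  expect_identical(filter_low_depth(tab, 0)$counts, tab$counts)
  rt <- random_table(nf = 10, ns = 12, seed = 9, lambda = 6)
  out50 <- filter_low_depth(rt, 50)
  expect_setequal(sample_ids(out50),
                  names(which(colSums(rt$counts) >= 50)))
})

test_that("zero-count features are pruned and filters are idempotent", {
  tab <- tiny_table()
  out <- prune_zero_features(tab)
  expect_identical(feature_ids(out), c("f1", "f2", "f3"))
  expect_identical(prune_zero_features(out)$counts, out$counts)
  expect_identical(filter_low_depth(filter_low_depth(tab, 5), 5)$counts,
                   filter_low_depth(tab, 5)$counts)
})

test_that("rank collapse sums groups and conserves column totals", {
  counts <- rbind(a1 = c(3, 4), a2 = c(1, 2), b1 = c(5, 0))
  colnames(counts) <- c("s1", "s2")
  tab <- feature_table(counts)
  tax <- taxonomy_table(c("a1", "a2", "b1"), rbind(
    c("Bacteria", "P1", "C1", "O1", "F1", "G"),
    c("Bacteria", "P1", "C1", "O1", "F2", "G"),
    c("Bacteria", "P2", "C2", "O2", "F3", "H")))
  out <- collapse_to_rank(tab, tax, "genus")
  expect_equal(out$counts["G", ], c(s1 = 4, s2 = 6))
  phy <- collapse_to_rank(tab, tax, "phylum")
  expect_equal(colSums(phy$counts), colSums(tab$counts))
})

test_that("collapse matches a brute-force group-by and labels unassigned", {
  rt <- random_table(nf = 12, ns = 5, seed = 11)
  gen <- c(rep(c("Ga", "Gb", ""), 4))
  fam <- rep("FamX", 12)
  tax <- taxonomy_table(feature_ids(rt),
                        cbind("Bacteria", "P", "C", "O", fam, gen))
  out <- collapse_to_rank(rt, tax, "genus")
  expected_label <- ifelse(gen == "", "unclassified:FamX", gen)
  brute <- rowsum(rt$counts, expected_label)
  expect_equal(out$counts, brute[rownames(out$counts), ])
  expect_true("unclassified:FamX" %in% feature_ids(out))
})

test_that("taxonomy reader accepts lineage-string and per-rank layouts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlineage",
               "f1\td__Bacteria;p__Firmicutes;c__Bacilli;o__Lb;f__Lbf;g__Lacto",
               "f2\td__Bacteria;p__Proteobacteria"), path)
  tax <- read_taxonomy_table(path)
  expect_identical(tax$genus, c("Lacto", ""))
  expect_identical(tax$domain, c("Bacteria", "Bacteria"))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy_table(tax, path2)
  expect_identical(as.data.frame(read_taxonomy_table(path2)),
                   as.data.frame(tax))
})

test_that("metadata derives dataset ids and validates factor levels", {
  meta <- sample_metadata(c("s1", "s2"), c("BP1", "BP1"),
                          segment = c("ceca", "ileum"))
  expect_identical(meta$dataset_id, c("BP1.ceca", "BP1.ileum"))
  expect_error(sample_metadata("s1", "BP1", segment = "gizzard"))
  expect_error(sample_metadata("s1", "BP1", segment = "ceca", doa = -1L))
  expect_warning(sample_metadata("s1", "BP1", segment = "ceca", doa = 400L),
                 "371")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, path)
  back <- read_sample_metadata(path)
  expect_identical(back$dataset_id, meta$dataset_id)
  expect_identical(as.character(back$segment), as.character(meta$segment))
})

test_that("depth filtering after taxonomic filtering matches depths on bacteria-only counts", {
  counts <- matrix(c(6000, 12000,
                     7000, 1000,
                     500, 300), 3, 2, byrow = TRUE,
                   dimnames = list(c("b1", "b2", "m1"), c("s1", "s2")))
  tab <- feature_table(counts)
  tax <- taxonomy_table(c("b1", "b2", "m1"), rbind(
    c("Bacteria", "P", "C", "O", "F", "G1"),
    c("Bacteria", "P", "C", "O", "F", "G2"),
    c("Bacteria", "P", "C", "Rickettsiales", "Mitochondria", "")))
  out <- filter_low_depth(filter_nonbacterial(tab, tax), 13000)
  bact_depth <- colSums(counts[c("b1", "b2"), ])
  expect_setequal(sample_ids(out), names(which(bact_depth >= 13000)))
})
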