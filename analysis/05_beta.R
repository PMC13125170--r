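#!/usr/bin/env Rscript
# Stage 5: beta diversity. Bray-Curtis on genus counts, PCoA, then for
# each design factor a dispersion-homogeneity test (ANOVA + permutation)
# and a one-factor PERMANOVA with 999 permutations. Where dispersions
# differ, the PERMANOVA is flagged descriptive rather than inferential.

suppressPackageStartupMessages(library(gutcore))

seed <- 1234
genus <- read_feature_table("results/genus_table.tsv", "taxon")
meta <- read_sample_metadata("results/corpus/metadata.tsv")
meta <- meta[match(sample_ids(genus), meta$sample_id), ]

bc <- bray_curtis(genus)
write_distance_matrix(bc, "results/bray_curtis.tsv")
pc <- pcoa(bc)
cat(sprintf("PCoA: first two axes explain %.1f%% and %.1f%%\n",
            100 * pc$proportion_explained[1], 100 * pc$proportion_explained[2]))
write.table(data.frame(sample_id = rownames(pc$coordinates),
                       pc$coordinates[, 1:3]),
            "results/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

factors <- list(segment = meta$segment, continent = meta$continent,
                bird_type = meta$bird_type, housing = meta$housing,
                hv_region = factor(meta$hv_region),
                age_category = age_categorize(meta$doa))
rows <- list()
for (nm in names(factors)) {
  g <- droplevels(factor(factors[[nm]]))
  if (nlevels(g) < 2 || any(table(g) < 2)) next
  disp <- suppressWarnings(dispersion_test(bc, g, n_perm = 999, seed = seed))
  pv <- permanova(bc, g, n_perm = 999, seed = seed, factor_name = nm)
  rows[[nm]] <- data.frame(factor_name = nm, pseudo_f = pv$pseudo_f,
                           r2 = pv$r2, p = pv$p,
                           dispersion_p = disp$p_perm,
                           interpretation = ifelse(disp$p_perm < 0.05,
                                                   "descriptive", "inferential"))
}
res <- do.call(rbind, rows)
rownames(res) <- NULL
print(res, digits = 3, row.names = FALSE)
write.table(res, "results/beta_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
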