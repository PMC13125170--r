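#!/usr/bin/env Rscript
# Stage 4: alpha diversity. Shannon and Simpson per sample; Simpson is
# rank-normalized before modelling. A random-intercept mixed model
# (BioProject as random effect) tests the design factors, then predictors
# whose every |t| is below 2 are dropped and the model refitted; aGVIF
# screens for collinearity.

suppressPackageStartupMessages(library(gutcore))

genus <- read_feature_table("results/genus_table.tsv", "taxon")
meta <- read_sample_metadata("results/corpus/metadata.tsv")
meta <- meta[match(sample_ids(genus), meta$sample_id), ]

alpha <- alpha_diversity(genus)
write.table(alpha, "results/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
by_seg <- tapply(alpha$shannon, meta$segment, mean)
cat("Mean Shannon by segment:\n")
print(round(by_seg[!is.na(by_seg)], 3))

for (resp in c("shannon", "simpson_rank_normal")) {
  preds <- select_estimable_predictors(alpha[[resp]], meta,
                                       c("segment", "continent", "doa",
                                         "bird_type", "housing", "hv_region"))
  fit <- fit_lmm(alpha[[resp]], meta, preds)
  red <- suppressWarnings(reduce_model(fit))
  cat(sprintf("\n%s: full model AIC(ML) %.1f -> reduced %.1f; kept: %s; dropped: %s\n",
              resp, attr(red, "aic_full"), attr(red, "aic_reduced"),
              paste(red$predictors, collapse = ", "),
              paste(attr(red, "dropped"), collapse = ", ")))
  out <- red$coefficients
  write.table(out, sprintf("results/alpha_model_%s.tsv", resp), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (any(!is.na(fit$agvif)))
    cat(sprintf("max aGVIF (full model): %.3f\n", max(fit$agvif, na.rm = TRUE)))
}
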