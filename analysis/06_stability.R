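#!/usr/bin/env Rscript
# Stage 6: functional stability. For every unordered pair of segments,
# a negative-binomial Wald test on the FO table (restricted to FOs
# detected in both groups) classifies non-differential FOs (nDFOs,
# adjusted p >= 0.05). The pairwise nDFO matrix, the upset-style
# intersections, the conserved set, and the pathways enriched in it are
# written as tables.

suppressPackageStartupMessages(library(gutcore))

fo <- read_feature_table("results/corpus/fo_table.tsv", "functional_ortholog")
meta <- read_sample_metadata("results/corpus/metadata.tsv")
genus <- read_feature_table("results/genus_table.tsv", "taxon")
keep <- intersect(sample_ids(fo), sample_ids(genus))  # depth-filtered samples
fo <- subset_feature_table(fo, samples = keep)
meta <- meta[match(keep, meta$sample_id), ]
truth <- read.delim("results/corpus/truth.tsv")
map <- read_pathway_map("results/corpus/pathway_map.tsv")

stab <- pairwise_stability(fo, droplevels(meta$segment), alpha = 0.05)
print(stab)
write_stability_matrix(stab, "results/stability_matrix.tsv")

sets <- Filter(Negate(is.null), stab$ndfo_sets)
inter <- intersect_ndfo(sets)
print(inter)
write.table(data.frame(fo_id = rownames(inter$membership),
                       inter$membership * 1, check.names = FALSE),
            "results/ndfo_membership.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

planted_stable <- truth$feature_id[truth$role == "stable_fo"]
cat(sprintf("Conserved nDFOs: %d, of which %d (%.0f%%) are planted stable FOs\n",
            length(inter$conserved),
            length(intersect(inter$conserved, planted_stable)),
            100 * mean(inter$conserved %in% planted_stable)))

universe <- sort(unique(unlist(stab$universes)))
enr <- enrich_pathways(inter$conserved, map, universe)
print(head(as.data.frame(enr), 5), digits = 3, row.names = FALSE)
write.table(as.data.frame(enr), "results/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Planted stable pathway path001 ranks %d by adjusted p\n",
            which(enr$pathway_id == "path001")))
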