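#!/usr/bin/env Rscript
# Stage 2: preprocessing. Retain bacterial non-organelle features, drop
# samples under 10,000 reads (computed on bacterial reads), prune
# zero-count taxa, and collapse to genus level for downstream analysis.

suppressPackageStartupMessages(library(gutcore))

tab <- read_feature_table("results/corpus/taxon_table.tsv", "taxon")
tax <- read_taxonomy_table("results/corpus/taxonomy.tsv")
n0 <- dim(tab)

tab <- filter_nonbacterial(tab, tax)
cat(sprintf("Taxonomic filter: %d -> %d features (organelles/non-bacteria removed)\n",
            n0[1], dim(tab)[1]))

tab <- filter_low_depth(tab, 10000)
cat(sprintf("Depth filter: %d -> %d samples at the 10,000-read floor\n",
            n0[2], dim(tab)[2]))

tab <- prune_zero_features(tab)
genus <- collapse_to_rank(tab, tax, "genus")
cat(sprintf("Genus collapse: %d features -> %d genera; reads conserved: %s\n",
            dim(tab)[1], dim(genus)[1],
            isTRUE(all.equal(colSums(tab$counts), colSums(genus$counts)))))

write_feature_table(tab, "results/filtered_table.tsv")
write_feature_table(genus, "results/genus_table.tsv")
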