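# Shared fixtures, built in code at test time.

tiny_counts <- function() {
  m <- matrix(c(5, 0, 3,
                0, 2, 1,
                7, 7, 0,
                0, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  m
}

tiny_table <- function() feature_table(tiny_counts(), "taxon")

tiny_taxonomy <- function() {
  taxonomy_table(paste0("f", 1:5), rbind(
    c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus"),
    c("Bacteria", "Firmicutes", "Clostridia", "Oscillospirales", "Ruminococcaceae", "Faecalibacterium"),
    c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rickettsiales", "Mitochondria", ""),
    c("Archaea", "Euryarchaeota", "Methanobacteria", "Methanobacteriales", "Methanobacteriaceae", "Methanobrevibacter"),
    c("Bacteria", "Cyanobacteria", "Cyanobacteriia", "Chloroplast", "", "")))
}

# random valid count table with reproducible contents
random_table <- function(nf = 20, ns = 8, seed = 42, lambda = 15,
                         kind = "taxon") {
  set.seed(seed)
  m <- matrix(rpois(nf * ns, lambda), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  feature_table(m, kind)
}

# metadata with b bioprojects x k samples each, one dataset per bioproject
grid_metadata <- function(b = 3, k = 4, segment = "ceca") {
  n <- b * k
  sample_metadata(sample_id = sprintf("s%02d", seq_len(n)),
                  bioproject_id = rep(sprintf("BP%02d", seq_len(b)), each = k),
                  segment = segment, doa = 21L)
}

# balanced two-factor design for mixed-model tests: every bioproject holds
# every (segment, bird_type) cell `rep` times
balanced_lmm_meta <- function(n_bp = 6, rep = 2) {
  cells <- expand.grid(segment = c("duodenum", "ceca"),
                       bird_type = c("broiler", "layer"),
                       bp = sprintf("BP%02d", seq_len(n_bp)),
                       r = seq_len(rep), stringsAsFactors = FALSE)
  sample_metadata(sample_id = sprintf("s%03d", seq_len(nrow(cells))),
                  bioproject_id = cells$bp, segment = cells$segment,
                  bird_type = cells$bird_type, doa = 14L)
}

small_corpus_spec <- function(...) {
  corpus_spec(n_datasets = 4, samples_per_dataset = 8, n_genera = 40,
              n_fos = 60, n_core = 4, n_differential_fos = 30,
              depth_range = c(2000, 20000), segments = c("ileum", "ceca"),
              n_pathways = 6, pathway_size_range = c(5, 12), ...)
}
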