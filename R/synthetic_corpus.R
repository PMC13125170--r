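#' Specify a synthetic multi-dataset corpus
#'
#' The generator emulates the post-denoising state of a multi-study 16S
#' meta-analysis corpus: several datasets (one BioProject x segment
#' combination each) with dataset-level compositional random effects,
#' planted core genera at controlled detection probability, planted stable
#' and differential functional orthologs (FOs) with negative-binomial
#' noise, organelle contaminant features, and sequencing depths spanning
#' the 10,000-read pruning threshold.
#'
#' Defaults mirror a desk-scale version of the study conditions the
#' pipeline targets: a dozen datasets of ~20 samples spread over the five
#' intestinal segments, a few hundred genera of which ten are core
#' (detection 0.95 within a dataset versus 0.2 background), and an FO
#' universe in which roughly half the orthologs differ between segments
#' while the rest are stable.
#'
#' @param n_datasets Number of datasets (BioProject x segment units).
#' @param samples_per_dataset Integer, or length-2 range to draw from.
#' @param n_genera Number of bacterial genera (before contaminants).
#' @param n_fos Number of functional orthologs.
#' @param n_core Number of planted core genera.
#' @param core_detection Per-sample detection probability of planted core
#'   genera within every dataset.
#' @param background_detection Detection probability of non-core genera.
#' @param dataset_effect_sd SD of the log-normal dataset-level perturbation
#'   of the global genus composition (log scale).
#' @param depth_range Expected reads per sample, drawn uniformly; spans the
#'   10,000-read filter by default.
#' @param contaminant_fraction Fraction (of `n_genera`) of extra
#'   mitochondria/chloroplast contaminant features inserted.
#' @param n_differential_fos Number of FOs planted as differential.
#' @param differential_factor Metadata column the planted fold changes act
#'   on (default `"segment"`).
#' @param log2fc Planted log2 fold change between the factor's first and
#'   last level; intermediate levels are graded linearly.
#' @param dispersion Negative-binomial overdispersion of FO counts
#'   (variance mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param segments Segment levels cycled over datasets.
#' @param n_pathways,pathway_size_range,stable_fraction Pathway map shape:
#'   number of pathways, membership size range, and the fraction of the
#'   planted stable pathway drawn from truly stable FOs.
#' @param seed Integer master seed; all sub-generators derive from it.
#' @return A validated `corpus_spec` list.
#' @export
corpus_spec <- function(n_datasets = 12, samples_per_dataset = 20,
                        n_genera = 300, n_fos = 500,
                        n_core = 10, core_detection = 0.95,
                        background_detection = 0.2,
                        dataset_effect_sd = 1.0,
                        depth_range = c(5000, 60000),
                        contaminant_fraction = 0.05,
                        n_differential_fos = 250,
                        differential_factor = "segment",
                        log2fc = 2,
                        dispersion = 0.2,
                        segments = c("duodenum", "jejunum", "ileum", "ceca", "feces"),
                        n_pathways = 20, pathway_size_range = c(10, 30),
                        stable_fraction = 0.9,
                        seed = 1) {
  stopifnot(n_datasets >= 1, n_genera >= 1, n_fos >= 1,
            n_core >= 0, n_core <= n_genera,
            core_detection >= 0, core_detection <= 1,
            background_detection >= 0, background_detection <= 1,
            dataset_effect_sd >= 0, dispersion >= 0,
            length(depth_range) == 2, depth_range[1] > 0,
            depth_range[2] >= depth_range[1],
            contaminant_fraction >= 0, contaminant_fraction < 1,
            n_differential_fos >= 0, n_differential_fos <= n_fos,
            is.finite(log2fc),
            n_pathways >= 1, length(pathway_size_range) == 2,
            pathway_size_range[2] >= pathway_size_range[1],
            pathway_size_range[2] <= n_fos,
            stable_fraction >= 0, stable_fraction <= 1)
  if (length(samples_per_dataset) == 1)
    samples_per_dataset <- rep(samples_per_dataset, 2)
  stopifnot(samples_per_dataset[1] >= 1,
            samples_per_dataset[2] >= samples_per_dataset[1])
  segments <- match.arg(segments, .segments, several.ok = TRUE)
  spec <- list(n_datasets = n_datasets,
               samples_per_dataset = as.integer(samples_per_dataset),
               n_genera = n_genera, n_fos = n_fos, n_core = n_core,
               core_detection = core_detection,
               background_detection = background_detection,
               dataset_effect_sd = dataset_effect_sd,
               depth_range = depth_range,
               contaminant_fraction = contaminant_fraction,
               n_differential_fos = n_differential_fos,
               differential_factor = differential_factor,
               log2fc = log2fc, dispersion = dispersion,
               segments = segments,
               n_pathways = n_pathways,
               pathway_size_range = as.integer(pathway_size_range),
               stable_fraction = stable_fraction,
               seed = as.integer(seed))
  class(spec) <- "corpus_spec"
  spec
}

genus_ids <- function(n) sprintf("Genus_%03d", seq_len(n))
fo_ids <- function(n) sprintf("K%05d", seq_len(n))

corpus_stable_fos <- function(spec) {
  setdiff(fo_ids(spec$n_fos), fo_ids(spec$n_fos)[seq_len(spec$n_differential_fos)])
}

#' Generate a synthetic corpus
#'
#' Draws taxon counts per sample from a multinomial over dataset-level
#' compositions (a log-normal perturbation of a global composition),
#' forces planted core genera present (count >= 1) in the detected
#' fraction of samples, draws FO counts from negative binomials whose
#' means carry the planted fold changes, inserts contaminant features,
#' and draws depths uniformly over `depth_range`. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec A [corpus_spec()].
#' @return A `synthetic_corpus`: list with `taxon_table`, `fo_table`,
#'   `taxonomy` ([taxonomy_table()]), `metadata` ([sample_metadata()]), and
#'   `truth` (planted core genera, stable/differential FO ids, planted
#'   enriched pathway id).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genera
  gid <- genus_ids(ng)
  core_ids <- gid[seq_len(spec$n_core)]

  # --- datasets and metadata ------------------------------------------------
  nd <- spec$n_datasets
  bioprojects <- sprintf("BP%03d", seq_len(nd))
  seg <- rep_len(spec$segments, nd)
  n_per <- if (spec$samples_per_dataset[1] == spec$samples_per_dataset[2])
    rep(spec$samples_per_dataset[1], nd)
  else
    sample(spec$samples_per_dataset[1]:spec$samples_per_dataset[2], nd, replace = TRUE)
  ds_bird <- sample(c("broiler", "layer", "other"), nd, replace = TRUE,
                    prob = c(0.65, 0.2, 0.15))
  ds_cont <- sample(c("Asia", "Europe", "NorthAmerica", "Africa", "Hawaii"), nd,
                    replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.05, 0.05))
  ds_house <- sample(c("cages", "floor_pens", "mixed", "unspecified"), nd,
                     replace = TRUE, prob = c(0.45, 0.35, 0.05, 0.15))
  ds_doa <- sample(c(3, 7, 14, 21, 28, 35, 42, 70), nd, replace = TRUE)
  ds_hv <- sample(c("V3-V4", "V4", "V1-V2"), nd, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
  ds_of_sample <- rep(seq_len(nd), n_per)
  ns <- length(ds_of_sample)
  sam <- sprintf("S%05d", seq_len(ns))
  meta <- sample_metadata(sample_id = sam,
                          bioproject_id = bioprojects[ds_of_sample],
                          segment = seg[ds_of_sample],
                          bird_type = ds_bird[ds_of_sample],
                          continent = ds_cont[ds_of_sample],
                          housing = ds_house[ds_of_sample],
                          doa = ds_doa[ds_of_sample],
                          hv_region = ds_hv[ds_of_sample])

  # --- taxon counts ---------------------------------------------------------
  base_w <- exp(stats::rnorm(ng, 0, 1.5))          # global composition weights
  ds_w <- base_w * exp(matrix(stats::rnorm(ng * nd, 0, spec$dataset_effect_sd),
                              ng, nd))             # dataset-level perturbation
  det_p <- ifelse(gid %in% core_ids, spec$core_detection, spec$background_detection)
  depth <- sample(spec$depth_range[1]:spec$depth_range[2], ns, replace = TRUE)
  counts <- matrix(0, ng, ns, dimnames = list(gid, sam))
  for (j in seq_len(ns)) {
    d <- ds_of_sample[j]
    mask <- stats::rbinom(ng, 1, det_p)
    if (sum(mask) == 0) mask[which.max(ds_w[, d])] <- 1
    w <- ds_w[, d] * mask
    counts[, j] <- stats::rmultinom(1, depth[j], w / sum(w))
    # planted core genera are forced present where detected
    forced <- gid %in% core_ids & mask == 1 & counts[, j] == 0
    counts[forced, j] <- 1
  }

  # --- contaminant features -------------------------------------------------
  n_contam <- round(spec$contaminant_fraction * ng)
  if (n_contam > 0) {
    cid <- sprintf("Contam_%02d", seq_len(n_contam))
    ccounts <- matrix(stats::rpois(n_contam * ns, lambda = depth * 0.001),
                      n_contam, ns, byrow = TRUE, dimnames = list(cid, sam))
    counts <- rbind(counts, ccounts)
  } else {
    cid <- character(0)
  }

  # --- taxonomy -------------------------------------------------------------
  phyla <- c("Firmicutes", "Bacteroidota", "Proteobacteria", "Actinobacteriota",
             "Campilobacterota", "Verrucomicrobiota", "Desulfobacterota",
             "Cyanobacteria")
  g_phy <- sample(phyla, ng, replace = TRUE,
                  prob = c(0.55, 0.15, 0.12, 0.08, 0.04, 0.03, 0.02, 0.01))
  lin <- cbind(domain = rep("Bacteria", ng),
               phylum = g_phy,
               class = paste0(g_phy, "_c"),
               order = paste0(g_phy, "_o"),
               family = paste0(g_phy, "_f"),
               genus = gid)
  if (n_contam > 0) {
    mito <- seq_len(n_contam) %% 2 == 1
    clin <- cbind(domain = rep("Bacteria", n_contam),
                  phylum = ifelse(mito, "Proteobacteria", "Cyanobacteria"),
                  class = ifelse(mito, "Alphaproteobacteria", "Cyanobacteriia"),
                  order = ifelse(mito, "Rickettsiales", "Chloroplast"),
                  family = ifelse(mito, "Mitochondria", "Chloroplast_f"),
                  genus = cid)
    lin <- rbind(lin, clin)
  }
  tax <- taxonomy_table(c(gid, cid), lin)

  # --- FO counts ------------------------------------------------------------
  nf <- spec$n_fos
  fid <- fo_ids(nf)
  diff_ids <- fid[seq_len(spec$n_differential_fos)]
  base_mu <- exp(stats::rnorm(nf, 3, 1))
  size_fac <- exp(stats::rnorm(ns, 0, 0.3))       # per-sample depth factor
  fac <- meta[[spec$differential_factor]]
  if (is.null(fac)) stop("unknown differential factor: ", spec$differential_factor)
  fac <- droplevels(factor(fac))
  lev <- levels(fac)
  grade <- if (length(lev) > 1)
    (match(fac, lev) - 1) / (length(lev) - 1) else rep(0, ns)
  # fold changes alternate in sign: segment differences run both ways, and a
  # corpus with no net compositional shift keeps median-of-ratios meaningful
  lfc_vec <- numeric(nf)
  lfc_vec[fid %in% diff_ids] <- spec$log2fc *
    rep_len(c(1, -1), length(diff_ids))
  # effects are centred on each FO's base mean (extreme levels at -lfc/2 and
  # +lfc/2) so the planted contrast between extreme levels is exactly lfc
  mu <- outer(base_mu, size_fac) * 2^(outer(lfc_vec, grade - 0.5))
  fo_counts <- matrix(
    if (spec$dispersion > 0)
      stats::rnbinom(nf * ns, mu = mu, size = 1 / spec$dispersion)
    else
      stats::rpois(nf * ns, lambda = mu),
    nf, ns, dimnames = list(fid, sam))

  structure(list(
    taxon_table = feature_table(counts, "taxon"),
    fo_table = feature_table(fo_counts, "functional_ortholog"),
    taxonomy = tax,
    metadata = meta,
    truth = list(core_genera = core_ids,
                 differential_fos = diff_ids,
                 stable_fos = setdiff(fid, diff_ids),
                 enriched_pathway = "path001")),
    class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("synthetic_corpus: %d taxa x %d samples, %d FOs, %d datasets\n",
              nrow(x$taxon_table$counts), ncol(x$taxon_table$counts),
              nrow(x$fo_table$counts), length(unique(x$metadata$dataset_id))))
  invisible(x)
}

#' Generate a pathway membership map
#'
#' Random pathway memberships over the FO universe, except the planted
#' stable pathway (`path001`), which is composed predominantly
#' (`spec$stable_fraction`) of planted stable FOs. Derives its own child
#' seed from `spec$seed` so the map is reproducible independently of the
#' corpus draw.
#'
#' @param spec A [corpus_spec()].
#' @return Named list mapping pathway id to a character vector of FO ids.
#' @export
generate_pathway_map <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed + 104729L)  # child seed for the pathway draw
  fid <- fo_ids(spec$n_fos)
  stable <- corpus_stable_fos(spec)
  diffs <- setdiff(fid, stable)
  sizes <- sample(spec$pathway_size_range[1]:spec$pathway_size_range[2],
                  spec$n_pathways, replace = TRUE)
  pid <- sprintf("path%03d", seq_len(spec$n_pathways))
  map <- vector("list", spec$n_pathways)
  names(map) <- pid
  for (i in seq_len(spec$n_pathways)) {
    if (i == 1 && length(stable) > 0) {
      k_stab <- min(ceiling(spec$stable_fraction * sizes[i]), length(stable))
      k_rest <- sizes[i] - k_stab
      map[[i]] <- c(sample(stable, k_stab),
                    if (k_rest > 0) sample(diffs, min(k_rest, length(diffs))))
    } else {
      map[[i]] <- sample(fid, sizes[i])
    }
  }
  map
}

#' Read/write a pathway map (two-column TSV: pathway_id, fo_id)
#' @param map Named list of FO id vectors.
#' @param path TSV path.
#' @export
write_pathway_map <- function(map, path) {
  df <- data.frame(pathway_id = rep(names(map), lengths(map)),
                   fo_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pathway_map
#' @return `read_pathway_map` returns the named list.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character")
  if (!all(c("pathway_id", "fo_id") %in% names(df)))
    stop("pathway map TSV needs columns pathway_id, fo_id")
  split(df$fo_id, df$pathway_id)
}

#' Write a synthetic corpus to a directory of TSV files
#'
#' Emits the same formats the pipeline reads (taxon/FO feature tables,
#' taxonomy, metadata) plus a `truth.tsv` (feature_id, role) recording the
#' planted structure.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(corpus$taxon_table, file.path(dir, "taxon_table.tsv"))
  write_feature_table(corpus$fo_table, file.path(dir, "fo_table.tsv"))
  write_taxonomy_table(corpus$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(corpus$metadata, file.path(dir, "metadata.tsv"))
  truth <- rbind(
    data.frame(feature_id = corpus$truth$core_genera, role = "core_genus"),
    data.frame(feature_id = corpus$truth$differential_fos, role = "differential_fo"),
    data.frame(feature_id = corpus$truth$stable_fos, role = "stable_fo"))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
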