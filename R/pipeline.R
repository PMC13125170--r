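#' Pipeline configuration
#'
#' A plain key-value configuration for [run_pipeline()]. All randomness in
#' the run flows from the single `seed`; stage outputs are plain TSVs
#' carrying a provenance header comment.
#'
#' @param input_dir Directory holding `taxon_table.tsv`, `fo_table.tsv`,
#'   `taxonomy.tsv`, `metadata.tsv` and optionally `pathway_map.tsv`
#'   (the formats written by [write_corpus()] / [write_pathway_map()]).
#' @param outdir Output directory.
#' @param min_reads Sample depth floor (default 10000).
#' @param t1,t2 Core-screen thresholds in percent (defaults 80 and 50).
#' @param alpha Adjusted-p threshold for the nDFO classification.
#' @param n_perm Permutations for PERMANOVA and the dispersion test.
#' @param seed Integer master seed.
#' @param stages Stages to run, in pipeline order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, outdir, min_reads = 10000,
                            t1 = 80, t2 = 50, alpha = 0.05, n_perm = 999,
                            seed = 1,
                            stages = c("filter", "profile", "core", "alpha",
                                       "beta", "stability", "enrich")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(input_dir = input_dir, outdir = outdir,
                 min_reads = min_reads, t1 = t1, t2 = t2, alpha = alpha,
                 n_perm = n_perm, seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

write_tsv_prov <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# gutcore %s seed=%d",
                     as.character(utils::packageVersion("gutcore")),
                     config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_log <- function(...) message("[gutcore] ", sprintf(...))

#' Run the full secondary-analysis pipeline
#'
#' Executes filter, profile, core, alpha, beta, stability and enrich in
#' order (skipping disabled stages), writing each stage's tables under
#' `config$outdir` and a content-hashed manifest at the end. Reruns with
#' an identical configuration and seed produce bit-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (data.frame of file and md5), and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- "load"
  out <- tryCatch({
    table <- read_feature_table(file.path(config$input_dir, "taxon_table.tsv"), "taxon")
    tax <- read_taxonomy_table(file.path(config$input_dir, "taxonomy.tsv"))
    meta <- read_sample_metadata(file.path(config$input_dir, "metadata.tsv"))
    fo_path <- file.path(config$input_dir, "fo_table.tsv")
    fo <- if (file.exists(fo_path)) read_feature_table(fo_path, "functional_ortholog")
    map_path <- file.path(config$input_dir, "pathway_map.tsv")
    map <- if (file.exists(map_path)) read_pathway_map(map_path)

    if ("filter" %in% config$stages) {
      stage <- "filter"
      table <- prune_zero_features(
        filter_low_depth(filter_nonbacterial(table, tax), config$min_reads))
      genus <- collapse_to_rank(table, tax, "genus")
      write_feature_table(genus, file.path(config$outdir, "genus_table.tsv"),
                          header = sprintf("gutcore filtered genus table seed=%d",
                                           config$seed))
      pipeline_log("filter: %d features, %d samples retained",
                   nrow(table$counts), ncol(table$counts))
    } else {
      genus <- collapse_to_rank(table, tax, "genus")
    }
    meta_f <- meta[meta$sample_id %in% sample_ids(genus), , drop = FALSE]
    res$genus_table <- genus

    if ("profile" %in% config$stages) {
      stage <- "profile"
      prof <- dataset_mean_relabund(genus, meta_f)
      res$profiles <- prof
      write_dataset_profiles(prof, file.path(config$outdir, "dataset_profiles.tsv"))
      gm <- grand_mean_relabund(prof)
      write_tsv_prov(data.frame(taxon = names(gm), grand_mean_relabund = gm),
                     file.path(config$outdir, "grand_mean_relabund.tsv"), config)
      summ <- corpus_summary(table, tax, meta_f, fo_table = fo)
      write_tsv_prov(summ, file.path(config$outdir, "corpus_summary.tsv"), config)
      pipeline_log("profile: %d datasets summarized", ncol(prof$abund))
    }

    if ("core" %in% config$stages) {
      stage <- "core"
      prev <- prevalence_by_dataset(genus, meta_f)
      prof <- res$profiles %||% dataset_mean_relabund(genus, meta_f)
      grid <- core_screen_grid(prev, profiles = prof)
      write_core_grid(grid, file.path(config$outdir, "core_grid.tsv"))
      core <- core_genera(prev, config$t1, config$t2)
      res$core <- core
      write_tsv_prov(data.frame(genus = core),
                     file.path(config$outdir, "core_genera.tsv"), config)
      pipeline_log("core: %d core genera at (%g, %g)", length(core),
                   config$t1, config$t2)
    }

    if ("alpha" %in% config$stages) {
      stage <- "alpha"
      adf <- alpha_diversity(genus)
      write_tsv_prov(adf, file.path(config$outdir, "alpha_diversity.tsv"), config)
      am <- match_metadata(genus, meta_f)
      preds <- select_estimable_predictors(adf$shannon, am, .lmm_predictors)
      if (length(unique(am$bioproject_id)) >= 2 && length(preds) >= 1) {
        fit <- fit_lmm(adf$shannon, am, preds)
        red <- reduce_model(fit)
        rep_df <- red$coefficients
        rep_df$agvif <- if (length(red$predictors) > 0)
          red$agvif[term_of_coefficient(red)[rep_df$term]] else NA_real_
        write_tsv_prov(rep_df, file.path(config$outdir, "alpha_model.tsv"), config)
        write_tsv_prov(data.frame(model = c("full", "reduced"),
                                  aic_ml = c(attr(red, "aic_full"),
                                             attr(red, "aic_reduced"))),
                       file.path(config$outdir, "alpha_model_aic.tsv"), config)
        res$alpha_model <- red
        pipeline_log("alpha: reduced model keeps %s",
                     paste(red$predictors, collapse = ", "))
      } else {
        pipeline_log("alpha: mixed model skipped (needs >= 2 BioProjects and a varying predictor)")
      }
      res$alpha <- adf
    }

    if ("beta" %in% config$stages) {
      stage <- "beta"
      bc <- bray_curtis(genus)
      write_distance_matrix(bc, file.path(config$outdir, "bray_curtis.tsv"))
      pc <- pcoa(bc)
      write_tsv_prov(data.frame(sample_id = rownames(pc$coordinates),
                                pc$coordinates[, seq_len(min(3, ncol(pc$coordinates))),
                                               drop = FALSE]),
                     file.path(config$outdir, "pcoa_coordinates.tsv"), config)
      am <- match_metadata(genus, meta_f)
      factors <- list(segment = am$segment, continent = am$continent,
                      bird_type = am$bird_type, housing = am$housing,
                      hv_region = factor(am$hv_region),
                      age_category = age_categorize(am$doa))
      rows <- list()
      for (nm in names(factors)) {
        g <- droplevels(factor(factors[[nm]]))
        if (nlevels(g) < 2 || any(table(g) < 2)) next
        disp <- dispersion_test(bc, g, n_perm = config$n_perm,
                                seed = config$seed + 11L)
        pv <- permanova(bc, g, n_perm = config$n_perm,
                        seed = config$seed + 13L, factor_name = nm)
        rows[[nm]] <- data.frame(
          factor_name = nm, pseudo_f = pv$pseudo_f, r2 = pv$r2, p = pv$p,
          dispersion_p_anova = disp$p_anova, dispersion_p_perm = disp$p_perm,
          interpretation = if (disp$p_perm < 0.05) "descriptive (heterogeneous dispersion)"
                           else "inferential")
      }
      beta_df <- do.call(rbind, rows)
      write_tsv_prov(beta_df, file.path(config$outdir, "beta_results.tsv"), config)
      res$beta <- beta_df
      pipeline_log("beta: %d factors tested", nrow(beta_df))
    }

    if ("stability" %in% config$stages && !is.null(fo)) {
      stage <- "stability"
      keep <- intersect(sample_ids(fo), meta_f$sample_id)
      fo_f <- subset_feature_table(fo, samples = keep)
      fm <- match_metadata(fo_f, meta_f)
      g <- droplevels(fm$segment)
      stab <- pairwise_stability(fo_f, g, alpha = config$alpha)
      res$stability <- stab
      write_stability_matrix(stab, file.path(config$outdir, "stability_matrix.tsv"))
      sets <- Filter(Negate(is.null), stab$ndfo_sets)
      if (length(sets) >= 2) {
        inter <- intersect_ndfo(sets)
        res$intersection <- inter
        write_tsv_prov(data.frame(fo_id = rownames(inter$membership),
                                  inter$membership * 1, check.names = FALSE),
                       file.path(config$outdir, "ndfo_membership.tsv"), config)
        write_tsv_prov(data.frame(fo_id = inter$conserved),
                       file.path(config$outdir, "ndfo_conserved.tsv"), config)
        pipeline_log("stability: %d conserved nDFOs over %d comparisons",
                     length(inter$conserved), length(sets))
      }
    }

    if ("enrich" %in% config$stages && !is.null(map) &&
        !is.null(res$intersection) && length(res$intersection$conserved) > 0) {
      stage <- "enrich"
      # universe = FOs tested in at least one comparison; conserved is a subset
      universe <- sort(unique(unlist(res$stability$universes)))
      enr <- enrich_pathways(res$intersection$conserved, map, universe)
      res$enrichment <- enr
      write_tsv_prov(as.data.frame(enr),
                     file.path(config$outdir, "enrichment.tsv"), config)
      pipeline_log("enrich: top pathway %s (padj = %.3g)",
                   enr$pathway_id[1], enr$padj[1])
    }

    files <- sort(list.files(config$outdir, pattern = "\\.tsv$", full.names = TRUE))
    files <- setdiff(files, file.path(config$outdir, "manifest.tsv"))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.table(manifest, file.path(config$outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(status = 0L, manifest = manifest, results = res)
  }, error = function(e) {
    pipeline_log("stage '%s' failed: %s", stage, conditionMessage(e))
    list(status = 1L, failed_stage = stage, error = conditionMessage(e),
         results = res)
  })
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
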