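# End-to-end pipeline: simulate (or ingest) -> genotype -> phenostats ->
# assoc -> select -> enrich, with a manifest recording seed, thresholds
# and per-stage record counts. Each stage reads and writes plain-text
# tables in the artifact directory, so stages can also be run singly.

stage_path <- function(out_dir, name) file.path(out_dir, name)

#' Simulation stage: generate a synthetic experiment into a directory
#'
#' @param config run configuration (see [default_run_config()]).
#' @param out_dir artifact directory (created if absent).
#' @param seed master seed (defaults to `config$seed`).
#' @return file paths written, invisibly.
#' @export
stage_simulate <- function(config = default_run_config(), out_dir,
                           seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config$sim, seed = seed)
  write_table_stable(sim$survival, stage_path(out_dir, "survival.csv"))
  write_table_stable(sim$plates, stage_path(out_dir, "plates.csv"))
  write_table_stable(sim$samples, stage_path(out_dir, "samples.tsv"))
  write_table_stable(sim$registry, stage_path(out_dir, "registry.tsv"))
  reg_cols <- sim$registry[match(sim$parent_counts$locus_id,
                                 sim$registry$locus_id),
                           c("contig", "position")]
  write_table_stable(cbind(sim$parent_counts["locus_id"],
                           reg_cols, sim$parent_counts[, -1L]),
                     stage_path(out_dir, "parent_counts.tsv"))
  write_table_stable(sim$pool_counts, stage_path(out_dir, "pool_counts.tsv"))
  write_gene_map(sim$gene2go, stage_path(out_dir, "gene2go.tsv"))
  write_matrix_tsv(sim$parent_genotypes / 2,
                   stage_path(out_dir, "truth_parent_freq.tsv"))
  truth <- list(seed = seed,
                causal = sim$truth$causal,
                anchor = sim$truth$anchor)
  yaml::write_yaml(list(seed = truth$seed, anchor = truth$anchor,
                        causal_loci = sim$truth$causal$locus_id,
                        causal_effect = sim$truth$causal$effect),
                   stage_path(out_dir, "truth.yaml"))
  write_table_stable(sim$truth$expected_survival,
                     stage_path(out_dir, "truth_expected_survival.tsv"))
  invisible(out_dir)
}

#' Genotyping stage: call genotypes and pooled MAFs from count tables
#'
#' @inheritParams stage_simulate
#' @return list with the filtered matrices and filter report, invisibly.
#' @export
stage_genotype <- function(config = default_run_config(), out_dir) {
  g <- config$genotype
  registry <- read_registry(stage_path(out_dir, "registry.tsv"))
  parent_counts <- read_counts_table(stage_path(out_dir, "parent_counts.tsv"))
  pool_counts <- read_counts_table(stage_path(out_dir, "pool_counts.tsv"))
  samples <- read_samples_table(stage_path(out_dir, "samples.tsv"))
  parent_mat <- call_parent_genotypes(parent_counts, registry,
                                      error_maf = g$error_maf,
                                      min_cov = g$min_parent_cov)
  amb_ids <- samples$sample_id[samples$temperature ==
                                 config$phenostats$ambient_temperature]
  minor <- designate_minor_alleles(
    pool_counts[pool_counts$sample_id %in% amb_ids, , drop = FALSE], registry)
  pooled_mat <- call_pooled_maf(pool_counts, minor,
                                min_cov = g$min_pool_cov)
  filt <- filter_genotype_data(parent_mat, pooled_mat,
                               g$max_missing_per_sample,
                               g$max_missing_per_locus)
  write_matrix_tsv(filt$parent, stage_path(out_dir, "parent_genotypes.tsv"))
  write_matrix_tsv(filt$pooled, stage_path(out_dir, "pooled_maf.tsv"))
  write_table_stable(minor, stage_path(out_dir, "minor_alleles.tsv"))
  write_table_stable(data.frame(step = names(filt$report),
                                n_removed = unlist(filt$report)),
                     stage_path(out_dir, "filter_report.tsv"), sort = FALSE)
  write_vcf_gt(filt$parent, registry,
               stage_path(out_dir, "parent_genotypes.vcf"))
  invisible(filt)
}

#' Phenotype-statistics stage
#'
#' @inheritParams stage_simulate
#' @return list of result tables, invisibly.
#' @export
stage_phenostats <- function(config = default_run_config(), out_dir,
                             seed = config$seed) {
  ph <- config$phenostats
  survival <- read_survival_table(stage_path(out_dir, "survival.csv"))
  plates <- read_survival_table(stage_path(out_dir, "plates.csv"))
  rel <- relative_survival(survival, ph$ambient_temperature)
  rel_plates <- relative_survival(plates, ph$ambient_temperature)
  om <- origin_effect_model(rel, ph$transform_power)
  hot_plates <- rel_plates[rel_plates$temperature == ph$hot_temperature, ]
  decline <- family_decline_tests(hot_plates)
  ve_family <- variance_explained(hot_plates, "family_id",
                                  transform_power = ph$transform_power)
  ve_parents <- variance_explained(hot_plates, c("dam_id", "sire_id"),
                                   transform_power = ph$transform_power)
  si <- survival_index(survival, ph$hot_temperature)
  hcfg <- config$heritability
  chain <- list(n_iter = hcfg$n_iter, burn_in = hcfg$burn_in,
                thin = hcfg$thin)
  priors <- list(nu = hcfg$nu, V = hcfg$V)
  # Elevated temperatures use ambient-standardized survival; the ambient
  # treatment (the standardization reference) uses raw plate survival.
  h2 <- list()
  for (tmp in sort(unique(plates$temperature))) {
    if (tmp == ph$ambient_temperature) {
      d <- plates[plates$temperature == tmp, ]
      y <- d$n_alive_60h / d$n_start
    } else {
      d <- rel_plates[rel_plates$temperature == tmp, ]
      y <- d$rel_survival
    }
    h2[[as.character(tmp)]] <- estimate_heritability(
      y, d$sire_id, d$dam_id, chain = chain, priors = priors,
      seed = derive_seed(seed, 40L + tmp))
  }
  h2tab <- do.call(rbind, lapply(names(h2), function(tk) {
    s <- h2[[tk]]$summary
    data.frame(temperature = as.numeric(tk),
               statistic = rownames(s), s, row.names = NULL)
  }))
  write_table_stable(rel, stage_path(out_dir, "relative_survival.csv"))
  write_table_stable(decline, stage_path(out_dir, "decline_tests.csv"))
  write_table_stable(rbind(ve_family, ve_parents),
                     stage_path(out_dir, "variance_explained.csv"))
  write_table_stable(si$families, stage_path(out_dir, "survival_index.csv"))
  write_table_stable(si$sires, stage_path(out_dir, "sire_index.csv"))
  write_table_stable(h2tab, stage_path(out_dir, "heritability.csv"))
  invisible(list(rel = rel, origin_model = om, decline = decline,
                 variance = rbind(ve_family, ve_parents), index = si,
                 heritability = h2))
}

#' Association stage
#'
#' @inheritParams stage_simulate
#' @return list of result tables, invisibly.
#' @export
stage_assoc <- function(config = default_run_config(), out_dir) {
  a <- config$assoc
  ph <- config$phenostats
  pooled <- read_matrix_tsv(stage_path(out_dir, "pooled_maf.tsv"))
  samples <- read_samples_table(stage_path(out_dir, "samples.tsv"))
  survival <- read_survival_table(stage_path(out_dir, "survival.csv"))
  minor <- read_table_checked(stage_path(out_dir, "minor_alleles.tsv"),
                              c("locus_id", "major", "minor"))
  registry <- read_registry(stage_path(out_dir, "registry.tsv"))
  parent_mat <- read_matrix_tsv(stage_path(out_dir, "parent_genotypes.tsv"))
  sire_index <- read_table_checked(stage_path(out_dir, "sire_index.csv"),
                                   c("sire_id", "index"), "index",
                                   sep = ",")
  amb <- samples[samples$temperature == ph$ambient_temperature, ]
  amb <- amb[amb$sample_id %in% rownames(pooled), ]
  maf <- pooled[amb$sample_id, , drop = FALSE]
  rownames(maf) <- amb$family_id
  sv <- survival[survival$temperature == ph$hot_temperature, ]
  scan <- scan_survival_association(maf, sv, minor_alleles = minor,
                                    strong_r = a$strong_r, alpha = a$alpha,
                                    min_families = a$min_families)
  sig <- scan[scan$significant & !is.na(scan$beneficial_allele), ]
  scores <- NULL; perf <- NULL
  if (nrow(sig)) {
    scores <- score_parents(parent_mat, sig, registry)
    sires <- scores[scores$parent_id %in% sire_index$sire_id, ]
    perf <- tryCatch(correlate_parent_performance(sires, sire_index),
                     error = function(e) NULL)
  }
  strong <- scan$locus_id[scan$class == "strong"]
  clust <- NULL
  sire_rows <- intersect(rownames(parent_mat), unique(survival$sire_id))
  if (length(strong) >= 2L && length(sire_rows) >= 2L) {
    clust <- cluster_paternal_genotypes(parent_mat[sire_rows, , drop = FALSE],
                                        strong, min_shared = a$min_shared)
    writeLines(dendrogram_newick(clust$hclust),
               stage_path(out_dir, "paternal_clustering.nwk"))
    write_matrix_tsv(clust$correlation,
                     stage_path(out_dir, "paternal_correlation.tsv"))
  }
  write_table_stable(scan, stage_path(out_dir, "assoc_results.tsv"))
  if (!is.null(scores))
    write_table_stable(scores, stage_path(out_dir, "parent_scores.tsv"))
  if (!is.null(perf))
    write_table_stable(data.frame(r = perf$r, p = perf$p, n = perf$n),
                       stage_path(out_dir, "parent_performance.tsv"))
  invisible(list(scan = scan, scores = scores, performance = perf,
                 clustering = clust))
}

#' Selection stage
#'
#' @inheritParams stage_simulate
#' @return list with the scans, summary and PCA, invisibly.
#' @export
stage_select <- function(config = default_run_config(), out_dir) {
  s <- config$select
  ph <- config$phenostats
  pool_counts <- read_counts_table(stage_path(out_dir, "pool_counts.tsv"))
  samples <- read_samples_table(stage_path(out_dir, "samples.tsv"))
  minor <- read_table_checked(stage_path(out_dir, "minor_alleles.tsv"),
                              c("locus_id", "major", "minor"))
  pooled <- read_matrix_tsv(stage_path(out_dir, "pooled_maf.tsv"))
  scans <- run_selection_scans(pool_counts, samples, minor,
                               ambient = ph$ambient_temperature,
                               hot = ph$hot_temperature, alpha = s$alpha)
  summ <- summarize_selection(scans,
                              fixation_threshold = s$fixation_threshold)
  for (nm in names(scans))
    write_table_stable(scans[[nm]],
                       stage_path(out_dir,
                                  sprintf("selection_%s.tsv", nm)))
  write_table_stable(summ$by_origin,
                     stage_path(out_dir, "selection_summary.tsv"))
  pca <- NULL
  if ("PGxIO" %in% names(scans)) {
    meta <- samples[samples$sample_id %in% rownames(pooled), ]
    pca <- tryCatch(
      hybrid_shift_pca(pooled, meta, scans[["PGxIO"]],
                       pca_alpha = s$pca_alpha,
                       max_missing = s$pca_missing),
      error = function(e) {
        message("hybrid PCA skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(pca))
      write_table_stable(pca$coords, stage_path(out_dir, "pca_coords.tsv"))
  }
  invisible(list(scans = scans, summary = summ, pca = pca))
}

#' Enrichment stage
#'
#' @inheritParams stage_simulate
#' @return list of enrichment tables (or `NULL` when no annotation map is
#'   present), invisibly.
#' @export
stage_enrich <- function(config = default_run_config(), out_dir) {
  e <- config$enrich
  map_path <- stage_path(out_dir, "gene2go.tsv")
  if (!file.exists(map_path)) {
    message("enrichment skipped: no gene2go.tsv in ", out_dir)
    return(invisible(NULL))
  }
  gene2go <- read_gene_map(map_path)
  registry <- read_registry(stage_path(out_dir, "registry.tsv"))
  assoc <- read_table_checked(stage_path(out_dir, "assoc_results.tsv"),
                              c("locus_id", "p_adj"), "p_adj")
  out <- list()
  run_one <- function(sig, tested, label) {
    sets <- genes_from_loci(sig, tested, registry)
    res <- fisher_enrichment(sets$study, sets$background, gene2go,
                             min_background = e$min_background,
                             alpha = e$alpha)
    write_table_stable(res, stage_path(out_dir,
                                       sprintf("enrichment_%s.tsv", label)))
    res
  }
  sig_assoc <- assoc$locus_id[assoc$p_adj < e$alpha]
  if (length(sig_assoc))
    out$predictive <- run_one(sig_assoc, assoc$locus_id, "predictive")
  sel_path <- stage_path(out_dir, "selection_all.tsv")
  if (file.exists(sel_path)) {
    sel <- read_table_checked(sel_path, c("locus_id", "p_adj"), "p_adj")
    sig_sel <- sel$locus_id[sel$p_adj < e$alpha]
    if (length(sig_sel))
      out$selection <- run_one(sig_sel, sel$locus_id, "selection")
  }
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes simulate -> genotype -> phenostats -> assoc -> select ->
#' enrich into `out_dir` and writes a manifest with the package version,
#' seed, thresholds and per-stage record counts. A stage failure aborts
#' with the stage name while preserving earlier outputs.
#'
#' @param config run configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param out_dir artifact directory.
#' @param seed master seed overriding `config$seed`.
#' @param simulate logical; when `FALSE` the input tables are expected to
#'   be present in `out_dir` already (ingest mode).
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = config$seed, simulate = TRUE) {
  config$seed <- seed
  res <- list()
  stages <- list(
    simulate = function() if (simulate) stage_simulate(config, out_dir, seed),
    genotype = function() stage_genotype(config, out_dir),
    phenostats = function() stage_phenostats(config, out_dir, seed),
    assoc = function() stage_assoc(config, out_dir),
    select = function() stage_select(config, out_dir),
    enrich = function() stage_enrich(config, out_dir))
  for (nm in names(stages)) {
    res[[nm]] <- tryCatch(stages[[nm]](), error = function(e)
      stop_param(sprintf("pipeline stage '%s' failed: %s", nm,
                         conditionMessage(e))))
  }
  manifest <- list(
    package = "reefcross",
    version = as.character(utils::packageVersion("reefcross")),
    seed = seed,
    thresholds = config[c("genotype", "assoc", "select", "enrich")],
    records = list(
      survival_rows = nrow(read_survival_table(
        stage_path(out_dir, "survival.csv"))),
      parent_samples = nrow(res$genotype$parent),
      parent_loci = ncol(res$genotype$parent),
      pooled_samples = nrow(res$genotype$pooled),
      pooled_loci = ncol(res$genotype$pooled),
      assoc_loci_tested = attr(res$assoc$scan, "n_tested"),
      selection_scans = length(res$select$scans),
      enrichment_terms = if (!is.null(res$enrich$predictive))
        nrow(res$enrich$predictive) else 0L))
  yaml::write_yaml(manifest, stage_path(out_dir, "manifest.yaml"))
  invisible(res)
}
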