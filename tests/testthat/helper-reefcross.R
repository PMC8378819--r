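# Shared fixture builders for the unit and acceptance tests.

nt <- c("A", "C", "G", "T")

counts_vec <- function(A = 0, C = 0, G = 0, T = 0) {
  c(A = A, C = C, G = G, T = T)
}

# Small registry for hand-built genotyping fixtures.
toy_registry <- function(n = 3, ref = rep("A", n), alt = rep("G", n)) {
  data.frame(locus_id = sprintf("L%05d", seq_len(n)),
             contig = "ctg001", position = seq_len(n) - 1L,
             ref = ref, alt = alt, gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

# Reduced pipeline configuration used by the pipeline and CLI tests.
tiny_config <- function() {
  cfg <- default_run_config()
  cfg$sim <- utils::modifyList(cfg$sim, list(
    n_loci = 200, n_causal = 5, n_larvae_per_family = 90,
    parent_mean_depth = 40, pool_mean_depth = 80))
  cfg$heritability$n_iter <- 2e4
  cfg$heritability$burn_in <- 2e3
  cfg
}

# One planted-signal association replicate: 400 single-cross families with
# unique parents (200 hot-origin, 200 cool-origin), 20 causal loci of equal
# effect, no extra-binomial family noise, association scanned on the
# ambient survivor-pool frequencies against 36-degree survival.
planted_assoc_rep <- function(seed) {
  m <- population_model(n_loci = 2000, divergence = 0.1, causal_loci = 20,
                        causal_effect = 0.16, beneficial_freq_hot = 0.7,
                        beneficial_freq_cool = 0.3, fixation_fraction = 0)
  pops <- simulate_populations(m, seed = seed)
  dams <- c(sprintf("PG-D%03d", 1:200), sprintf("IO-D%03d", 1:200))
  sires <- c(sprintf("PG-S%03d", 1:200), sprintf("IO-S%03d", 1:200))
  des <- data.frame(family_id = paste(dams, sires, sep = "x"),
                    dam_id = dams, sire_id = sires,
                    origin = rep(c("PG", "IO"), each = 200),
                    stringsAsFactors = FALSE)
  par <- draw_design_parents(des, pops, seed = seed)
  s <- simulate_family_survival(des, par, pops, n_larvae_per_family = 120,
                                temperatures = c(27, 36),
                                baseline_survival = c("27" = 0.95, "36" = 0.5),
                                temp_scale = c("27" = 0, "36" = 1),
                                dam_effect_sd = 0, family_effect_sd = 0,
                                seed = seed)
  amb <- s$samples[s$samples$temperature == 27, ]
  maf <- s$pool_freq[amb$sample_id, , drop = FALSE]
  rownames(maf) <- amb$family_id
  sv <- s$survival[s$survival$temperature == 36, ]
  list(scan = scan_survival_association(maf, sv),
       causal = pops$causal$locus_id)
}

# One global-null replicate on the default 50-family crossed design
# with genotype-independent noise channels (dam and family intercepts)
# switched off, so survival is independent of every locus.
null_assoc_rep <- function(seed) {
  des <- make_cross_design()
  m <- population_model(n_loci = 2000, causal_loci = 0)
  pops <- simulate_populations(m, seed = seed)
  par <- draw_design_parents(des, pops, seed = seed)
  s <- simulate_family_survival(des, par, pops, n_larvae_per_family = 180,
                                temperatures = c(27, 36),
                                baseline_survival = c("27" = 0.95, "36" = 0.55),
                                temp_scale = c("27" = 0, "36" = 1),
                                dam_effect_sd = 0, family_effect_sd = 0,
                                seed = seed)
  amb <- s$samples[s$samples$temperature == 27, ]
  maf <- s$pool_freq[amb$sample_id, , drop = FALSE]
  rownames(maf) <- amb$family_id
  sv <- s$survival[s$survival$temperature == 36, ]
  sum(scan_survival_association(maf, sv)$significant)
}

# One selection-scan ordering replicate at the shipped defaults, with the
# 33-degree arm dropped (it plays no role in the 27-vs-36 contrast) and
# per-arm larval numbers preserved.
ordering_rep <- function(seed) {
  sim <- simulate_experiment(list(temperatures = c(27, 36),
                                  baseline_survival = c("27" = 0.95, "36" = 0.55),
                                  temp_scale = c("27" = 0, "36" = 1),
                                  n_larvae_per_family = 180), seed = seed)
  amb_ids <- sim$samples$sample_id[sim$samples$temperature == 27]
  minors <- designate_minor_alleles(
    sim$pool_counts[sim$pool_counts$sample_id %in% amb_ids, ], sim$registry)
  scans <- run_selection_scans(sim$pool_counts, sim$samples, minors)
  vapply(c("IO", "PGxIO", "PG"), function(o)
    if (o %in% names(scans)) mean(scans[[o]]$significant) else NA_real_,
    numeric(1))
}

# One hybrid-PCA replicate under strong selection: 12 causal loci of
# effect 1.2 on a 50-family design with unique parents per cross,
# sequenced at 300x. Returns the PC1-2 distances of the hybrid centroids
# to the hot-purebred centroid.
pca_shift_rep <- function(seed) {
  m <- population_model(n_loci = 2000, divergence = 0.1, causal_loci = 12,
                        causal_effect = 1.2, beneficial_freq_hot = 0.6,
                        beneficial_freq_cool = 0.2, fixation_fraction = 0)
  pops <- simulate_populations(m, seed = seed)
  pg_d <- sprintf("PG-D%02d", 1:38); io_d <- sprintf("IO-D%02d", 1:12)
  pg_s <- sprintf("PG-S%02d", 1:18); io_s <- sprintf("IO-S%02d", 1:32)
  des <- rbind(
    data.frame(dam_id = pg_d[1:18], sire_id = pg_s, origin = "PG"),
    data.frame(dam_id = io_d, sire_id = io_s[1:12], origin = "IO"),
    data.frame(dam_id = pg_d[19:38], sire_id = io_s[13:32], origin = "PGxIO"))
  des <- data.frame(family_id = paste(des$dam_id, des$sire_id, sep = "x"),
                    des, stringsAsFactors = FALSE)
  par <- draw_design_parents(des, pops, seed = seed)
  s <- simulate_family_survival(des, par, pops, n_larvae_per_family = 180,
                                temperatures = c(27, 36),
                                baseline_survival = c("27" = 0.95, "36" = 0.55),
                                temp_scale = c("27" = 0, "36" = 1),
                                seed = seed)
  pool_counts <- emit_read_counts(s$pool_freq, pops$registry,
                                  mean_depth = 300, error_rate = 0.005,
                                  seed = seed)
  amb_ids <- s$samples$sample_id[s$samples$temperature == 27]
  minors <- designate_minor_alleles(
    pool_counts[pool_counts$sample_id %in% amb_ids, ], pops$registry)
  maf <- call_pooled_maf(pool_counts, minors)
  hyb <- scan_selection(pool_counts, s$samples, minors, origin = "PGxIO")
  pca <- hybrid_shift_pca(maf, s$samples, hyb)
  co <- pca$coords
  centroid <- function(sel) colMeans(co[sel, c("PC1", "PC2"), drop = FALSE])
  pg <- centroid(co$origin == "PG")
  d27 <- sqrt(sum((centroid(co$origin == "PGxIO" & co$temperature == 27) - pg)^2))
  d36 <- sqrt(sum((centroid(co$origin == "PGxIO" & co$temperature == 36) - pg)^2))
  list(n_loci = length(pca$loci), d27 = d27, d36 = d36)
}

# One heritability-recovery replicate: plate-level responses simulated
# directly from the Gaussian sire-dam model on the realized 50-family
# design with 3 replicates, V_dam = 0.1, V_e = 0.9 and V_sire solved from
# the target h2 under the with-maternal formula.
herit_rep <- function(seed, h2_true) {
  des <- make_cross_design()
  v_dam <- 0.1; v_e <- 0.9
  v_sire <- h2_true * (v_dam + v_e) / (4 * (1 - h2_true))
  set.seed(seed)
  sires <- unique(des$sire_id); dams <- unique(des$dam_id)
  su <- stats::setNames(rnorm(length(sires), 0, sqrt(v_sire)), sires)
  du <- stats::setNames(rnorm(length(dams), 0, sqrt(v_dam)), dams)
  d <- des[rep(seq_len(nrow(des)), each = 3), ]
  y <- su[d$sire_id] + du[d$dam_id] + rnorm(nrow(d), 0, sqrt(v_e))
  fit <- suppressWarnings(
    estimate_heritability(y, d$sire_id, d$dam_id, seed = seed))
  ci <- fit$summary["h2_with_maternal", c("lower95", "upper95")]
  ci[[1]] <= h2_true && h2_true <= ci[[2]]
}
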