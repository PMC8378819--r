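# Forward simulator for a two-population coral breeding experiment:
# diverged source allele frequencies, a dam x sire cross design with
# one-direction hybrids, genotype-dependent heat mortality of larvae, and
# pooled read-count sampling with sequencing error.

#' Define a two-population genetic model
#'
#' Describes the loci segregating in a hot-adapted and a cool-adapted source
#' population. Non-causal loci share an ancestral frequency perturbed
#' symmetrically in the two populations; causal loci carry a beneficial
#' (heat-survival increasing) derived allele at higher frequency in the hot
#' population, with a configurable fraction fixed there.
#'
#' @param n_loci number of biallelic loci.
#' @param divergence standard deviation, in (0, 1), of the symmetric
#'   between-population perturbation of non-causal allele frequencies.
#' @param causal_loci either a single count of causal loci (sampled at
#'   simulation time) or an explicit integer vector of locus indices.
#' @param causal_effect per-allele-copy log-odds increment to heat survival
#'   (> 0 means the derived allele is beneficial). Scalar or one value per
#'   causal locus.
#' @param beneficial_freq_hot,beneficial_freq_cool frequency of the
#'   beneficial allele in the hot and cool population at non-fixed causal
#'   loci. Must satisfy `beneficial_freq_hot >= beneficial_freq_cool`.
#' @param fixation_fraction fraction of causal loci at which the beneficial
#'   allele is fixed (frequency 1) in the hot population.
#' @return an object of class `population_model`.
#' @export
population_model <- function(n_loci = 2000,
                             divergence = 0.1,
                             causal_loci = 20,
                             causal_effect = 0.5,
                             beneficial_freq_hot = 0.42,
                             beneficial_freq_cool = 0.28,
                             fixation_fraction = 0.1) {
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1)
    stop_param("'n_loci' must be a positive count")
  n_loci <- as.integer(n_loci)
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      divergence < 0 || divergence >= 1)
    stop_param("'divergence' must lie in [0, 1)")
  if (length(causal_loci) == 1L && causal_loci >= 0 &&
      (causal_loci == floor(causal_loci))) {
    n_causal <- as.integer(causal_loci)
    idx <- NULL
  } else {
    idx <- sort(unique(as.integer(causal_loci)))
    if (length(idx) && (min(idx) < 1L || max(idx) > n_loci))
      stop_param("'causal_loci' indices must lie in 1..n_loci")
    n_causal <- length(idx)
  }
  check_prob(beneficial_freq_hot, "beneficial_freq_hot")
  check_prob(beneficial_freq_cool, "beneficial_freq_cool")
  if (any(beneficial_freq_hot < beneficial_freq_cool))
    stop_param("'beneficial_freq_hot' must be >= 'beneficial_freq_cool'")
  check_prob(fixation_fraction, "fixation_fraction")
  structure(list(n_loci = n_loci, divergence = divergence,
                 n_causal = n_causal, causal_idx = idx,
                 causal_effect = causal_effect,
                 beneficial_freq_hot = beneficial_freq_hot,
                 beneficial_freq_cool = beneficial_freq_cool,
                 fixation_fraction = fixation_fraction),
            class = "population_model")
}

locus_ids <- function(n) sprintf("L%05d", seq_len(n))

make_locus_registry <- function(n_loci, seed) {
  set.seed(derive_seed(seed, 11L))
  ref <- sample(NUCLEOTIDES, n_loci, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(NUCLEOTIDES, b), 1L), "")
  data.frame(locus_id = locus_ids(n_loci),
             contig = sprintf("ctg%03d", ((seq_len(n_loci) - 1L) %/% 50L) + 1L),
             position = as.integer(((seq_len(n_loci) - 1L) %% 50L) * 36L),
             ref = ref, alt = unname(alt),
             gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate diverged source-population allele frequencies
#'
#' Draws derived-allele frequencies for the hot and cool population. The
#' ancestral (reference) allele is the registry reference base; frequencies
#' refer to the derived (alternate) allele. At causal loci the derived
#' allele is beneficial under heat and is at least as frequent in the hot
#' population; a `fixation_fraction` of causal loci (the first ones in
#' index order) are fixed in the hot population.
#'
#' @param model a [population_model()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list with elements `registry` (locus table with reference and
#'   alternate base), `freq_hot`, `freq_cool` (named derived-allele
#'   frequency vectors) and `causal` (data frame of locus id, per-copy
#'   effect and hot-population fixation flag).
#' @export
simulate_populations <- function(model, seed = 1L) {
  stopifnot(inherits(model, "population_model"))
  registry <- make_locus_registry(model$n_loci, seed)
  set.seed(derive_seed(seed, 12L))
  n <- model$n_loci
  ancestral <- runif(n, 0.05, 0.95)
  noise_hot <- rnorm(n, 0, model$divergence / 2)
  noise_cool <- rnorm(n, 0, model$divergence / 2)
  freq_hot <- pmin(pmax(ancestral + noise_hot, 0), 1)
  freq_cool <- pmin(pmax(ancestral + noise_cool, 0), 1)

  idx <- model$causal_idx
  if (is.null(idx) && model$n_causal > 0L)
    idx <- sort(sample.int(n, model$n_causal))
  k <- length(idx)
  causal <- data.frame(locus_id = character(0), effect = numeric(0),
                       fixed_hot = logical(0), stringsAsFactors = FALSE)
  if (k > 0L) {
    n_fixed <- round(model$fixation_fraction * k)
    fixed <- seq_len(k) <= n_fixed
    fh <- rep_len(model$beneficial_freq_hot, k)
    fc <- rep_len(model$beneficial_freq_cool, k)
    fh[fixed] <- 1
    freq_hot[idx] <- fh
    freq_cool[idx] <- fc
    causal <- data.frame(locus_id = registry$locus_id[idx],
                         effect = rep_len(model$causal_effect, k),
                         fixed_hot = fixed, stringsAsFactors = FALSE)
  }
  names(freq_hot) <- names(freq_cool) <- registry$locus_id
  list(registry = registry, freq_hot = freq_hot, freq_cool = freq_cool,
       causal = causal)
}

#' Draw diploid parental genotypes under Hardy-Weinberg proportions
#'
#' @param freq named vector of derived-allele frequencies.
#' @param n_parents number of individuals to draw.
#' @param seed integer seed.
#' @param ids optional character vector of parent identifiers.
#' @return integer matrix (parents x loci) of derived-allele copy counts in
#'   \{0, 1, 2\}.
#' @export
draw_parents <- function(freq, n_parents, seed = 1L, ids = NULL) {
  check_prob(freq, "freq")
  stopifnot(n_parents >= 1)
  set.seed(derive_seed(seed, 13L))
  g <- matrix(rbinom(n_parents * length(freq), 2L, rep(freq, each = n_parents)),
              nrow = n_parents)
  rownames(g) <- ids %||% sprintf("P%03d", seq_len(n_parents))
  colnames(g) <- names(freq)
  g
}

#' Enumerate a realized dam x sire cross design
#'
#' Crosses are enumerated deterministically, dam-major then sire, within
#' each origin category; when fewer crosses were realized than the
#' combinatorial maximum the last-enumerated pairs are dropped. Hybrids run
#' in a single direction: cool-origin dam x hot-origin sire.
#'
#' @param n_hot_sires,n_cool_sires,n_hot_dams,n_cool_dams parents per
#'   region (hot = "PG", cool = "IO").
#' @param realized named vector of realized family counts per category
#'   (`PG`, `IO`, `PGxIO`).
#' @return a data frame with columns `family_id`, `dam_id`, `sire_id`,
#'   `origin`.
#' @export
make_cross_design <- function(n_hot_sires = 10, n_cool_sires = 7,
                              n_hot_dams = 2, n_cool_dams = 2,
                              realized = c(PG = 18, IO = 12, PGxIO = 20)) {
  stopifnot(all(c("PG", "IO", "PGxIO") %in% names(realized)))
  hot_sires <- sprintf("PG-S%02d", seq_len(n_hot_sires))
  cool_sires <- sprintf("IO-S%02d", seq_len(n_cool_sires))
  hot_dams <- sprintf("PG-D%d", seq_len(n_hot_dams))
  cool_dams <- sprintf("IO-D%d", seq_len(n_cool_dams))

  enumerate <- function(dams, sires, origin, n_realized) {
    maxn <- length(dams) * length(sires)
    if (n_realized > maxn)
      stop_param(sprintf(
        "realized %s crosses (%d) exceed the combinatorial maximum (%d)",
        origin, n_realized, maxn))
    if (n_realized == 0) return(NULL)
    grid <- expand.grid(sire_id = sires, dam_id = dams,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; reorder to dam-major.
    grid <- grid[, c("dam_id", "sire_id")]
    grid <- grid[seq_len(n_realized), , drop = FALSE]
    grid$origin <- origin
    grid
  }

  out <- rbind(enumerate(hot_dams, hot_sires, "PG", realized[["PG"]]),
               enumerate(cool_dams, cool_sires, "IO", realized[["IO"]]),
               enumerate(cool_dams, hot_sires, "PGxIO", realized[["PGxIO"]]))
  if (is.null(out) || nrow(out) == 0L)
    stop_param("the realized design contains no crosses")
  if (anyDuplicated(out[c("dam_id", "sire_id")]))
    stop_param("duplicate dam x sire pairs in design")
  unused <- setdiff(c(hot_dams[seq_len(n_hot_dams)], cool_dams,
                      hot_sires, cool_sires),
                    c(out$dam_id, out$sire_id))
  if (length(unused))
    warning("parents absent from every realized cross: ",
            paste(unused, collapse = ", "))
  data.frame(family_id = paste(out$dam_id, out$sire_id, sep = "x"),
             out, row.names = NULL, stringsAsFactors = FALSE)
}

#' Draw parental genotypes for every parent in a cross design
#'
#' @param design a cross design from [make_cross_design()].
#' @param pops output of [simulate_populations()].
#' @param seed integer seed.
#' @return integer matrix (parents x loci) of derived-allele copy counts;
#'   hot-origin parents ("PG-" prefix) are drawn from the hot population.
#' @export
draw_design_parents <- function(design, pops, seed = 1L) {
  ids <- sort(unique(c(design$dam_id, design$sire_id)))
  hot <- grepl("^PG-", ids)
  g_hot <- draw_parents(pops$freq_hot, max(sum(hot), 1L),
                        seed = derive_seed(seed, 14L), ids = ids[hot])
  g_cool <- draw_parents(pops$freq_cool, max(sum(!hot), 1L),
                         seed = derive_seed(seed, 15L), ids = ids[!hot])
  g <- rbind(if (sum(hot)) g_hot[seq_len(sum(hot)), , drop = FALSE],
             if (sum(!hot)) g_cool[seq_len(sum(!hot)), , drop = FALSE])
  g[ids, , drop = FALSE]
}

default_baseline_survival <- c("27" = 0.95, "33" = 0.75, "36" = 0.55)
default_temp_scale <- c("27" = 0, "33" = 0.5, "36" = 1)

#' Simulate larval heat survival and post-selection pooled allele frequencies
#'
#' Each larva inherits alleles by independent Mendelian segregation from its
#' parents. Survival to 60 h is Bernoulli with
#' `logit p = baseline(T) + scale(T) * sum(effect * beneficial copies) +
#' dam effect + family effect`, where `scale(27) = 0` so genetic effects act
#' only under heat. The baseline is parameterized by the survival
#' probability of a larva carrying the design-average expected number of
#' beneficial copies. Pooled samples are the survivors of each family x
#' temperature; the function returns their derived-allele frequencies at
#' every locus.
#'
#' @param design cross design from [make_cross_design()].
#' @param parent_genotypes matrix from [draw_design_parents()].
#' @param pops output of [simulate_populations()].
#' @param n_larvae_per_family total larvae per family split evenly across
#'   temperatures and plates.
#' @param temperatures integer vector of treatment temperatures (degrees C).
#' @param baseline_survival named survival probability per temperature for a
#'   larva at the anchor genotype.
#' @param temp_scale named multiplier per temperature applied to the causal
#'   genetic term (0 at ambient).
#' @param dam_effect_sd,family_effect_sd standard deviations of normal
#'   random intercepts (logit scale) shared by dam and by family.
#' @param n_plates_per_temp replicate plates per family and temperature.
#' @param seed integer seed.
#' @return a list with `survival` (family x temperature counts), `plates`
#'   (plate-level counts), `pool_freq` (samples x loci matrix of survivor
#'   derived-allele frequencies; `NA` rows when no larva survived),
#'   `samples` (pooled-sample metadata) and `truth` (ground-truth record).
#' @export
simulate_family_survival <- function(design, parent_genotypes, pops,
                                     n_larvae_per_family = 270,
                                     temperatures = c(27, 33, 36),
                                     baseline_survival = default_baseline_survival,
                                     temp_scale = default_temp_scale,
                                     dam_effect_sd = 0.25,
                                     family_effect_sd = 0.25,
                                     n_plates_per_temp = 3,
                                     seed = 1L) {
  stopifnot(n_larvae_per_family >= 1)
  tkey <- as.character(temperatures)
  if (!all(tkey %in% names(baseline_survival)) ||
      !all(tkey %in% names(temp_scale)))
    stop_param("every temperature needs a baseline_survival and temp_scale entry")
  causal <- pops$causal
  loci <- colnames(parent_genotypes)
  cidx <- match(causal$locus_id, loci)
  eff <- causal$effect
  # Anchor: expected beneficial-copy load of an idealized hybrid larva.
  anchor <- if (length(cidx))
    sum(eff * (pops$freq_hot[cidx] + pops$freq_cool[cidx])) else 0
  n_per_plate <- max(1L, round(n_larvae_per_family /
                                 (length(temperatures) * n_plates_per_temp)))

  set.seed(derive_seed(seed, 16L))
  dams <- unique(design$dam_id)
  dam_u <- setNames(rnorm(length(dams), 0, dam_effect_sd), dams)
  fam_u <- setNames(rnorm(nrow(design), 0, family_effect_sd), design$family_id)

  plates <- list(); pool_rows <- list(); samples <- list(); expect <- list()
  for (i in seq_len(nrow(design))) {
    fam <- design$family_id[i]
    gd <- parent_genotypes[design$dam_id[i], ]
    gs <- parent_genotypes[design$sire_id[i], ]
    pd <- gd / 2; ps <- gs / 2   # transmission probabilities per locus
    for (tmp in temperatures) {
      tk <- as.character(tmp)
      n <- n_per_plate * n_plates_per_temp
      # Causal genotypes of every larva in this family x temperature.
      if (length(cidx)) {
        gl <- matrix(rbinom(n * length(cidx), 1L, rep(pd[cidx], each = n)) +
                       rbinom(n * length(cidx), 1L, rep(ps[cidx], each = n)),
                     nrow = n)
        load <- as.vector(gl %*% eff)
      } else {
        gl <- NULL
        load <- numeric(n)
      }
      lp <- qlogis(baseline_survival[[tk]]) +
        temp_scale[[tk]] * (load - anchor) +
        dam_u[[design$dam_id[i]]] + fam_u[[fam]]
      p <- plogis(lp)
      alive <- rbinom(n, 1L, p)
      plate <- rep(seq_len(n_plates_per_temp), each = n_per_plate)
      plates[[length(plates) + 1L]] <- data.frame(
        family_id = fam, dam_id = design$dam_id[i],
        sire_id = design$sire_id[i], origin = design$origin[i],
        temperature = tmp, plate = seq_len(n_plates_per_temp),
        n_start = n_per_plate,
        n_alive_60h = as.integer(tapply(alive, plate, sum)),
        stringsAsFactors = FALSE)
      ns <- sum(alive)
      freq <- rep(NA_real_, length(loci))
      if (ns > 0L) {
        # Non-causal loci are independent of survival: survivor allele
        # counts are direct binomial draws from each parent's transmission
        # probability, avoiding simulation of full larval genotypes.
        freq <- (rbinom(length(loci), ns, pd) + rbinom(length(loci), ns, ps)) /
          (2 * ns)
        if (length(cidx))
          freq[cidx] <- colMeans(gl[alive == 1L, , drop = FALSE]) / 2
      }
      sample_id <- sprintf("%s_%sC", fam, tk)
      pool_rows[[sample_id]] <- freq
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = sample_id, family_id = fam, origin = design$origin[i],
        temperature = tmp, n_survivors = ns, stringsAsFactors = FALSE)
      expect[[length(expect) + 1L]] <- data.frame(
        family_id = fam, temperature = tmp, expected_survival = mean(p),
        stringsAsFactors = FALSE)
    }
  }
  plates <- do.call(rbind, plates)
  survival <- aggregate(cbind(n_start, n_alive_60h) ~
                          family_id + dam_id + sire_id + origin + temperature,
                        data = plates, FUN = sum)
  survival <- survival[order(match(survival$family_id, design$family_id),
                             survival$temperature), ]
  rownames(survival) <- NULL
  pool_freq <- do.call(rbind, pool_rows)
  colnames(pool_freq) <- loci
  samples <- do.call(rbind, samples)
  truth <- list(parent_genotypes = parent_genotypes, causal = causal,
                expected_survival = do.call(rbind, expect),
                dam_effects = dam_u, family_effects = fam_u,
                anchor = anchor, seed = seed)
  list(survival = survival, plates = plates, pool_freq = pool_freq,
       samples = samples, truth = truth)
}

#' Emit per-locus nucleotide read counts
#'
#' Samples sequencing depth per locus (Poisson by default, negative
#' binomial with a dispersion knob otherwise), draws derived-allele reads
#' binomially from the true sample frequency, and flips each read to a
#' uniformly chosen other base with probability `error_rate`.
#'
#' @param freq samples x loci matrix of true derived-allele frequencies
#'   (for parents, copies / 2; rows may be a named vector for one sample).
#'   `NA` frequencies yield zero depth.
#' @param registry locus registry giving reference and alternate base.
#' @param mean_depth mean sequencing depth per locus.
#' @param error_rate per-read probability of a base-call error, in [0, 0.5).
#' @param depth_model `"poisson"` or `"nbinom"`.
#' @param dispersion negative-binomial size parameter (ignored for Poisson).
#' @param seed integer seed.
#' @return long data frame with columns `locus_id`, `sample_id`, `A`, `C`,
#'   `G`, `T`.
#' @export
emit_read_counts <- function(freq, registry, mean_depth = 100,
                             error_rate = 0.005,
                             depth_model = c("poisson", "nbinom"),
                             dispersion = 5, seed = 1L) {
  depth_model <- match.arg(depth_model)
  if (mean_depth <= 0) stop_param("'mean_depth' must be positive")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_param("'error_rate' must lie in [0, 0.5)")
  if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1,
                                         dimnames = list("S1", names(freq)))
  stopifnot(identical(colnames(freq), registry$locus_id))
  set.seed(derive_seed(seed, 17L))
  n_loci <- ncol(freq)
  ref_i <- match(registry$ref, NUCLEOTIDES)
  alt_i <- match(registry$alt, NUCLEOTIDES)
  out <- vector("list", nrow(freq))
  for (s in seq_len(nrow(freq))) {
    f <- freq[s, ]
    depth <- if (depth_model == "poisson") rpois(n_loci, mean_depth)
             else rnbinom(n_loci, size = dispersion, mu = mean_depth)
    depth[is.na(f)] <- 0L
    f0 <- ifelse(is.na(f), 0, f)
    alt_reads <- rbinom(n_loci, depth, f0)
    ref_reads <- depth - alt_reads
    counts <- matrix(0L, n_loci, 4L, dimnames = list(NULL, NUCLEOTIDES))
    if (error_rate > 0) {
      err_ref <- rbinom(n_loci, ref_reads, error_rate)
      err_alt <- rbinom(n_loci, alt_reads, error_rate)
      ref_reads <- ref_reads - err_ref
      alt_reads <- alt_reads - err_alt
      for (i in which(err_ref + err_alt > 0L)) {
        for (from in c("r", "a")) {
          ne <- if (from == "r") err_ref[i] else err_alt[i]
          if (ne == 0L) next
          src <- if (from == "r") ref_i[i] else alt_i[i]
          tgt <- setdiff(1:4, src)
          add <- as.vector(rmultinom(1L, ne, rep(1 / 3, 3)))
          counts[i, tgt] <- counts[i, tgt] + add
        }
      }
    }
    counts[cbind(seq_len(n_loci), ref_i)] <-
      counts[cbind(seq_len(n_loci), ref_i)] + ref_reads
    counts[cbind(seq_len(n_loci), alt_i)] <-
      counts[cbind(seq_len(n_loci), alt_i)] + alt_reads
    out[[s]] <- data.frame(locus_id = registry$locus_id,
                           sample_id = rownames(freq)[s],
                           counts, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate an intragenic-SNP annotation and gene-to-GO map
#'
#' Assigns consecutive loci to genes (a fraction remain intergenic) and
#' draws Gene Ontology style term annotations per gene.
#'
#' @param registry locus registry.
#' @param loci_per_gene loci per annotated gene.
#' @param intergenic_fraction fraction of loci left outside any gene.
#' @param n_terms size of the simulated term vocabulary.
#' @param terms_per_gene maximum number of terms drawn per gene (uniform
#'   between 1 and this value).
#' @param seed integer seed.
#' @return list with an updated `registry` (gene_id filled in) and
#'   `gene2go` (data frame gene_id, term_id).
#' @export
simulate_annotation <- function(registry, loci_per_gene = 3,
                                intergenic_fraction = 0.2,
                                n_terms = 40, terms_per_gene = 3,
                                seed = 1L) {
  set.seed(derive_seed(seed, 18L))
  n <- nrow(registry)
  gene_of <- sprintf("g%04d", ((seq_len(n) - 1L) %/% loci_per_gene) + 1L)
  intergenic <- runif(n) < intergenic_fraction
  gene_of[intergenic] <- NA_character_
  registry$gene_id <- gene_of
  genes <- sort(unique(na.omit(gene_of)))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  # Skewed term usage so some terms are common (background >= 5) and
  # others rare, as in real ontologies.
  wts <- 1 / seq_len(n_terms)
  g2g <- lapply(genes, function(g) {
    k <- sample.int(terms_per_gene, 1L)
    data.frame(gene_id = g,
               term_id = sample(terms, k, prob = wts),
               stringsAsFactors = FALSE)
  })
  list(registry = registry, gene2go = do.call(rbind, g2g))
}

#' Default simulation parameters for the breeding experiment
#'
#' The defaults describe a desk-scale experiment: 2,000 biallelic loci of which
#' 20 affect heat survival, a 4-dam x 17-sire design realized as 50
#' families (18 hot purebred, 12 cool purebred, 20 one-direction hybrids),
#' 270 larvae per family over three temperatures, and pooled sequencing at
#' about 120x with a 0.5% error rate.
#'
#' @return a named list of parameters accepted by [simulate_experiment()].
#' @export
sim_defaults <- function() {
  list(n_loci = 2000, divergence = 0.1, n_causal = 20, causal_effect = 0.5,
       beneficial_freq_hot = 0.42, beneficial_freq_cool = 0.28,
       fixation_fraction = 0.1,
       n_hot_sires = 10, n_cool_sires = 7, n_hot_dams = 2, n_cool_dams = 2,
       realized = c(PG = 18, IO = 12, PGxIO = 20),
       n_larvae_per_family = 270, temperatures = c(27, 33, 36),
       baseline_survival = default_baseline_survival,
       temp_scale = default_temp_scale,
       dam_effect_sd = 0.25, family_effect_sd = 0.25, n_plates_per_temp = 3,
       parent_mean_depth = 60, pool_mean_depth = 120, error_rate = 0.005,
       depth_model = "poisson", dispersion = 5,
       loci_per_gene = 3, intergenic_fraction = 0.2, n_go_terms = 40)
}

#' Run the full synthetic breeding experiment
#'
#' Convenience wrapper chaining [simulate_populations()],
#' [make_cross_design()], [draw_design_parents()],
#' [simulate_family_survival()], [emit_read_counts()] and
#' [simulate_annotation()] under one master seed.
#'
#' @param params parameter list; see [sim_defaults()] for names and
#'   defaults. Supplied entries override the defaults.
#' @param seed master integer seed.
#' @return list with `pops`, `design`, `parent_genotypes`, `survival`,
#'   `plates`, `pool_freq`, `samples`, `parent_counts`, `pool_counts`,
#'   `registry`, `gene2go` and `truth`.
#' @export
simulate_experiment <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(sim_defaults(), params)
  model <- population_model(n_loci = p$n_loci, divergence = p$divergence,
                            causal_loci = p$n_causal,
                            causal_effect = p$causal_effect,
                            beneficial_freq_hot = p$beneficial_freq_hot,
                            beneficial_freq_cool = p$beneficial_freq_cool,
                            fixation_fraction = p$fixation_fraction)
  pops <- simulate_populations(model, seed = seed)
  ann <- simulate_annotation(pops$registry, loci_per_gene = p$loci_per_gene,
                             intergenic_fraction = p$intergenic_fraction,
                             n_terms = p$n_go_terms, seed = seed)
  pops$registry <- ann$registry
  design <- make_cross_design(p$n_hot_sires, p$n_cool_sires,
                              p$n_hot_dams, p$n_cool_dams, p$realized)
  parents <- draw_design_parents(design, pops, seed = seed)
  sim <- simulate_family_survival(design, parents, pops,
                                  n_larvae_per_family = p$n_larvae_per_family,
                                  temperatures = p$temperatures,
                                  baseline_survival = p$baseline_survival,
                                  temp_scale = p$temp_scale,
                                  dam_effect_sd = p$dam_effect_sd,
                                  family_effect_sd = p$family_effect_sd,
                                  n_plates_per_temp = p$n_plates_per_temp,
                                  seed = seed)
  parent_counts <- emit_read_counts(parents / 2, pops$registry,
                                    mean_depth = p$parent_mean_depth,
                                    error_rate = p$error_rate,
                                    depth_model = p$depth_model,
                                    dispersion = p$dispersion,
                                    seed = derive_seed(seed, 21L))
  pool_counts <- emit_read_counts(sim$pool_freq, pops$registry,
                                  mean_depth = p$pool_mean_depth,
                                  error_rate = p$error_rate,
                                  depth_model = p$depth_model,
                                  dispersion = p$dispersion,
                                  seed = derive_seed(seed, 22L))
  list(pops = pops, design = design, parent_genotypes = parents,
       survival = sim$survival, plates = sim$plates,
       pool_freq = sim$pool_freq, samples = sim$samples,
       parent_counts = parent_counts, pool_counts = pool_counts,
       registry = pops$registry, gene2go = ann$gene2go, truth = sim$truth)
}
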