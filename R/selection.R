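# Detection of allele-frequency shifts between heat-exposed and ambient
# pooled samples, per-origin summaries, fixation contrasts, and the PCA of
# hybrid allele-frequency movement.

#' Normalize pooled read counts to a common library size
#'
#' Each sample's per-locus counts are scaled to the median per-sample
#' total depth and rounded half-to-even, so binomial models see integer
#' counts on a comparable scale. P values downstream are approximate under
#' this rounding.
#'
#' @param counts long count table (`locus_id`, `sample_id`, `A`..`T`).
#' @return count table of the same shape with normalized integer counts.
#' @export
normalize_pool_counts <- function(counts) {
  cmat <- as.matrix(counts[NUCLEOTIDES])
  totals <- tapply(rowSums(cmat), counts$sample_id, sum)
  target <- median(totals)
  f <- target / totals[counts$sample_id]
  f[!is.finite(f)] <- 0
  counts[NUCLEOTIDES] <- round(cmat * as.vector(f))
  counts
}

sample_locus_matrix <- function(counts, minor_alleles, what) {
  cmat <- as.matrix(counts[NUCLEOTIDES])
  mi <- match(counts$locus_id, minor_alleles$locus_id)
  v <- switch(what,
              minor = cmat[cbind(seq_len(nrow(cmat)),
                                 match(minor_alleles$minor[mi], NUCLEOTIDES))],
              total = rowSums(cmat))
  samples <- sort(unique(counts$sample_id))
  m <- matrix(0, length(samples), nrow(minor_alleles),
              dimnames = list(samples, minor_alleles$locus_id))
  m[cbind(match(counts$sample_id, samples), mi)] <- v
  m
}

#' Scan loci for allele-frequency response to heat exposure
#'
#' For each locus, minor- and major-allele read counts (normalized to a
#' common library size) of the families' heat-exposed pools are compared
#' with their ambient pools through a binomial logistic regression on
#' temperature; the reported p value is the likelihood-ratio test of the
#' temperature term. Families lacking a sequenced pool at either
#' temperature are excluded; a family contributes to a locus only when it
#' has coverage at both temperatures there. Bonferroni adjustment is over
#' the loci tested within the scan.
#'
#' @param pool_counts long pooled count table.
#' @param samples pooled-sample metadata (`sample_id`, `family_id`,
#'   `origin`, `temperature`).
#' @param minor_alleles data frame from [designate_minor_alleles()].
#' @param origin optional origin category to restrict the scan to
#'   (`NULL` scans all families together).
#' @param ambient,hot the two temperatures contrasted (default 27 and 36).
#' @param alpha significance level for the Bonferroni-adjusted flag.
#' @param min_families minimum families with coverage at both temperatures
#'   for a locus to be tested (default 2).
#' @param normalize logical; scale counts to the median library size first.
#' @return data frame per tested locus: mean MAF at both temperatures,
#'   mean shift (hot minus ambient), `p`, `p_adj`, `significant`,
#'   `n_families`; attribute `n_tested` records the Bonferroni m.
#' @export
scan_selection <- function(pool_counts, samples, minor_alleles,
                           origin = NULL, ambient = 27, hot = 36,
                           alpha = 0.05, min_families = 2L,
                           normalize = TRUE) {
  meta <- samples
  if (!is.null(origin)) meta <- meta[meta$origin == origin, , drop = FALSE]
  meta <- meta[meta$temperature %in% c(ambient, hot), , drop = FALSE]
  both <- names(which(tapply(meta$temperature, meta$family_id,
                             function(t) all(c(ambient, hot) %in% t))))
  meta <- meta[meta$family_id %in% both, , drop = FALSE]
  if (length(both) < min_families)
    stop_param("fewer than ", min_families,
               " families represented at both temperatures")
  counts <- pool_counts[pool_counts$sample_id %in% meta$sample_id, ,
                        drop = FALSE]
  if (normalize) counts <- normalize_pool_counts(counts)
  minor <- sample_locus_matrix(counts, minor_alleles, "minor")
  total <- sample_locus_matrix(counts, minor_alleles, "total")
  # align one ambient and one hot sample per family
  amb_meta <- meta[meta$temperature == ambient, , drop = FALSE]
  hot_meta <- meta[meta$temperature == hot, , drop = FALSE]
  hot_meta <- hot_meta[match(amb_meta$family_id, hot_meta$family_id), ,
                       drop = FALSE]
  sid_a <- amb_meta$sample_id
  sid_h <- hot_meta$sample_id
  ma <- minor[sid_a, , drop = FALSE]; ta <- total[sid_a, , drop = FALSE]
  mh <- minor[sid_h, , drop = FALSE]; th <- total[sid_h, , drop = FALSE]
  valid <- ta > 0 & th > 0
  nfam <- colSums(valid)
  tested <- nfam >= min_families

  a <- colSums(ma * valid); n1 <- colSums(ta * valid)
  c_ <- colSums(mh * valid); n2 <- colSums(th * valid)
  b <- n1 - a; d <- n2 - c_
  # binomial GLM likelihood-ratio (G) statistic of the temperature term
  phat <- (a + c_) / pmax(n1 + n2, 1)
  xlog <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (xlog(a, n1 * phat) + xlog(b, n1 * (1 - phat)) +
              xlog(c_, n2 * phat) + xlog(d, n2 * (1 - phat)))
  p <- pchisq(pmax(g, 0), df = 1, lower.tail = FALSE)

  sh <- (mh / ifelse(th > 0, th, 1)) - (ma / ifelse(ta > 0, ta, 1))
  shift <- colSums(sh * valid) / pmax(nfam, 1)
  maf_a <- colSums((ma / ifelse(ta > 0, ta, 1)) * valid) / pmax(nfam, 1)
  maf_h <- colSums((mh / ifelse(th > 0, th, 1)) * valid) / pmax(nfam, 1)

  out <- data.frame(locus_id = colnames(minor),
                    origin = origin %||% "all",
                    n_families = nfam, maf_ambient = maf_a, maf_hot = maf_h,
                    shift = shift, p = p, stringsAsFactors = FALSE)
  out <- out[tested, , drop = FALSE]
  m <- nrow(out)
  if (!m) stop_param("no testable loci in the selection scan")
  out$p_adj <- pmin(out$p * m, 1)
  out$significant <- out$p_adj < alpha
  attr(out, "n_tested") <- m
  rownames(out) <- NULL
  out
}

#' Run selection scans for all families and per origin
#'
#' @inheritParams scan_selection
#' @return named list of scan results: `all`, then one entry per origin
#'   category present (categories with too few families are skipped with a
#'   message).
#' @export
run_selection_scans <- function(pool_counts, samples, minor_alleles,
                                ambient = 27, hot = 36, alpha = 0.05) {
  origins <- intersect(ORIGIN_LEVELS, unique(samples$origin))
  out <- list(all = scan_selection(pool_counts, samples, minor_alleles,
                                   origin = NULL, ambient = ambient,
                                   hot = hot, alpha = alpha))
  for (o in origins) {
    out[[o]] <- tryCatch(
      scan_selection(pool_counts, samples, minor_alleles, origin = o,
                     ambient = ambient, hot = hot, alpha = alpha),
      error = function(e) {
        message("selection scan skipped for ", o, ": ", conditionMessage(e))
        NULL
      })
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Summarize selection scans per origin
#'
#' Reports, per scan, the proportion of tested loci with a significant
#' temperature effect and the mean absolute frequency shift among
#' significant loci. For heat-selected loci (significant in any scan, or
#' an explicit set), fixation is called when a family group's mean
#' ambient minor-allele frequency falls below `fixation_threshold`; the
#' hot:cool relative fixation likelihood is their ratio.
#'
#' @param scans named list from [run_selection_scans()].
#' @param selected_loci optional character vector of heat-selected locus
#'   ids; defaults to loci significant in any scan.
#' @param fixation_threshold frequency below which an allele counts as
#'   fixed (default 0.01).
#' @return list with `by_origin` (proportion significant, mean absolute
#'   shift), `fixation` (per-purebred-group fixed fractions) and
#'   `fixation_ratio` (PG over IO).
#' @export
summarize_selection <- function(scans, selected_loci = NULL,
                                fixation_threshold = 0.01) {
  by <- do.call(rbind, lapply(names(scans), function(nm) {
    s <- scans[[nm]]
    sig <- s[s$significant, , drop = FALSE]
    data.frame(scan = nm, n_tested = nrow(s), n_significant = nrow(sig),
               prop_significant = nrow(sig) / nrow(s),
               mean_abs_shift_significant =
                 if (nrow(sig)) mean(abs(sig$shift)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(selected_loci))
    selected_loci <- unique(unlist(lapply(scans, function(s)
      s$locus_id[s$significant])))
  fixation <- NULL; ratio <- NA_real_
  groups <- intersect(c("PG", "IO"), names(scans))
  if (length(selected_loci) && length(groups) == 2L) {
    frac <- vapply(groups, function(o) {
      s <- scans[[o]]
      i <- match(selected_loci, s$locus_id)
      mean(s$maf_ambient[i[!is.na(i)]] < fixation_threshold)
    }, numeric(1))
    fixation <- data.frame(origin = groups, fixed_fraction = frac,
                           row.names = NULL)
    if (frac[["IO"]] > 0) ratio <- frac[["PG"]] / frac[["IO"]]
  }
  list(by_origin = by, fixation = fixation, fixation_ratio = ratio,
       n_selected = length(selected_loci))
}

#' Principal components of pooled MAFs at heat-selected loci
#'
#' Filters loci to those with a strong selection response in the hybrid
#' scan (Bonferroni-adjusted p below `pca_alpha`) and less than
#' `max_missing` missing data across all samples, imputes remaining
#' missing values by origin-group means (hybrids by the hybrid group
#' itself), centers columns and projects all samples on the top two
#' principal components. PC signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param maf samples x loci pooled MAF matrix (all origins, both
#'   temperatures).
#' @param samples pooled-sample metadata matching `maf` rows.
#' @param hybrid_scan selection-scan result for the hybrid subset.
#' @param pca_alpha adjusted-p threshold for locus inclusion (default 0.001).
#' @param max_missing maximum missing fraction per locus (default 0.1).
#' @return list with `coords` (sample metadata plus PC1/PC2),
#'   `loadings`, `var_explained` and the retained `loci`.
#' @export
hybrid_shift_pca <- function(maf, samples, hybrid_scan,
                             pca_alpha = 0.001, max_missing = 0.1) {
  sel <- hybrid_scan$locus_id[hybrid_scan$p_adj < pca_alpha]
  sel <- intersect(sel, colnames(maf))
  missfrac <- colMeans(is.na(maf[, sel, drop = FALSE]))
  keep <- sel[missfrac < max_missing]
  if (length(keep) < 2L)
    stop_param(sprintf(
      "fewer than 2 loci pass the PCA filters (%d pass adjusted p < %g, %d also pass missingness < %g)",
      length(sel), pca_alpha, length(keep), max_missing))
  x <- maf[samples$sample_id, keep, drop = FALSE]
  grp <- samples$origin
  for (o in unique(grp)) {
    rows <- grp == o
    mu <- colMeans(x[rows, , drop = FALSE], na.rm = TRUE)
    for (j in seq_along(keep)) {
      nas <- rows & is.na(x[, j])
      if (any(nas)) x[nas, j] <- mu[j]
    }
  }
  # any column still missing (group entirely missing) -> overall mean
  for (j in which(colSums(is.na(x)) > 0))
    x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  coords <- cbind(samples[match(rownames(scores), samples$sample_id),
                          c("sample_id", "family_id", "origin", "temperature")],
                  as.data.frame(scores))
  rownames(coords) <- NULL
  list(coords = coords, loadings = loadings,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       loci = keep)
}
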