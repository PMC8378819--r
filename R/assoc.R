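# Per-SNP association between baseline (ambient) pooled allele frequencies
# and family heat survival, beneficial-allele scoring of parents, and
# clustering of paternal genotypes at strongly associated SNPs.

binom_lrt <- function(X_full, X_null, prop, n) {
  fam <- binomial()
  full <- glm.fit(X_full, prop, weights = n, family = fam)
  null <- glm.fit(X_null, prop, weights = n, family = fam)
  stat <- max(null$deviance - full$deviance, 0)
  list(p = pchisq(stat, df = ncol(X_full) - ncol(X_null), lower.tail = FALSE),
       slope = coef(full)[2L])
}

#' Scan SNPs for association between baseline MAF and heat survival
#'
#' For each locus, family survival counts at the hot temperature are
#' regressed on the family's ambient minor-allele frequency with a
#' binomial logistic model adjusting for parental origin (fixed
#' covariate); the MAF slope is tested by likelihood ratio. The Pearson
#' correlation R between ambient MAF and the raw survival proportion
#' classifies loci: `strong` when `|R| >= strong_r`, `moderate_weak` when
#' weaker but nominally associated (raw p below `alpha`), `none`
#' otherwise. Bonferroni adjustment uses the number of loci actually
#' tested (non-missing MAF in at least `min_families` families).
#'
#' @param maf matrix of ambient pooled minor-allele frequencies with one
#'   row per family (rownames are family ids).
#' @param survival data frame with `family_id`, `origin`, `n_start`,
#'   `n_alive_60h` at the hot temperature.
#' @param minor_alleles optional data frame from
#'   [designate_minor_alleles()]; when given, the beneficial allele is
#'   reported as a base, otherwise as `"minor"`/`"major"`.
#' @param strong_r absolute-correlation threshold for the strong class.
#' @param alpha significance level.
#' @param min_families minimum families with non-missing MAF (default 3).
#' @return data frame with one row per tested locus: `locus_id`, `n_families`,
#'   `R`, `slope`, `p`, `p_adj`, `beneficial_allele`, `class`,
#'   `significant` (Bonferroni-adjusted p below `alpha`).
#' @export
scan_survival_association <- function(maf, survival, minor_alleles = NULL,
                                      strong_r = 0.5, alpha = 0.05,
                                      min_families = 3L) {
  fams <- intersect(rownames(maf), survival$family_id)
  if (length(fams) < min_families)
    stop_param("fewer than ", min_families, " families with both MAF and survival")
  maf <- maf[fams, , drop = FALSE]
  sv <- survival[match(fams, survival$family_id), ]
  alive <- sv$n_alive_60h
  n <- sv$n_start
  prop <- alive / n
  origin <- factor(sv$origin)
  odum <- if (nlevels(origin) > 1L)
    stats::model.matrix(~origin)[, -1L, drop = FALSE] else NULL

  res <- lapply(seq_len(ncol(maf)), function(j) {
    x <- maf[, j]
    ok <- !is.na(x)
    if (sum(ok) < min_families) return(NULL)
    if (var(x[ok]) == 0)
      return(data.frame(locus_id = colnames(maf)[j], n_families = sum(ok),
                        R = NA_real_, slope = NA_real_, p = 1,
                        stringsAsFactors = FALSE))
    r <- cor(x[ok], prop[ok])
    Xn <- cbind(intercept = rep(1, sum(ok)),
                if (!is.null(odum)) odum[ok, , drop = FALSE])
    Xf <- cbind(Xn[, 1L, drop = FALSE], x = x[ok],
                if (!is.null(odum)) odum[ok, , drop = FALSE])
    fit <- binom_lrt(Xf, Xn, prop[ok], n[ok])
    data.frame(locus_id = colnames(maf)[j], n_families = sum(ok),
               R = r, slope = unname(fit$slope), p = fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) stop_param("no testable loci")
  m <- nrow(out)
  out$p_adj <- pmin(out$p * m, 1)
  out$beneficial_allele <- ifelse(is.na(out$R), NA_character_,
                                  ifelse(out$R > 0, "minor", "major"))
  if (!is.null(minor_alleles)) {
    i <- match(out$locus_id, minor_alleles$locus_id)
    out$beneficial_allele <- ifelse(
      is.na(out$beneficial_allele), NA_character_,
      ifelse(out$beneficial_allele == "minor",
             minor_alleles$minor[i], minor_alleles$major[i]))
    out$minor_allele <- minor_alleles$minor[i]
  }
  out$class <- ifelse(!is.na(out$R) & abs(out$R) >= strong_r, "strong",
                      ifelse(out$p < alpha, "moderate_weak", "none"))
  out$significant <- out$p_adj < alpha
  attr(out, "n_tested") <- m
  rownames(out) <- NULL
  out
}

#' Summarize an association scan
#'
#' @param assoc data frame from [scan_survival_association()].
#' @return one-row data frame with the number of loci tested, counts and
#'   percentages per strength class, and the Bonferroni-significant count.
#' @export
summarize_association <- function(assoc) {
  m <- nrow(assoc)
  n_strong <- sum(assoc$class == "strong")
  n_mod <- sum(assoc$class == "moderate_weak")
  data.frame(n_tested = m, n_strong = n_strong,
             pct_strong = 100 * n_strong / m,
             n_moderate_weak = n_mod, pct_moderate_weak = 100 * n_mod / m,
             n_significant = sum(assoc$significant))
}

#' Score parents for their proportion of beneficial alleles
#'
#' At each supplied locus a parent carrying two, one or zero copies of the
#' beneficial allele scores 1, 0.5 or 0; scores are averaged over loci
#' with a non-missing genotype. Parent genotypes are distance-from-
#' reference scores, so beneficial-allele copies are derived through the
#' locus registry (alternate allele copies = 2 x score).
#'
#' @param parent_matrix parents x loci genotype score matrix.
#' @param beneficial data frame with `locus_id` and `beneficial_allele`
#'   (a base), e.g. the significant subset of an association scan.
#' @param registry locus registry with reference and alternate base.
#' @return data frame with `parent_id`, `n_loci_scored`, `proportion`.
#' @export
score_parents <- function(parent_matrix, beneficial, registry) {
  if (!nrow(beneficial)) stop_param("no loci supplied for scoring")
  loci <- intersect(beneficial$locus_id, colnames(parent_matrix))
  if (!length(loci)) stop_param("no scored loci present in the parent matrix")
  ri <- match(loci, registry$locus_id)
  bi <- match(loci, beneficial$locus_id)
  ben <- beneficial$beneficial_allele[bi]
  sub <- parent_matrix[, loci, drop = FALSE]
  # per-locus score of the beneficial allele, from distance-from-ref scores
  locus_score <- function(scores, k) {
    if (ben[k] == registry$alt[ri[k]]) scores
    else if (ben[k] == registry$ref[ri[k]]) 1 - scores
    else NA_real_
  }
  for (k in seq_along(loci)) sub[, k] <- locus_score(sub[, k], k)
  data.frame(parent_id = rownames(sub),
             n_loci_scored = rowSums(!is.na(sub)),
             proportion = rowMeans(sub, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate parental beneficial-allele scores with offspring performance
#'
#' Pearson correlation between each sire's mean beneficial-allele
#' proportion and its mean offspring survival index, with support for an
#' exclusion list (e.g. sires represented by a single cross).
#'
#' @param scores data frame from [score_parents()].
#' @param sire_index data frame with `sire_id` and `index` (per-sire mean
#'   survival index).
#' @param exclude character vector of sire ids to drop.
#' @return list with `r`, `p`, `n` and the merged `data`.
#' @export
correlate_parent_performance <- function(scores, sire_index, exclude = NULL) {
  d <- merge(scores, sire_index, by.x = "parent_id", by.y = "sire_id")
  d <- d[!(d$parent_id %in% exclude) & !is.na(d$proportion) &
           !is.na(d$index), , drop = FALSE]
  if (nrow(d) < 3L) stop_param("fewer than 3 sires after exclusions")
  ct <- cor.test(d$proportion, d$index, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d), data = d)
}

#' Cluster paternal genotypes at strongly associated SNPs
#'
#' Pairwise Pearson correlations of parental genotype scores over shared
#' non-missing loci, followed by average-linkage hierarchical clustering
#' on `1 - correlation`. Parents are ordered by id before clustering so
#' leaf order is deterministic under ties.
#'
#' @param parent_matrix parents x loci genotype score matrix.
#' @param loci locus ids to use (e.g. the strong class of a scan).
#' @param min_shared pairs sharing fewer non-missing loci than this are
#'   flagged low-confidence.
#' @return list with `correlation` (matrix), `shared` (pairwise
#'   non-missing locus counts), `low_confidence` (logical matrix),
#'   `hclust` and `order` (leaf order as parent ids).
#' @export
cluster_paternal_genotypes <- function(parent_matrix, loci,
                                       min_shared = 10L) {
  loci <- intersect(loci, colnames(parent_matrix))
  if (nrow(parent_matrix) < 2L || length(loci) < 2L)
    stop_param("need at least 2 parents and 2 loci")
  m <- parent_matrix[sort(rownames(parent_matrix)), loci, drop = FALSE]
  cc <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  shared <- tcrossprod(!is.na(m))
  low <- shared < min_shared
  diag(low) <- FALSE
  if (any(low))
    warning("parent pairs sharing fewer than ", min_shared,
            " loci flagged low-confidence")
  d <- 1 - cc
  d[is.na(d)] <- 2  # uncorrelatable pairs at maximal distance
  hc <- hclust(as.dist(d), method = "average")
  list(correlation = cc, shared = shared, low_confidence = low,
       hclust = hc, order = rownames(m)[hc$order])
}

#' Export a clustering as a newick string
#'
#' @param hc an `hclust` object.
#' @return single newick-format character string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
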