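# Threshold-based genotype and pooled allele-frequency calling from
# per-locus nucleotide read counts, plus dataset-level filters.

#' Call one parental genotype from nucleotide counts
#'
#' Alleles carrying strictly less than `error_maf` of the reads are treated
#' as sequencing error and discarded. If the remaining coverage is strictly
#' below `min_cov` the genotype is not called. Otherwise the score is the
#' "distance from the reference base": 0 for homozygous reference, 0.5 for
#' heterozygous, 1 for homozygous alternate. Sites with more than two
#' surviving alleles are set to missing and flagged.
#'
#' @param counts named numeric vector of reads per nucleotide (A, C, G, T).
#' @param ref reference base at the locus.
#' @param error_maf strict minor-allele read-fraction threshold below which
#'   an allele is discarded (default 0.05).
#' @param min_cov strict minimum post-filter coverage to call (default 5).
#' @return a list with `score` (0, 0.5, 1 or `NA`), `alleles` (bases
#'   retained after the error filter) and `multiallelic` (logical flag).
#' @export
call_parent_genotype <- function(counts, ref, error_maf = 0.05, min_cov = 5) {
  counts <- counts[NUCLEOTIDES]
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop_param("negative read counts")
  total <- sum(counts)
  if (total == 0)
    return(list(score = NA_real_, alleles = character(0),
                multiallelic = FALSE))
  keep <- counts / total >= error_maf & counts > 0
  remaining <- sum(counts[keep])
  alleles <- NUCLEOTIDES[keep]
  if (remaining < min_cov)
    return(list(score = NA_real_, alleles = alleles, multiallelic = FALSE))
  if (length(alleles) > 2L)
    return(list(score = NA_real_, alleles = alleles, multiallelic = TRUE))
  score <- if (length(alleles) == 2L) 0.5
           else if (identical(alleles, ref)) 0 else 1
  list(score = score, alleles = alleles, multiallelic = FALSE)
}

#' Call a parent x locus genotype matrix from a count table
#'
#' Vectorized application of the [call_parent_genotype()] rules to a long
#' count table.
#'
#' @param counts long data frame with columns `locus_id`, `sample_id`, `A`,
#'   `C`, `G`, `T`.
#' @param registry locus registry providing the reference base.
#' @param error_maf,min_cov thresholds as in [call_parent_genotype()].
#' @return numeric matrix (samples x loci) of scores in \{0, 0.5, 1\} with
#'   `NA` for uncalled sites; multiallelic sites carry attribute
#'   `n_multiallelic`.
#' @export
call_parent_genotypes <- function(counts, registry,
                                  error_maf = 0.05, min_cov = 5) {
  stopifnot(all(c("locus_id", "sample_id", NUCLEOTIDES) %in% names(counts)))
  cmat <- as.matrix(counts[NUCLEOTIDES])
  total <- rowSums(cmat)
  frac <- cmat / ifelse(total == 0, 1, total)
  keep <- frac >= error_maf & cmat > 0
  remaining <- rowSums(cmat * keep)
  n_alleles <- rowSums(keep)
  ref <- registry$ref[match(counts$locus_id, registry$locus_id)]
  if (anyNA(ref)) stop_param("count table contains loci absent from the registry")
  ref_kept <- keep[cbind(seq_len(nrow(cmat)), match(ref, NUCLEOTIDES))]
  score <- rep(NA_real_, nrow(cmat))
  callable <- remaining >= min_cov & n_alleles <= 2L & n_alleles >= 1L
  score[callable & n_alleles == 2L] <- 0.5
  score[callable & n_alleles == 1L & ref_kept] <- 0
  score[callable & n_alleles == 1L & !ref_kept] <- 1
  multi <- remaining >= min_cov & n_alleles > 2L
  if (any(multi))
    warning(sum(multi), " multiallelic site(s) set to missing")
  samples <- sort(unique(counts$sample_id))
  mat <- matrix(NA_real_, length(samples), nrow(registry),
                dimnames = list(samples, registry$locus_id))
  mat[cbind(match(counts$sample_id, samples),
            match(counts$locus_id, registry$locus_id))] <- score
  attr(mat, "n_multiallelic") <- sum(multi)
  mat
}

#' Designate the global minor allele per locus
#'
#' The minor allele is defined once per locus as the less frequent of the
#' two most abundant alleles across all ambient-temperature pooled samples
#' combined, with ties broken by nucleotide lexicographic order. A single
#' consistent axis is required to compare frequencies across samples and
#' temperatures.
#'
#' @param pool_counts long count table of the ambient pooled samples.
#' @param registry locus registry.
#' @return data frame with columns `locus_id`, `major`, `minor`.
#' @export
designate_minor_alleles <- function(pool_counts, registry) {
  stopifnot(all(c("locus_id", NUCLEOTIDES) %in% names(pool_counts)))
  agg <- rowsum(as.matrix(pool_counts[NUCLEOTIDES]), pool_counts$locus_id)
  agg <- agg[match(registry$locus_id, rownames(agg)), , drop = FALSE]
  agg[is.na(agg)] <- 0
  # Lexicographic tie-break: order() is stable, so among equal counts the
  # alphabetically earlier base ranks first and becomes the major allele.
  pick <- t(apply(agg, 1L, function(x) order(-x, NUCLEOTIDES)[1:2]))
  major <- NUCLEOTIDES[pick[, 1L]]
  minor <- NUCLEOTIDES[pick[, 2L]]
  none <- rowSums(agg) == 0
  major[none] <- registry$ref[none]
  minor[none] <- registry$alt[none]
  data.frame(locus_id = registry$locus_id, major = major, minor = minor,
             stringsAsFactors = FALSE)
}

#' Call pooled minor-allele frequencies
#'
#' Frequency of the designated minor allele among all reads at a locus,
#' called only when total coverage reaches `min_cov` (strictly below is
#' missing). Scale-free: multiplying all counts by a constant leaves a
#' non-missing frequency unchanged.
#'
#' @param counts long count table of pooled samples.
#' @param minor_alleles data frame from [designate_minor_alleles()].
#' @param min_cov minimum total coverage (default 50).
#' @return numeric matrix (samples x loci) of frequencies in [0, 1] of the
#'   per-locus global minor allele, `NA` below coverage.
#' @export
call_pooled_maf <- function(counts, minor_alleles, min_cov = 50) {
  stopifnot(all(c("locus_id", "sample_id", NUCLEOTIDES) %in% names(counts)))
  cmat <- as.matrix(counts[NUCLEOTIDES])
  total <- rowSums(cmat)
  mi <- match(counts$locus_id, minor_alleles$locus_id)
  if (anyNA(mi)) stop_param("count table contains loci without a designated minor allele")
  minor_reads <- cmat[cbind(seq_len(nrow(cmat)),
                            match(minor_alleles$minor[mi], NUCLEOTIDES))]
  maf <- ifelse(total >= min_cov, minor_reads / total, NA_real_)
  samples <- sort(unique(counts$sample_id))
  mat <- matrix(NA_real_, length(samples), nrow(minor_alleles),
                dimnames = list(samples, minor_alleles$locus_id))
  mat[cbind(match(counts$sample_id, samples), mi)] <- maf
  mat
}

filter_one_matrix <- function(mat, max_missing_per_sample,
                              max_missing_per_locus, label) {
  report <- list()
  miss_s <- rowMeans(is.na(mat))
  drop_s <- miss_s > max_missing_per_sample
  report[[paste0(label, "_samples_removed")]] <- sum(drop_s)
  mat <- mat[!drop_s, , drop = FALSE]
  miss_l <- colMeans(is.na(mat))
  drop_l <- miss_l > max_missing_per_locus
  report[[paste0(label, "_loci_removed_missing")]] <- sum(drop_l)
  mat <- mat[, !drop_l, drop = FALSE]
  mono <- apply(mat, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1L])
  })
  report[[paste0(label, "_loci_removed_monomorphic")]] <- sum(mono)
  mat <- mat[, !mono, drop = FALSE]
  list(mat = mat, report = report)
}

#' Filter genotype and pooled-frequency matrices
#'
#' Removal order within each matrix: samples with too much missing data,
#' then loci with too much missing data, then loci monomorphic across all
#' retained samples. The two matrices keep independent locus sets; no
#' intersection is forced.
#'
#' @param parent_matrix parent genotype score matrix.
#' @param pooled_matrix pooled minor-allele frequency matrix.
#' @param max_missing_per_sample,max_missing_per_locus missingness
#'   fractions in [0, 1] above which a sample or locus is dropped.
#' @return list with filtered `parent`, `pooled` and a `report` of counts
#'   removed at each step, in order.
#' @export
filter_genotype_data <- function(parent_matrix, pooled_matrix,
                                 max_missing_per_sample = 0.5,
                                 max_missing_per_locus = 0.3) {
  check_prob(max_missing_per_sample, "max_missing_per_sample")
  check_prob(max_missing_per_locus, "max_missing_per_locus")
  fp <- filter_one_matrix(parent_matrix, max_missing_per_sample,
                          max_missing_per_locus, "parent")
  fq <- filter_one_matrix(pooled_matrix, max_missing_per_sample,
                          max_missing_per_locus, "pooled")
  if (ncol(fp$mat) == 0L && ncol(fq$mat) == 0L)
    stop_param("no loci survive filtering")
  list(parent = fp$mat, pooled = fq$mat, report = c(fp$report, fq$report))
}
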