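# Gene-level functional enrichment of loci implicated by the association
# and selection scans: one-sided Fisher (hypergeometric tail) tests of GO
# term over-representation against a background of genes containing tested
# intragenic SNPs.

#' Map significant and tested loci to gene sets
#'
#' The study set contains every gene with at least one significant
#' intragenic locus; the background contains every gene with at least one
#' tested intragenic locus. Intergenic loci are dropped and counted.
#'
#' @param significant_loci character vector of significant locus ids.
#' @param tested_loci character vector of all tested locus ids.
#' @param registry locus registry with a `gene_id` column (`NA` for
#'   intergenic loci).
#' @return list with `study`, `background` (character vectors of gene
#'   ids) and `n_intergenic_dropped`.
#' @export
genes_from_loci <- function(significant_loci, tested_loci, registry) {
  stopifnot("gene_id" %in% names(registry))
  gene_of <- setNames(registry$gene_id, registry$locus_id)
  sig_genes <- gene_of[intersect(significant_loci, names(gene_of))]
  bg_genes <- gene_of[intersect(tested_loci, names(gene_of))]
  dropped <- sum(is.na(sig_genes)) + sum(is.na(bg_genes))
  study <- sort(unique(na.omit(sig_genes)))
  background <- sort(unique(na.omit(bg_genes)))
  if (!length(study)) stop_param("empty study gene set")
  list(study = unname(study), background = unname(background),
       n_intergenic_dropped = dropped)
}

propagate_terms <- function(gene2go, ancestors) {
  # ancestors: named list, term -> character vector of ancestor terms
  ext <- lapply(seq_len(nrow(gene2go)), function(i) {
    t <- gene2go$term_id[i]
    anc <- ancestors[[t]]
    data.frame(gene_id = gene2go$gene_id[i],
               term_id = unique(c(t, anc)), stringsAsFactors = FALSE)
  })
  unique(do.call(rbind, ext))
}

#' One-sided Fisher enrichment of GO terms in a study gene set
#'
#' For every term annotated in the background, the upper hypergeometric
#' tail P(X >= observed study count) is computed. A term is flagged
#' significant when p is below `alpha` and the term occurs at least
#' `min_background` times in the background set; no multiple-testing
#' correction is applied across terms. If an ancestor map is supplied,
#' annotations are propagated up the ontology (true-path rule) before
#' counting.
#'
#' @param study,background character vectors of gene ids with
#'   `study` a subset of `background`.
#' @param gene2go data frame with columns `gene_id`, `term_id`.
#' @param min_background minimum background occurrences (default 5).
#' @param alpha significance level (default 0.05).
#' @param ancestors optional named list mapping a term to its ancestor
#'   terms for true-path propagation.
#' @return data frame per term: `term_id`, `study_count`,
#'   `background_count`, `study_size`, `background_size`, `p`,
#'   `significant`, sorted by p.
#' @export
fisher_enrichment <- function(study, background, gene2go,
                              min_background = 5L, alpha = 0.05,
                              ancestors = NULL) {
  if (!all(study %in% background))
    stop_param("study set must be a subset of the background set")
  bad <- !grepl("^GO:\\d{7}$", gene2go$term_id)
  if (any(bad))
    stop_param("malformed term ids: ",
               paste(head(unique(gene2go$term_id[bad])), collapse = ", "))
  if (!is.null(ancestors)) gene2go <- propagate_terms(gene2go, ancestors)
  g2g <- unique(gene2go[gene2go$gene_id %in% background, , drop = FALSE])
  if (!nrow(g2g)) stop_param("no annotated background genes")
  N <- length(unique(background))
  n <- length(unique(study))
  bg_count <- table(g2g$term_id)
  st_count <- table(g2g$term_id[g2g$gene_id %in% study])
  terms <- names(bg_count)
  k <- as.integer(st_count[terms]); k[is.na(k)] <- 0L
  K <- as.integer(bg_count[terms])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, study_count = k, background_count = K,
                    study_size = n, background_size = N, p = p,
                    significant = p < alpha & K >= min_background,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}
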