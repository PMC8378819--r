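# Interchange formats: schema-validated TSV/CSV readers and byte-stable
# writers, a minimal GT-only VCF export, and the run configuration.

read_table_checked <- function(path, required, numeric_cols = character(0),
                               sep = "\t") {
  if (!file.exists(path)) stop_param("file not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_param("file ", basename(path), " lacks required column(s): ",
               paste(missing, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad))
      stop_param("malformed numeric in ", basename(path), " column '", cc,
                 "' at row ", bad[1L])
    df[[cc]] <- v
  }
  df
}

#' Write a table with byte-stable output
#'
#' Rows are sorted by all columns (left to right) and numeric columns are
#' formatted at 6 significant digits, so two writes of the same table are
#' byte-identical.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param sep field separator (tab by default, comma for `.csv`).
#' @param sort logical; sort rows before writing.
#' @return the path, invisibly.
#' @export
write_table_stable <- function(df, path,
                               sep = if (grepl("\\.csv$", path)) "," else "\t",
                               sort = TRUE) {
  if (sort && nrow(df) > 1L)
    df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
  fmt <- df
  for (cc in names(fmt))
    if (is.double(fmt[[cc]]))
      fmt[[cc]] <- ifelse(is.na(fmt[[cc]]), "NA",
                          formatC(signif(fmt[[cc]], 6), digits = 6,
                                  format = "g"))
  write.table(fmt, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname read_tables
#' @export
read_survival_table <- function(path) {
  df <- read_table_checked(path,
                           c("family_id", "dam_id", "sire_id", "origin",
                             "temperature", "n_start", "n_alive_60h"),
                           c("temperature", "n_start", "n_alive_60h"),
                           sep = ",")
  if (any(df$n_alive_60h > df$n_start))
    stop_param("n_alive_60h exceeds n_start in ", basename(path))
  df
}

#' Read and write pipeline interchange tables
#'
#' Schema-validated readers for the pipeline's file formats: survival CSV,
#' per-locus nucleotide count TSV, locus registry TSV, pooled-sample
#' metadata TSV, numeric sample x locus matrix TSV, and the two-column
#' gene-to-GO map (comma-separated term lists).
#'
#' @param path file path.
#' @name read_tables
#' @export
read_counts_table <- function(path) {
  read_table_checked(path, c("locus_id", "sample_id", NUCLEOTIDES),
                     NUCLEOTIDES)
}

#' @rdname read_tables
#' @export
read_registry <- function(path) {
  read_table_checked(path, c("locus_id", "contig", "position", "ref", "alt"),
                     "position")
}

#' @rdname read_tables
#' @export
read_samples_table <- function(path) {
  read_table_checked(path, c("sample_id", "family_id", "origin",
                             "temperature"), "temperature")
}

#' @rdname read_tables
#' @export
read_matrix_tsv <- function(path) {
  df <- read_table_checked(path, "sample_id")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}

#' Write a sample x locus matrix as TSV
#'
#' @param m numeric matrix with sample rownames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_stable(df, path)
}

#' @rdname read_tables
#' @export
read_gene_map <- function(path) {
  df <- read_table_checked(path, c("gene_id", "term_ids"))
  terms <- strsplit(df$term_ids, ",", fixed = TRUE)
  data.frame(gene_id = rep(df$gene_id, lengths(terms)),
             term_id = trimws(unlist(terms)), stringsAsFactors = FALSE)
}

#' Write a gene-to-GO map as a two-column TSV
#'
#' @param gene2go long data frame (`gene_id`, `term_id`).
#' @param path output path.
#' @export
write_gene_map <- function(gene2go, path) {
  sp <- split(gene2go$term_id, gene2go$gene_id)
  df <- data.frame(gene_id = names(sp),
                   term_ids = vapply(sp, function(x)
                     paste(sort(unique(x)), collapse = ","), ""),
                   stringsAsFactors = FALSE)
  write_table_stable(df, path)
}

#' Export parental genotypes as a minimal VCF
#'
#' Writes VCFv4.2 with a GT field only. Internal 0-based positions become
#' 1-based VCF coordinates. Scores map to genotypes as 0 = `0/0`,
#' 0.5 = `0/1`, 1 = `1/1`, missing = `./.`.
#'
#' @param parent_matrix parents x loci genotype score matrix.
#' @param registry locus registry.
#' @param path output path.
#' @export
write_vcf_gt <- function(parent_matrix, registry, path) {
  loci <- colnames(parent_matrix)
  reg <- registry[match(loci, registry$locus_id), ]
  gt <- ifelse(is.na(parent_matrix), "./.",
               ifelse(parent_matrix == 0, "0/0",
                      ifelse(parent_matrix == 0.5, "0/1", "1/1")))
  gt <- t(matrix(gt, nrow = nrow(parent_matrix)))  # loci x parents
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(parent_matrix)),
                   collapse = "\t"))
  body <- paste(reg$contig, reg$position + 1L, reg$locus_id, reg$ref,
                reg$alt, ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Default run configuration
#'
#' All thresholds carry the pipeline's reference defaults: 5% error MAF,
#' 5x parental and 50x pooled coverage, |R| >= 0.5 for the strong
#' association class, frequency < 0.01 for fixation, adjusted p < 0.001
#' and < 10% missing data for the PCA, and GO significance at p < 0.05
#' with at least 5 background occurrences.
#'
#' @return nested named list of stage parameters.
#' @export
default_run_config <- function() {
  list(sim = sim_defaults(),
       genotype = list(error_maf = 0.05, min_parent_cov = 5,
                       min_pool_cov = 50,
                       max_missing_per_sample = 0.5,
                       max_missing_per_locus = 0.3),
       phenostats = list(ambient_temperature = 27, hot_temperature = 36,
                         transform_power = 3),
       heritability = list(n_iter = 1e5, burn_in = 1e4, thin = 10,
                           nu = 0.002, V = 1),
       assoc = list(strong_r = 0.5, alpha = 0.05, min_families = 3,
                    min_shared = 10),
       select = list(alpha = 0.05, pca_alpha = 0.001, pca_missing = 0.1,
                     fixation_threshold = 0.01),
       enrich = list(alpha = 0.05, min_background = 5),
       seed = 1L)
}

#' Read a run configuration from a YAML file
#'
#' Entries in the file override the defaults of [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}
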