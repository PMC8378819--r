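# Survival-rate statistics for the breeding experiment: standardization to
# ambient, origin and parental effect models with partial eta-squared,
# per-family decline tests, the paternal survival index, and field
# survival summaries.

#' Standardize survival to ambient values per family
#'
#' Survival rates at elevated temperature are divided by the family's
#' ambient (27 degree) survival to remove mortality unrelated to heat,
#' and capped at 1. Works on family-level or plate-level tables; the
#' ambient reference is always the family-level pooled ambient rate.
#'
#' @param table survival table with columns `family_id`, `dam_id`,
#'   `sire_id`, `origin`, `temperature`, `n_start`, `n_alive_60h` and
#'   optionally `plate`.
#' @param ambient_temperature the reference temperature (default 27).
#' @return data frame of elevated-temperature rows with columns
#'   `rel_survival` (standardized, capped at 1) and `survival` (raw rate).
#'   Families with zero ambient survival get `NA` with a warning.
#' @export
relative_survival <- function(table, ambient_temperature = 27) {
  req <- c("family_id", "origin", "temperature", "n_start", "n_alive_60h")
  stopifnot(all(req %in% names(table)))
  if (any(table$n_alive_60h > table$n_start) || any(table$n_alive_60h < 0))
    stop_param("survivor counts must lie in [0, n_start]")
  amb <- table[table$temperature == ambient_temperature, ]
  if (!all(unique(table$family_id) %in% amb$family_id))
    stop_param("every family needs an ambient row")
  amb_rate <- tapply(amb$n_alive_60h, amb$family_id, sum) /
    tapply(amb$n_start, amb$family_id, sum)
  out <- table[table$temperature != ambient_temperature, , drop = FALSE]
  out$survival <- out$n_alive_60h / out$n_start
  ref <- amb_rate[out$family_id]
  out$rel_survival <- ifelse(ref > 0, pmin(out$survival / ref, 1), NA_real_)
  if (any(ref == 0))
    warning("families with zero ambient survival set to missing: ",
            paste(unique(out$family_id[ref == 0]), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Origin and temperature effects on standardized survival
#'
#' Fits the linear model `rel_survival^k ~ temperature * origin` (cube
#' transform by default, to improve normality and variance homogeneity)
#' and reports the ANOVA table plus Tukey honest-significant-difference
#' pairwise origin comparisons within each temperature. Comparisons are
#' computed on the transformed scale; group means are reported on both
#' scales.
#'
#' @param rel data frame from [relative_survival()].
#' @param transform_power exponent applied to the response (default 3).
#' @return list with `anova`, `tukey` (one table per temperature) and
#'   `means` (group means on both scales).
#' @export
origin_effect_model <- function(rel, transform_power = 3) {
  rel <- rel[!is.na(rel$rel_survival), , drop = FALSE]
  rel$y <- rel$rel_survival^transform_power
  rel$temperature <- factor(rel$temperature)
  rel$origin <- factor(rel$origin, levels = intersect(ORIGIN_LEVELS, rel$origin))
  single_origin <- nlevels(rel$origin) < 2L
  if (single_origin) {
    warning("single origin level: model degenerates to temperature only")
    fit <- aov(y ~ temperature, data = rel)
  } else if (nlevels(rel$temperature) > 1L) {
    fit <- aov(y ~ temperature * origin, data = rel)
  } else {
    fit <- aov(y ~ origin, data = rel)
  }
  tuk <- NULL
  if (!single_origin) {
    tuk <- lapply(split(rel, rel$temperature), function(d) {
      if (nrow(d) < 3L || length(unique(d$origin)) < 2L) return(NULL)
      TukeyHSD(aov(y ~ origin, data = droplevels(d)))$origin
    })
  }
  means <- aggregate(cbind(transformed = y, rel_survival) ~
                       temperature + origin, data = rel, FUN = mean)
  list(anova = anova(fit), tukey = tuk, means = means, fit = fit)
}

#' Per-family one-tailed decline tests at an elevated temperature
#'
#' One-sample t tests of mean standardized survival < 1 across replicate
#' plates, with Benjamini-Hochberg false-discovery-rate adjustment across
#' families. Zero-variance replicate sets get an exact decision: all
#' values below 1 give p = 0, all equal to 1 give p = 1.
#'
#' @param rel plate-level data frame from [relative_survival()] restricted
#'   to one temperature (rows per family and plate).
#' @return data frame with `family_id`, `origin`, `mean_rel`, `p`,
#'   `p_adj`, sorted by family.
#' @export
family_decline_tests <- function(rel) {
  rel <- rel[!is.na(rel$rel_survival), , drop = FALSE]
  if (length(unique(rel$temperature)) > 1L)
    stop_param("decline tests expect a single temperature")
  fams <- split(rel, rel$family_id)
  res <- lapply(fams, function(d) {
    x <- d$rel_survival
    if (length(x) < 2L) {
      p <- NA_real_
    } else if (sd(x) == 0) {
      warning("zero-variance replicates for family ", d$family_id[1L])
      p <- if (all(x < 1)) 0 else 1
    } else {
      p <- t.test(x, mu = 1, alternative = "less")$p.value
    }
    data.frame(family_id = d$family_id[1L], origin = d$origin[1L],
               n_rep = length(x), mean_rel = mean(x), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$family_id), ]
}

#' Partial eta-squared effect sizes for survival models
#'
#' Fits linear models of (transformed) standardized survival on the
#' requested factors and reports the partial eta-squared of each term,
#' `SS_effect / (SS_effect + SS_residual)`. For multi-factor models
#' Type-II sums of squares are used, as the parental design is unbalanced.
#'
#' @param rel data frame with one response row per observation (plate- or
#'   family-level standardized survival at one temperature).
#' @param factors character vector of model terms, e.g. `"family_id"` or
#'   `c("dam_id", "sire_id")`.
#' @param response column to analyse (default `"rel_survival"`).
#' @param transform_power exponent applied to the response (default 3,
#'   matching the origin model).
#' @return data frame with `term`, `ss`, `ss_resid`, `partial_eta_sq`, `p`.
#' @export
variance_explained <- function(rel, factors, response = "rel_survival",
                               transform_power = 3) {
  stopifnot(all(factors %in% names(rel)), response %in% names(rel))
  d <- rel[!is.na(rel[[response]]), , drop = FALSE]
  d$y <- d[[response]]^transform_power
  for (f in factors) d[[f]] <- factor(d[[f]])
  form <- stats::reformulate(factors, response = "y")
  fit <- lm(form, data = d)
  if (fit$df.residual == 0L)
    stop_param("saturated model (no residual degrees of freedom) for terms: ",
               paste(factors, collapse = " + "))
  tab <- if (length(factors) > 1L) car::Anova(fit, type = 2) else anova(fit)
  terms_i <- match(factors, rownames(tab))
  ss <- tab[terms_i, "Sum Sq"]
  ss_res <- tab["Residuals", "Sum Sq"]
  pcol <- grep("^Pr", colnames(tab), value = TRUE)[1L]
  data.frame(term = factors, ss = ss, ss_resid = ss_res,
             partial_eta_sq = ss / (ss + ss_res),
             p = tab[terms_i, pcol], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Paternal survival index at the hottest temperature
#'
#' Family heat survival `h` is expressed relative to the maternal mean `m`
#' (mean survival across all families of the same dam at that
#' temperature): `index = h / m - 1`. The index isolates the paternal
#' contribution; per-sire mean indices are also reported.
#'
#' @param table family-level survival table.
#' @param temperature temperature at which to compute the index (default 36).
#' @return list with `families` (per-family index) and `sires` (per-sire
#'   mean index and origin).
#' @export
survival_index <- function(table, temperature = 36) {
  d <- table[table$temperature == temperature, , drop = FALSE]
  if (!nrow(d)) stop_param("no rows at the requested temperature")
  d$survival <- d$n_alive_60h / d$n_start
  m <- tapply(d$survival, d$dam_id, mean)
  mm <- m[d$dam_id]
  idx <- ifelse(mm > 0, d$survival / mm - 1, NA_real_)
  if (any(mm == 0)) warning("maternal mean of zero: index set to missing")
  fam <- data.frame(sire_id = d$sire_id, dam_id = d$dam_id,
                    family_id = d$family_id, origin = d$origin,
                    survival = d$survival, maternal_mean = as.vector(mm),
                    index = as.vector(idx), stringsAsFactors = FALSE)
  sires <- aggregate(index ~ sire_id, data = fam, FUN = mean, na.rm = TRUE)
  sires$origin <- ifelse(grepl("^PG", sires$sire_id), "PG", "IO")
  list(families = fam[order(fam$family_id), ], sires = sires)
}

#' Summarize origin-level field survival
#'
#' Per-origin juvenile survival rates (survivors / deployed), the fraction
#' of families per origin with at least one survivor, and the ratio of the
#' hybrid rate to the hot-purebred rate.
#'
#' @param field data frame with columns `origin`, `deployed`, `survivors`
#'   and optionally `family_id` (family-level rows) or `families` /
#'   `families_with_survivors` (pre-aggregated origin rows).
#' @return list with `by_origin` (rate and family fractions) and
#'   `hybrid_pg_ratio`.
#' @export
field_survival_summary <- function(field) {
  stopifnot(all(c("origin", "deployed", "survivors") %in% names(field)))
  if ("family_id" %in% names(field)) {
    by <- do.call(rbind, lapply(split(field, field$origin), function(d)
      data.frame(origin = d$origin[1L], deployed = sum(d$deployed),
                 survivors = sum(d$survivors), families = nrow(d),
                 families_with_survivors = sum(d$survivors > 0),
                 stringsAsFactors = FALSE)))
  } else {
    stopifnot(all(c("families", "families_with_survivors") %in% names(field)))
    by <- field
  }
  zero <- by$deployed == 0
  if (any(zero)) {
    warning("origins with zero deployed omitted: ",
            paste(by$origin[zero], collapse = ", "))
    by <- by[!zero, , drop = FALSE]
  }
  by$rate <- by$survivors / by$deployed
  by$fraction_families_with_survivors <-
    by$families_with_survivors / by$families
  ratio <- NA_real_
  if (all(c("PGxIO", "PG") %in% by$origin)) {
    pg <- by$rate[by$origin == "PG"]
    hy <- by$rate[by$origin == "PGxIO"]
    ratio <- if (pg > 0) hy / pg else NA_real_
  }
  rownames(by) <- NULL
  list(by_origin = by, hybrid_pg_ratio = ratio,
       total_deployed = sum(by$deployed))
}
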