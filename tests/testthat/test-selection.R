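selection_fixture <- function(minor_amb = 50, minor_hot = 20, depth = 100) {
  sam <- expand.grid(family_id = c("F1", "F2"), temperature = c(27, 36),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sam$origin <- "PGxIO"
  sam$sample_id <- sprintf("%s_%dC", sam$family_id, sam$temperature)
  minor <- ifelse(sam$temperature == 27, minor_amb, minor_hot)
  counts <- data.frame(locus_id = "L00001", sample_id = sam$sample_id,
                       A = depth - minor, C = minor, G = 0, T = 0,
                       stringsAsFactors = FALSE)
  ma <- data.frame(locus_id = "L00001", major = "A", minor = "C",
                   stringsAsFactors = FALSE)
  list(samples = sam, counts = counts, minor = ma)
}

test_that("the selection scan recovers a worked frequency shift", {
  fx <- selection_fixture()
  scan <- scan_selection(fx$counts, fx$samples, fx$minor)
  # 50% ambient vs 20% heat-exposed in both families
  expect_equal(scan$shift, -0.3, tolerance = 1e-12)
  expect_equal(scan$maf_ambient, 0.5)
  expect_equal(scan$maf_hot, 0.2)
  expect_equal(scan$n_families, 2)
  expect_lt(scan$p, 1e-5)
  expect_true(scan$significant)
})

test_that("swapping temperature labels flips the shift, not the p value", {
  fx <- selection_fixture()
  swapped <- fx$samples
  swapped$temperature <- ifelse(swapped$temperature == 27, 36, 27)
  a <- scan_selection(fx$counts, fx$samples, fx$minor)
  b <- scan_selection(fx$counts, swapped, fx$minor)
  expect_equal(b$shift, -a$shift, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("scans demand families covered at both temperatures", {
  fx <- selection_fixture()
  one <- fx$samples[fx$samples$family_id == "F1", ]
  expect_error(scan_selection(fx$counts, one, fx$minor),
               "fewer than 2 families")
  # a family missing its heat pool is excluded, leaving one family
  drop_hot <- fx$samples[!(fx$samples$family_id == "F2" &
                             fx$samples$temperature == 36), ]
  expect_error(scan_selection(fx$counts, drop_hot, fx$minor),
               "fewer than 2 families")
})

test_that("count normalization equalizes library sizes", {
  counts <- data.frame(locus_id = rep(c("L1", "L2"), 2),
                       sample_id = rep(c("S1", "S2"), each = 2),
                       A = c(100, 100, 300, 300), C = c(100, 100, 300, 300),
                       G = 0, T = 0, stringsAsFactors = FALSE)
  norm <- normalize_pool_counts(counts)
  totals <- tapply(rowSums(as.matrix(norm[nt])), norm$sample_id, sum)
  expect_equal(as.vector(totals), c(800, 800))
  # frequencies preserved
  expect_equal(norm$C / (norm$A + norm$C), rep(0.5, 4))
})

test_that("selection summaries compute fixation contrast between origins", {
  mk <- function(origin, sig, maf) {
    data.frame(locus_id = sprintf("L%d", seq_along(sig)), origin = origin,
               n_families = 5, maf_ambient = maf, maf_hot = maf,
               shift = ifelse(sig, 0.2, 0), p = ifelse(sig, 1e-6, 0.5),
               p_adj = ifelse(sig, 1e-4, 1), significant = sig,
               stringsAsFactors = FALSE)
  }
  scans <- list(all = mk("all", c(TRUE, TRUE, FALSE, FALSE),
                         c(0.2, 0.3, 0.4, 0.5)),
                PG = mk("PG", rep(FALSE, 4), c(0.005, 0.2, 0.3, 0.4)),
                IO = mk("IO", rep(FALSE, 4), c(0.005, 0.008, 0.3, 0.4)))
  s <- summarize_selection(scans)
  expect_equal(s$n_selected, 2)  # L1, L2 significant in the pooled scan
  expect_equal(s$by_origin$prop_significant, c(0.5, 0, 0))
  # among selected loci: PG fixed at L1 only, IO at both
  expect_equal(s$fixation$fixed_fraction[s$fixation$origin == "PG"], 0.5)
  expect_equal(s$fixation$fixed_fraction[s$fixation$origin == "IO"], 1)
  expect_equal(s$fixation_ratio, 0.5)
})

test_that("the hybrid PCA names the binding filter when it cannot run", {
  maf <- matrix(runif(9), 3, dimnames = list(sprintf("S%d", 1:3),
                                             sprintf("L%d", 1:3)))
  samples <- data.frame(sample_id = rownames(maf), family_id = "F1",
                        origin = "PGxIO", temperature = 27,
                        stringsAsFactors = FALSE)
  scan <- data.frame(locus_id = colnames(maf), p_adj = 1)
  expect_error(hybrid_shift_pca(maf, samples, scan),
               "0 pass adjusted p < 0.001", fixed = TRUE)
  scan$p_adj <- 1e-6
  maf[1, 1:2] <- NA  # 1/3 missing exceeds the 10% ceiling
  expect_error(hybrid_shift_pca(maf, samples, scan),
               "3 pass adjusted p < 0.001, 1 also pass missingness < 0.1",
               fixed = TRUE)
})
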