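test_that("call_parent_genotype applies the three filtering rules", {
  # error filter boundary: exactly 5% of reads is retained (>= is inclusive)
  expect_equal(call_parent_genotype(counts_vec(A = 95, C = 5), "A")$score, 0.5)
  expect_equal(call_parent_genotype(counts_vec(A = 96, C = 4), "A")$score, 0)
  # coverage boundary: exactly 5 post-filter reads is called
  expect_equal(call_parent_genotype(counts_vec(A = 5), "A")$score, 0)
  expect_true(is.na(call_parent_genotype(counts_vec(A = 4), "A")$score))
  # no reads at all
  res <- call_parent_genotype(counts_vec(), "A")
  expect_true(is.na(res$score))
  expect_equal(res$alleles, character(0))
  # three surviving alleles flagged multiallelic
  res <- call_parent_genotype(counts_vec(A = 10, C = 10, G = 10), "A")
  expect_true(is.na(res$score))
  expect_true(res$multiallelic)
  expect_error(call_parent_genotype(counts_vec(A = -1), "A"), "negative")
})

test_that("matrix genotype calls agree with the scalar caller", {
  set.seed(42)
  n <- 200
  reg <- toy_registry(n, ref = sample(nt, n, replace = TRUE))
  counts <- data.frame(locus_id = reg$locus_id, sample_id = "P01",
                       A = rpois(n, 3), C = rpois(n, 3),
                       G = rpois(n, 3), T = rpois(n, 3),
                       stringsAsFactors = FALSE)
  mat <- suppressWarnings(call_parent_genotypes(counts, reg))
  expect_equal(dim(mat), c(1L, n))
  single <- vapply(seq_len(n), function(i)
    call_parent_genotype(unlist(counts[i, nt]), reg$ref[i])$score, numeric(1))
  expect_equal(unname(mat[1, ]), single)
})

test_that("minor alleles are designated globally with lexicographic ties", {
  reg <- toy_registry(3, ref = c("A", "G", "T"), alt = c("C", "A", "C"))
  counts <- data.frame(locus_id = rep(reg$locus_id, 2),
                       sample_id = rep(c("S1", "S2"), each = 3),
                       A = c(10, 5, 0, 10, 5, 0), C = c(3, 0, 0, 3, 0, 0),
                       G = c(0, 5, 0, 0, 5, 0), T = c(1, 0, 0, 1, 0, 0),
                       stringsAsFactors = FALSE)
  ma <- designate_minor_alleles(counts, reg)
  expect_equal(ma$major, c("A", "A", "T"))  # tie at L2: A before G
  expect_equal(ma$minor, c("C", "G", "C"))  # L3 uncovered: registry fallback
})

test_that("pooled MAF calls are scale-free and coverage-gated", {
  reg <- toy_registry(2)
  ma <- data.frame(locus_id = reg$locus_id, major = "A", minor = "G",
                   stringsAsFactors = FALSE)
  counts <- data.frame(locus_id = reg$locus_id, sample_id = "S1",
                       A = c(60, 30), C = 0, G = c(20, 10), T = 0,
                       stringsAsFactors = FALSE)
  maf <- call_pooled_maf(counts, ma, min_cov = 50)
  expect_equal(unname(maf[1, ]), c(0.25, NA))  # 40 reads at L2: below 50x
  counts2 <- counts
  counts2[nt] <- counts2[nt] * 3
  maf2 <- call_pooled_maf(counts2, ma, min_cov = 50)
  expect_equal(unname(maf2[1, ]), c(0.25, 0.25))
})

test_that("filtering removes samples, then loci, then monomorphic loci", {
  parent <- rbind(P1 = c(0, 0.5, NA, 1),
                  P2 = c(NA, NA, NA, NA),   # sample too sparse
                  P3 = c(0, 1, NA, 1))
  colnames(parent) <- sprintf("L%d", 1:4)
  pooled <- rbind(S1 = c(0.1, 0.2), S2 = c(0.3, 0.2), S3 = c(0.2, 0.2))
  colnames(pooled) <- c("M1", "M2")
  filt <- filter_genotype_data(parent, pooled,
                               max_missing_per_sample = 0.5,
                               max_missing_per_locus = 0.3)
  expect_equal(rownames(filt$parent), c("P1", "P3"))
  # L3 all-missing after the sample drop; L1 and L4 monomorphic in P1/P3
  expect_equal(colnames(filt$parent), "L2")
  expect_equal(filt$report$parent_samples_removed, 1)
  expect_equal(filt$report$parent_loci_removed_missing, 1)
  expect_equal(filt$report$parent_loci_removed_monomorphic, 2)
  # M2 constant across pooled samples
  expect_equal(colnames(filt$pooled), "M1")
  expect_error(
    filter_genotype_data(parent[, 1, drop = FALSE] * 0,
                         pooled[, 2, drop = FALSE]),
    "no loci survive")
})
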