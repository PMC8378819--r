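assoc_fixture <- function() {
  x <- seq(0.1, 0.8, by = 0.1)
  maf <- cbind(L1 = x, L2 = rep(0.4, 8), L3 = rev(x))
  rownames(maf) <- sprintf("F%d", 1:8)
  survival <- data.frame(family_id = rownames(maf), origin = "PG",
                         temperature = 36, n_start = 200,
                         n_alive_60h = round(200 * x),
                         stringsAsFactors = FALSE)
  list(maf = maf, survival = survival)
}

test_that("the association scan classifies planted and flat loci", {
  fx <- assoc_fixture()
  scan <- scan_survival_association(fx$maf, fx$survival)
  expect_equal(attr(scan, "n_tested"), 3L)
  l1 <- scan[scan$locus_id == "L1", ]
  expect_gt(l1$R, 0.99)
  expect_equal(l1$class, "strong")
  expect_true(l1$significant)
  expect_equal(l1$beneficial_allele, "minor")
  l2 <- scan[scan$locus_id == "L2", ]
  expect_true(is.na(l2$R))
  expect_equal(l2$p, 1)
  expect_equal(l2$class, "none")
  l3 <- scan[scan$locus_id == "L3", ]
  expect_lt(l3$R, -0.99)
  expect_equal(l3$beneficial_allele, "major")
  expect_equal(scan$p_adj, pmin(scan$p * 3, 1))
  expect_error(
    scan_survival_association(fx$maf[1:2, ], fx$survival[1:2, ]),
    "fewer than 3 families")
})

test_that("beneficial alleles are reported as bases when designated", {
  fx <- assoc_fixture()
  ma <- data.frame(locus_id = c("L1", "L2", "L3"),
                   major = "A", minor = "C", stringsAsFactors = FALSE)
  scan <- scan_survival_association(fx$maf, fx$survival, minor_alleles = ma)
  expect_equal(scan$beneficial_allele[scan$locus_id == "L1"], "C")
  expect_equal(scan$beneficial_allele[scan$locus_id == "L3"], "A")
  expect_equal(scan$minor_allele, rep("C", 3))
})

test_that("association summaries report class percentages", {
  assoc <- data.frame(class = c(rep("strong", 2), rep("moderate_weak", 3),
                                rep("none", 5)),
                      significant = c(TRUE, FALSE, rep(FALSE, 8)))
  s <- summarize_association(assoc)
  expect_equal(s$n_tested, 10)
  expect_equal(s$pct_strong, 20)
  expect_equal(s$pct_moderate_weak, 30)
  expect_equal(s$n_significant, 1)
})

test_that("parent scoring converts genotype scores through the registry", {
  reg <- toy_registry(2, ref = c("A", "A"), alt = c("G", "G"))
  pm <- rbind(P1 = c(1, 0), P2 = c(0.5, NA), P3 = c(0, 1))
  colnames(pm) <- reg$locus_id
  ben <- data.frame(locus_id = reg$locus_id,
                    beneficial_allele = c("G", "A"),  # alt then ref
                    stringsAsFactors = FALSE)
  sc <- score_parents(pm, ben, reg)
  expect_equal(sc$proportion[sc$parent_id == "P1"], 1)    # (1 + (1-0))/2
  expect_equal(sc$proportion[sc$parent_id == "P2"], 0.5)  # only L1 scored
  expect_equal(sc$n_loci_scored, c(2, 1, 2))
  expect_equal(sc$proportion[sc$parent_id == "P3"], 0)
  expect_error(score_parents(pm, ben[0, ], reg), "no loci")
})

test_that("parent-performance correlation honours exclusions", {
  scores <- data.frame(parent_id = sprintf("S%d", 1:5),
                       n_loci_scored = 10,
                       proportion = c(0.1, 0.3, 0.5, 0.7, 0.9))
  idx <- data.frame(sire_id = sprintf("S%d", 1:5),
                    index = c(-0.2, 0, 0.1, 0.3, 0.5))
  pp <- correlate_parent_performance(scores, idx)
  expect_equal(pp$n, 5)
  expect_equal(pp$r, cor(scores$proportion, idx$index), tolerance = 1e-12)
  pp2 <- correlate_parent_performance(scores, idx, exclude = "S5")
  expect_equal(pp2$n, 4)
  expect_error(correlate_parent_performance(scores, idx,
                                            exclude = c("S1", "S2", "S3")),
               "fewer than 3 sires")
})

test_that("paternal clustering is deterministic and flags sparse overlap", {
  set.seed(8)
  pm <- matrix(sample(c(0, 0.5, 1), 60, replace = TRUE), nrow = 3,
               dimnames = list(c("S2", "S1", "S3"), sprintf("L%d", 1:20)))
  cl <- cluster_paternal_genotypes(pm, sprintf("L%d", 1:20))
  expect_s3_class(cl$hclust, "hclust")
  expect_setequal(cl$order, c("S1", "S2", "S3"))
  expect_identical(cl, cluster_paternal_genotypes(pm, sprintf("L%d", 1:20)))
  expect_warning(cluster_paternal_genotypes(pm, sprintf("L%d", 1:20),
                                            min_shared = 50),
                 "low-confidence")
  expect_error(cluster_paternal_genotypes(pm, "L1"), "at least 2")
})
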