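test_that("population_model validates its arguments", {
  expect_error(population_model(beneficial_freq_hot = 0.2,
                                beneficial_freq_cool = 0.5),
               "beneficial_freq_hot")
  expect_error(population_model(divergence = 1.5), "divergence")
  expect_error(population_model(n_loci = 100, causal_loci = c(5, 200)),
               "causal_loci")
})

test_that("simulate_populations sets causal frequencies and is deterministic", {
  m <- population_model(n_loci = 100, causal_loci = c(5, 10),
                        causal_effect = 0.4, beneficial_freq_hot = 0.8,
                        beneficial_freq_cool = 0.3, fixation_fraction = 0.5)
  pops <- simulate_populations(m, seed = 7)
  expect_equal(nrow(pops$registry), 100)
  expect_equal(pops$causal$locus_id, pops$registry$locus_id[c(5, 10)])
  # half the causal loci (the first in index order) fixed in the hot pool
  expect_equal(unname(pops$freq_hot[5]), 1)
  expect_equal(unname(pops$freq_hot[10]), 0.8)
  expect_equal(unname(pops$freq_cool[c(5, 10)]), c(0.3, 0.3))
  expect_true(all(pops$freq_hot >= 0 & pops$freq_hot <= 1))
  pops2 <- simulate_populations(m, seed = 7)
  expect_identical(pops, pops2)
  pops3 <- simulate_populations(m, seed = 8)
  expect_false(identical(pops$freq_hot, pops3$freq_hot))
})

test_that("draw_parents respects Hardy-Weinberg limits", {
  freq <- c(L1 = 0, L2 = 1, L3 = 0.5)
  g <- draw_parents(freq, 10, seed = 3, ids = sprintf("P%02d", 1:10))
  expect_equal(dim(g), c(10L, 3L))
  expect_true(all(g %in% 0:2))
  expect_true(all(g[, "L1"] == 0))
  expect_true(all(g[, "L2"] == 2))
})

test_that("make_cross_design enumerates the realized study design", {
  des <- make_cross_design()
  expect_equal(nrow(des), 50L)
  expect_equal(as.vector(table(des$origin)[c("PG", "IO", "PGxIO")]),
               c(18L, 12L, 20L))
  expect_false(anyDuplicated(des[c("dam_id", "sire_id")]) > 0)
  expect_true(all(des$family_id == paste(des$dam_id, des$sire_id, sep = "x")))
  # hybrids run one direction: cool dam x hot sire
  hyb <- des[des$origin == "PGxIO", ]
  expect_true(all(grepl("^IO-", hyb$dam_id)))
  expect_true(all(grepl("^PG-", hyb$sire_id)))
  expect_error(make_cross_design(realized = c(PG = 100, IO = 12, PGxIO = 20)),
               "combinatorial maximum")
})

test_that("simulate_family_survival produces consistent counts and pools", {
  m <- population_model(n_loci = 50, causal_loci = 5, causal_effect = 0.5)
  pops <- simulate_populations(m, seed = 2)
  des <- make_cross_design(n_hot_sires = 2, n_cool_sires = 2,
                           n_hot_dams = 1, n_cool_dams = 1,
                           realized = c(PG = 2, IO = 2, PGxIO = 2))
  par <- draw_design_parents(des, pops, seed = 2)
  s <- simulate_family_survival(des, par, pops, n_larvae_per_family = 60,
                                temperatures = c(27, 36),
                                baseline_survival = c("27" = 0.9, "36" = 1e-6),
                                temp_scale = c("27" = 0, "36" = 1), seed = 2)
  expect_true(all(s$survival$n_alive_60h <= s$survival$n_start))
  expect_equal(nrow(s$samples), nrow(des) * 2L)
  expect_equal(dim(s$pool_freq), c(nrow(des) * 2L, 50L))
  # pools with no survivors carry missing frequencies
  dead <- s$samples$sample_id[s$samples$n_survivors == 0]
  expect_gt(length(dead), 0)
  expect_true(all(is.na(s$pool_freq[dead, ])))
  alive <- s$samples$sample_id[s$samples$n_survivors > 0]
  expect_true(all(s$pool_freq[alive, ] >= 0 & s$pool_freq[alive, ] <= 1))
})

test_that("emit_read_counts places reads on registry alleles only", {
  reg <- toy_registry(4, ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"))
  freq <- matrix(c(0.5, 0, 1, NA), nrow = 1,
                 dimnames = list("S1", reg$locus_id))
  counts <- emit_read_counts(freq, reg, mean_depth = 80, error_rate = 0,
                             seed = 5)
  cmat <- as.matrix(counts[nt])
  # with zero error every read lands on the reference or alternate base
  other <- vapply(seq_len(4), function(i)
    sum(cmat[i, setdiff(nt, c(reg$ref[i], reg$alt[i]))]), numeric(1))
  expect_true(all(other == 0))
  # missing input frequency yields zero depth
  expect_equal(sum(cmat[4, ]), 0)
  counts2 <- emit_read_counts(freq, reg, mean_depth = 80, error_rate = 0,
                              seed = 5)
  expect_identical(counts, counts2)
  expect_error(emit_read_counts(freq, reg, mean_depth = 0), "mean_depth")
  expect_error(emit_read_counts(freq, reg, error_rate = 0.7), "error_rate")
})

test_that("simulate_experiment is reproducible under one master seed", {
  p <- list(n_loci = 60, n_causal = 3, n_larvae_per_family = 30,
            parent_mean_depth = 20, pool_mean_depth = 30)
  a <- simulate_experiment(p, seed = 11)
  b <- simulate_experiment(p, seed = 11)
  expect_identical(a$survival, b$survival)
  expect_identical(a$pool_counts, b$pool_counts)
  expect_identical(a$parent_genotypes, b$parent_genotypes)
  c <- simulate_experiment(p, seed = 12)
  expect_false(identical(a$pool_counts, c$pool_counts))
})
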