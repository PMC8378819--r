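sim_sire_dam <- function(n_sires, n_dams, reps, v_s, v_d, v_e, seed) {
  set.seed(seed)
  grid <- expand.grid(sire = sprintf("S%02d", seq_len(n_sires)),
                      dam = sprintf("D%02d", seq_len(n_dams)),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  su <- stats::setNames(rnorm(n_sires, 0, sqrt(v_s)), unique(grid$sire))
  du <- stats::setNames(rnorm(n_dams, 0, sqrt(v_d)), unique(grid$dam))
  grid$y <- su[grid$sire] + du[grid$dam] + rnorm(nrow(grid), 0, sqrt(v_e))
  grid
}

test_that("the Gibbs sampler is deterministic and internally consistent", {
  d <- sim_sire_dam(8, 4, 3, 0.3, 0.1, 0.6, seed = 5)
  f1 <- estimate_heritability(d$y, d$sire, d$dam, seed = 9)
  f2 <- estimate_heritability(d$y, d$sire, d$dam, seed = 9)
  expect_identical(f1$summary, f2$summary)
  # additive variance is exactly four times the sire component per draw
  expect_equal(f1$draws[, "V_A"], 4 * f1$draws[, "V_sire"])
  h2 <- f1$draws[, "h2_with_maternal"]
  expect_true(all(h2 >= 0 & h2 <= 1))
  expect_true(all(h2 <= f1$draws[, "h2_no_maternal"]))
  expect_equal(rownames(f1$summary),
               c("V_sire", "V_dam", "V_resid", "mu", "V_A",
                 "h2_no_maternal", "h2_with_maternal"))
  f3 <- estimate_heritability(d$y, d$sire, d$dam, seed = 10)
  expect_false(identical(f1$summary, f3$summary))
})

test_that("the posterior separates sire from dam variance", {
  # strong paternal signal, no maternal signal
  d <- sim_sire_dam(20, 5, 3, 1, 0, 0.25, seed = 21)
  fit <- estimate_heritability(d$y, d$sire, d$dam, seed = 21)
  expect_gt(fit$summary["V_sire", "mean"], fit$summary["V_dam", "mean"])
  expect_gt(fit$summary["h2_with_maternal", "mean"], 0.5)
})

test_that("degenerate inputs are rejected and short chains warn", {
  expect_error(estimate_heritability(rnorm(10), rep("S1", 10),
                                     rep(c("D1", "D2"), 5)),
               "at least 2 sires")
  expect_error(estimate_heritability(c(1, 2), c("S1", "S2"), c("D1", "D2")),
               "too few observations")
  d <- sim_sire_dam(6, 3, 2, 0.3, 0.1, 0.6, seed = 3)
  expect_warning(
    estimate_heritability(d$y, d$sire, d$dam,
                          chain = list(n_iter = 120, burn_in = 20, thin = 1),
                          seed = 3),
    "effective sample size")
})
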