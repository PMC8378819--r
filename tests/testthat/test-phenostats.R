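surv_row <- function(family, dam, sire, origin, temp, n, alive, plate = NULL) {
  d <- data.frame(family_id = family, dam_id = dam, sire_id = sire,
                  origin = origin, temperature = temp, n_start = n,
                  n_alive_60h = alive, stringsAsFactors = FALSE)
  if (!is.null(plate)) d$plate <- plate
  d
}

test_that("relative survival standardizes to ambient and caps at one", {
  tab <- rbind(surv_row("F1", "D1", "S1", "PG", 27, 100, 80),
               surv_row("F1", "D1", "S1", "PG", 36, 100, 90),
               surv_row("F2", "D1", "S2", "PG", 27, 100, 0),
               surv_row("F2", "D1", "S2", "PG", 36, 100, 10))
  expect_warning(rel <- relative_survival(tab), "zero ambient")
  expect_equal(rel$rel_survival[rel$family_id == "F1"], 1)  # 0.9/0.8 capped
  expect_true(is.na(rel$rel_survival[rel$family_id == "F2"]))
  expect_error(relative_survival(tab[tab$temperature == 36, ]),
               "ambient row")
  bad <- tab; bad$n_alive_60h[1] <- 200
  expect_error(relative_survival(bad), "n_start")
})

test_that("partial eta-squared matches the hand-computed toy example", {
  rel <- data.frame(grp = rep(c("a", "b"), each = 3),
                    rel_survival = c(1, 2, 3, 4, 5, 6),
                    stringsAsFactors = FALSE)
  ve <- variance_explained(rel, "grp", transform_power = 1)
  expect_equal(ve$partial_eta_sq, 13.5 / 17.5, tolerance = 1e-12)
  expect_error(variance_explained(rel[c(1, 4), ], "grp", transform_power = 1),
               "saturated")
})

test_that("family decline tests handle zero-variance replicates exactly", {
  rel <- data.frame(family_id = rep(c("F1", "F2", "F3"), each = 3),
                    origin = "PG", temperature = 36,
                    rel_survival = c(0.5, 0.5, 0.5, 1, 1, 1, 0.4, 0.5, 0.6),
                    stringsAsFactors = FALSE)
  expect_warning(res <- family_decline_tests(rel), "zero-variance")
  expect_equal(res$p[res$family_id == "F1"], 0)
  expect_equal(res$p[res$family_id == "F2"], 1)
  expect_true(res$p[res$family_id == "F3"] > 0 &&
                res$p[res$family_id == "F3"] < 0.05)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("survival index reproduces the worked dam-relative example", {
  tab <- rbind(surv_row("F1", "D1", "S1", "PG", 36, 100, 72),
               surv_row("F2", "D1", "S2", "PG", 36, 100, 34))
  si <- survival_index(tab, temperature = 36)
  # maternal mean (0.72 + 0.34)/2 = 0.53; index 0.72/0.53 - 1
  expect_equal(si$families$index[si$families$family_id == "F1"],
               0.72 / 0.53 - 1, tolerance = 1e-12)
  expect_equal(si$sires$index[si$sires$sire_id == "S1"], 0.72 / 0.53 - 1)
  expect_error(survival_index(tab, temperature = 33), "no rows")
})

test_that("origin model warns when only one origin is present", {
  rel <- data.frame(origin = "PG", temperature = rep(c(33, 36), 6),
                    rel_survival = rep(c(0.9, 0.5, 0.8, 0.4), 3),
                    stringsAsFactors = FALSE)
  expect_warning(om <- origin_effect_model(rel), "single origin")
  expect_null(om$tukey)
})

test_that("field survival summary reproduces the reported rate ratio", {
  field <- data.frame(origin = c("PGxIO", "PG"),
                      families = c(8, 6), families_with_survivors = c(5, 2),
                      deployed = c(10000, 10000), survivors = c(192, 31),
                      stringsAsFactors = FALSE)
  fs <- field_survival_summary(field)
  expect_equal(fs$hybrid_pg_ratio, 192 / 31, tolerance = 1e-12)
  expect_equal(fs$hybrid_pg_ratio, 6.19, tolerance = 0.01)
  # family-level rows aggregate to the same origin table
  fam <- data.frame(origin = rep("PG", 3), family_id = c("a", "b", "c"),
                    deployed = c(100, 200, 50), survivors = c(0, 4, 0),
                    stringsAsFactors = FALSE)
  fs2 <- field_survival_summary(fam)
  expect_equal(fs2$by_origin$families_with_survivors, 1)
  expect_equal(fs2$by_origin$rate, 4 / 350)
})
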