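test_that("the pooled two-sample z reproduces the worked examples", {
  # (0.082, 0.036) vs (0.062, 0.025), R = 10000 -> delta 0.020, z ~ 45.6
  z1 <- pairwise_z(0.082, 0.036, 0.062, 0.025, 10000)
  expect_equal(round(z1, 1), 45.6)
  # (0.082, 0.036) vs (0.014, 0.019) -> delta ~ 0.068, z ~ 167
  z2 <- pairwise_z(0.082, 0.036, 0.014, 0.019, 10000)
  expect_equal(round(z2), 167)
  # antisymmetry of the statistic itself
  expect_equal(pairwise_z(0.014, 0.019, 0.082, 0.036, 10000), -z2)
})

test_that("pairwise comparison fills delta, p and direction coherently", {
  a <- importance_from_drops("TFI17", c(0.08, 0.09, 0.07, 0.085, 0.082))
  b <- importance_from_drops("TFI13", c(0.01, 0.02, 0.015, 0.012, 0.018))
  pc <- pairwise_compare(a, b, alpha_corrected = 0.0167)
  expect_equal(pc$delta, a$mu - b$mu)
  expect_equal(pc$z, pairwise_z(a$mu, a$sigma, b$mu, b$sigma, 5))
  expect_equal(pc$p_two_tailed, 2 * pnorm(-abs(pc$z)))
  expect_true(pc$significant)
  expect_equal(pc$direction, "a")

  # self-comparison: zero delta, z = 0, never significant
  self <- pairwise_compare(a, a, 0.05)
  expect_equal(self$delta, 0)
  expect_equal(self$z, 0)
  expect_false(self$significant)

  # mismatched R or subset is an error
  b2 <- importance_from_drops("TFI13", c(0.01, 0.02))
  expect_error(pairwise_compare(a, b2), "different R")
  b3 <- importance_from_drops("TFI13", b$drops, subset = "validation")
  expect_error(pairwise_compare(a, b3), "subset")
})

test_that("an unused feature is dominated when the other importance is significant", {
  used <- importance_from_drops("TFI17", c(0.08, 0.09, 0.07, 0.085, 0.082,
                                           0.09, 0.08, 0.075))
  unused <- importance_from_drops("TFI19", rep(0, 8))
  pc <- pairwise_compare(used, unused, alpha_corrected = 0.05)
  expect_true(pc$significant)
  expect_equal(pc$direction, "a")
  pc_rev <- pairwise_compare(unused, used, alpha_corrected = 0.05)
  expect_equal(pc_rev$direction, "b")
  # but an unused feature against a non-significant one stays undecided
  weak <- importance_from_drops("TFI12", c(-0.01, 0.01, -0.012, 0.011,
                                           -0.009, 0.008, 0.01, -0.01))
  expect_false(pairwise_compare(weak, unused, alpha_corrected = 0.05)$significant)
})

test_that("Bonferroni thresholds and the comparison count match the design", {
  expect_equal(round(bonferroni_alpha(0.05, 3), 4), 0.0167)
  expect_equal(round(bonferroni_alpha(0.05, 105), 6), 0.000476)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m")
  expect_error(bonferroni_alpha(1.2, 3), "alpha")

  psychosocial <- paste0("TFI", 19:25)
  physical <- c("TFI13", "TFI17", "TFI18")
  expect_equal(count_hypothesis_comparisons(psychosocial, physical), 21)
  expect_equal(count_hypothesis_comparisons("TFI19", "TFI13"), 1)
  expect_equal(count_hypothesis_comparisons(paste0("TFI", 19:22),
                                            physical), 12)
  expect_error(count_hypothesis_comparisons(psychosocial, "TFI19"),
               "disjoint")
  expect_error(count_hypothesis_comparisons(character(0), physical),
               "nonempty")
})

test_that("comparison matrices are antisymmetric with symmetric significance", {
  coh <- generate_cohort(one_signal_spec(n = 700, seed = 31))
  sp <- split_dataset(coh, seed = 31)
  m <- train_model(model_config("random_forest", seed = 31), coh[sp$train, ])
  tab <- importance_table(m, coh[sp$test, ], R = 150, seed = 9)
  cm <- comparison_matrix(tab, alpha = 0.05)
  expect_equal(cm$m, choose(15, 2))
  expect_equal(cm$alpha_corrected, 0.05 / 105)
  expect_equal(cm$delta, -t(cm$delta))
  expect_equal(cm$z, -t(cm$z))
  expect_true(all(diag(cm$delta) == 0))
  expect_identical(cm$significant, t(cm$significant))
  expect_false(any(diag(cm$significant)))
  expect_equal(nrow(cm$pairs), choose(15, 2))
  # sign convention: positive delta in row TFI17 means TFI17 more important
  expect_true(all(cm$delta["TFI17", setdiff(tfi_items(), "TFI17")] > 0))
  # the dominant signal item is significant against every noise item
  expect_true(all(cm$significant["TFI17", setdiff(tfi_items(), "TFI17")]))
})

test_that("identical importance distributions produce no significant cells", {
  drops <- c(0.01, 0.02, 0.015, 0.018, 0.012, 0.02)
  res <- lapply(c("TFI11", "TFI12", "TFI13"), importance_from_drops,
                drops = drops)
  cm <- comparison_matrix(res, alpha = 0.05, m = 3)
  expect_equal(cm$alpha_corrected, bonferroni_alpha(0.05, 3))
  expect_false(any(cm$significant))
  expect_true(all(cm$delta == 0))
})

test_that("importance orderings built into the data are never significantly inverted", {
  # construction: three items with importance A > B > C by design
  withr::with_seed(77, {
    for (rep in 1:5) {
      base <- abs(rnorm(200, 0.05, 0.01))
      a <- importance_from_drops("TFI17", base + 0.04)
      b <- importance_from_drops("TFI20", base + 0.02)
      c_ <- importance_from_drops("TFI13", base)
      cm <- comparison_matrix(list(a, b, c_), alpha = 0.05, m = 3)
      if (cm$significant["TFI17", "TFI20"] && cm$significant["TFI20", "TFI13"]) {
        # no significant C > A reversal alongside A > B and B > C
        expect_false(cm$significant["TFI13", "TFI17"] &&
                       cm$delta["TFI13", "TFI17"] > 0)
      }
    }
  })
})
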