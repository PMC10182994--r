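algorithms <- c("decision_tree", "random_forest", "adaboost")

test_that("all three families separate a perfectly separable toy set", {
  d <- separable_frame(60)
  for (a in algorithms) {
    cfg <- model_config(a, seed = 3)
    m <- train_model(cfg, d)
    r <- evaluate_rates(m, d)
    expect_equal(r$tpr, 1, label = paste(a, "training TPR"))
    expect_equal(r$tnr, 1, label = paste(a, "training TNR"))
  }
})

test_that("config invariants and validation errors are enforced", {
  expect_error(model_config("decision_tree", n_estimators = 5), "one estimator")
  expect_error(model_config("adaboost", max_depth = 0), "max_depth")
  expect_error(model_config("random_forest", min_leaf_fraction = 0.7),
               "min_leaf_fraction")
  d <- separable_frame(40)
  d$frail <- 1L
  expect_error(train_model(model_config("decision_tree"), d), "both classes")
  d2 <- separable_frame(40)
  d2$TFI15 <- 2L
  expect_error(train_model(model_config("decision_tree"), d2), "binary")
})

test_that("decision tree honours depth and leaf-fraction constraints", {
  coh <- make_complete_cohort(n = 400, seed = 21)
  cfg <- model_config("decision_tree", max_depth = 3, min_leaf_fraction = 0.1)
  m <- train_model(cfg, coh)
  fr <- m$fit$frame
  leaves <- fr[fr$var == "<leaf>", ]
  expect_true(all(leaves$n >= ceiling(0.1 * nrow(coh))))
  # depth of an rpart node = floor(log2(its number)); root is node 1
  depths <- floor(log2(as.numeric(rownames(fr))))
  expect_lte(max(depths), 3)
})

test_that("fitting and prediction are deterministic given config and data", {
  coh <- make_complete_cohort(n = 250, seed = 14)
  probe <- make_complete_cohort(n = 100, seed = 15)
  for (a in algorithms) {
    cfg <- model_config(a, seed = 8)
    p1 <- predict(train_model(cfg, coh), probe)
    p2 <- predict(train_model(cfg, coh), probe)
    expect_identical(p1, p2, label = paste(a, "determinism"))
    expect_true(all(p1 %in% c(0L, 1L)))
  }
})

test_that("the lookup-table fast path agrees exactly with direct prediction", {
  coh <- make_complete_cohort(n = 300, seed = 33)
  probe <- make_complete_cohort(n = 200, seed = 34)
  mf <- tfiperm:::model_frame(probe)
  bits <- tfiperm:::pattern_bits(mf$X)
  for (a in algorithms) {
    m <- train_model(model_config(a, seed = 2), coh)
    expect_identical(tfiperm:::table_predict(m, bits),
                     tfiperm:::raw_predict(m, mf$X),
                     label = paste(a, "table vs direct"))
  }
})

test_that("confusion rates follow their definitions and conserve counts", {
  # arithmetic example: 34 of 43 positives, 14 of 16 negatives correct
  truth <- c(rep(1L, 43), rep(0L, 16))
  pred <- c(rep(1L, 34), rep(0L, 9), rep(0L, 14), rep(1L, 2))
  r <- classification_rates(truth, pred)
  expect_equal(round(r$tpr, 4), 0.7907)
  expect_equal(r$tnr, 0.8750)
  expect_equal(sum(r$counts), 59)

  r2 <- classification_rates(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(r2$tpr, 1)
  expect_equal(r2$tnr, 0)

  r3 <- classification_rates(rep(1L, 5), rep(1L, 5))
  expect_true(is.na(r3$tnr))
  expect_match(attr(r3$tnr, "reason"), "no negative")

  # property: counts always split the evaluated sample by true class
  withr::with_seed(5, {
    for (i in 1:20) {
      truth <- rbinom(50, 1, 0.6)
      pred <- rbinom(50, 1, 0.5)
      r <- classification_rates(truth, pred)
      expect_equal(unname(r$counts["tp"] + r$counts["fn"]), sum(truth == 1))
      expect_equal(unname(r$counts["tn"] + r$counts["fp"]), sum(truth == 0))
    }
  })
})

test_that("selection maximises balance then prefers the lowest complexity", {
  heat <- data.frame(
    algorithm = "decision_tree",
    max_depth = c(2, 3, 5, 5),
    min_leaf_fraction = c(0.1, 0.1, 0.1, 0.2),
    n_estimators = 1,
    tpr_val = c(1.0, 0.8, 0.8, 0.8),
    tnr_val = c(0.2, 0.8, 0.8, 0.8)
  )
  heat$objective <- pmin(heat$tpr_val, heat$tnr_val)
  ord <- tfiperm:::rank_configs(heat)
  # balanced (0.8, 0.8) beats unbalanced (1.0, 0.2); among the tied balanced
  # configs the smallest depth wins
  expect_equal(heat$max_depth[ord[1]], 3)
  expect_equal(heat$objective[ord[1]], 0.8)
  # among equal depths, the larger leaf fraction (simpler tree) ranks first
  expect_equal(heat$min_leaf_fraction[ord[2:3]], c(0.2, 0.1))
})

test_that("select_hyperparameters returns the single grid point, and a heatmap", {
  coh <- make_complete_cohort(n = 240, seed = 55)
  sp <- split_dataset(coh, seed = 1)
  grid1 <- data.frame(max_depth = 2, min_leaf_fraction = 0.1, n_estimators = 1)
  sel <- select_hyperparameters("decision_tree", grid1, coh[sp$train, ],
                                coh[sp$validation, ], seed = 9)
  expect_equal(sel$config$max_depth, 2L)
  expect_equal(nrow(sel$heatmap), 1)
  expect_true(all(c("tpr_val", "tnr_val", "objective") %in%
                    names(sel$heatmap)))
  expect_error(select_hyperparameters("decision_tree", NULL, coh, coh),
               "empty")
})

test_that("the study's three configurations train without error on the default cohort", {
  coh <- drop_incomplete(generate_cohort(cohort_spec(n = 666, seed = 61)))
  sp <- split_dataset(coh, seed = 61)
  for (a in algorithms) {
    m <- train_model(model_config(a, seed = 61), coh[sp$train, ])
    r <- evaluate_rates(m, coh[sp$validation, ])
    expect_s3_class(m, "tfi_model")
    expect_true(is.finite(r$tpr) && is.finite(r$tnr))
  }
})

test_that("with one strongly predictive item all three models beat chance on validation", {
  coh <- generate_cohort(one_signal_spec(n = 900, seed = 62))
  sp <- split_dataset(coh, seed = 62)
  for (a in algorithms) {
    m <- train_model(model_config(a, seed = 62), coh[sp$train, ])
    r <- evaluate_rates(m, coh[sp$validation, ])
    expect_gt(min(r$tpr, r$tnr), 0.5,
              label = paste(a, "validation min(TPR,TNR)"))
  }
})
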