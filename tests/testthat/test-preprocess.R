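test_that("drop_incomplete keeps exactly the complete records, idempotently", {
  coh <- make_complete_cohort(n = 120, seed = 2)
  expect_identical(drop_incomplete(coh), coh) # nothing missing: identity

  coh2 <- coh
  coh2$TFI19[5] <- NA # a single missing item excludes the record
  kept <- drop_incomplete(coh2)
  expect_equal(nrow(kept), 119)
  expect_false("R00005" %in% kept$record_id)
  expect_identical(drop_incomplete(kept), kept)

  # constructed 666-record cohort with exactly 54 incomplete records -> 612
  big <- make_complete_cohort(n = 666, seed = 8)
  big[seq_len(54), "TFI15"] <- NA
  expect_equal(nrow(drop_incomplete(big)), 612)

  all_na <- coh
  for (id in tfi_items()) all_na[[id]] <- NA_integer_
  expect_error(drop_incomplete(all_na), "complete")
})

test_that("split sizes follow the 4/6-1/6-1/6 rule with the documented tie-break", {
  expect_equal(unname(tfiperm:::split_sizes(612, c(4, 1, 1) / 6)),
               c(408, 102, 102))
  expect_equal(unname(tfiperm:::split_sizes(6, c(4, 1, 1) / 6)), c(4, 1, 1))
  # odd remainder goes to validation
  expect_equal(unname(tfiperm:::split_sizes(8, c(4, 1, 1) / 6)), c(5, 2, 1))
  for (n in c(6, 7, 13, 100, 611, 612, 613)) {
    s <- tfiperm:::split_sizes(n, c(4, 1, 1) / 6)
    expect_equal(sum(s), n)
    expect_equal(unname(s["train"]), round(4 / 6 * n))
    expect_lte(abs(s[["validation"]] - s[["test"]]), 1)
  }
})

test_that("split is an exact partition, reproducible, and stratifiable", {
  coh <- make_complete_cohort(n = 121, prevalence = 0.8, seed = 13)
  for (seed in c(1, 2, 3)) {
    sp <- split_dataset(coh, seed = seed)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_idx), seq_len(nrow(coh))) # partition, no overlap
  }
  expect_identical(split_dataset(coh, seed = 5), split_dataset(coh, seed = 5))
  expect_false(identical(split_dataset(coh, seed = 5)$train,
                         split_dataset(coh, seed = 6)$train))

  st <- split_dataset(coh, seed = 4, stratify = TRUE)
  expect_equal(sort(c(st$train, st$validation, st$test)), seq_len(nrow(coh)))
  # stratified: every subset keeps both classes
  for (g in c("train", "validation", "test")) {
    expect_setequal(unique(coh$frail[st[[g]]]), c(0, 1))
  }

  expect_error(split_dataset(coh[1:3, ]), "empty")
  incomplete <- coh
  incomplete$TFI11[1] <- NA
  expect_error(split_dataset(incomplete), "complete-case")
  expect_error(split_dataset(coh, fractions = c(0.5, 0.5, 0.2)), "fractions")
})

test_that("split JSON round-trips", {
  coh <- make_complete_cohort(n = 60, seed = 1)
  sp <- split_dataset(coh, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  back <- read_split(path)
  expect_equal(back$train, sp$train)
  expect_equal(back$test, sp$test)
  expect_equal(back$seed, sp$seed)
})

test_that("positive-response profile computes within-class means and abs differences", {
  # construct a cohort whose class means are exactly the reported examples:
  # frail 100 records (61 positive on TFI17, 31 on TFI23),
  # non-frail 100 records (7 positive on TFI17, 16 on TFI23)
  n <- 200
  X <- as.data.frame(matrix(0L, n, 15))
  names(X) <- tfi_items()
  frail <- rep(c(1L, 0L), each = 100)
  X$TFI17 <- c(rep(1L, 61), rep(0L, 39), rep(1L, 7), rep(0L, 93))
  X$TFI23 <- c(rep(1L, 31), rep(0L, 69), rep(1L, 16), rep(0L, 84))
  coh <- cbind(record_id = sprintf("P%03d", 1:n), X, frail = frail)
  prof <- positive_response_profile(coh)
  expect_equal(prof$item_id, tfi_items())
  t17 <- prof[prof$item_id == "TFI17", ]
  expect_equal(c(t17$mean_frail, t17$mean_nonfrail, t17$abs_difference),
               c(0.61, 0.07, 0.54))
  t23 <- prof[prof$item_id == "TFI23", ]
  expect_equal(c(t23$mean_frail, t23$mean_nonfrail, t23$abs_difference),
               c(0.31, 0.16, 0.15))
  # identical class means give zero difference
  t11 <- prof[prof$item_id == "TFI11", ]
  expect_equal(t11$abs_difference, 0)
  expect_true(all(prof$abs_difference >= 0 & prof$abs_difference <= 1))

  single <- coh[coh$frail == 1, ]
  expect_error(positive_response_profile(single), "non-frail")
})

test_that("large-sample profile recovers the generating probabilities", {
  spec <- cohort_spec(n = 8000, missing_rate = 0, seed = 19)
  coh <- generate_cohort(spec)
  prof <- positive_response_profile(coh)
  n_frail <- sum(coh$frail == 1)
  n_nonfrail <- sum(coh$frail == 0)
  for (pr in spec$profiles) {
    row <- prof[prof$item_id == pr$item_id, ]
    # 4 binomial SDs, the generator's stated moment-match contract
    expect_lt(abs(row$mean_frail - pr$p_frail),
              4 * sqrt(pr$p_frail * (1 - pr$p_frail) / n_frail))
    expect_lt(abs(row$mean_nonfrail - pr$p_nonfrail),
              4 * sqrt(pr$p_nonfrail * (1 - pr$p_nonfrail) / n_nonfrail))
  }
})

test_that("cohort summary reports per-class counts and percentages", {
  coh <- generate_cohort(cohort_spec(n = 666, prevalence = 562 / 666,
                                     missing_rate = 0, seed = 77))
  # force the exact study composition for the headline share
  coh$frail <- c(rep(1L, 562), rep(0L, 104))
  s <- summarize_cohort(coh)
  fr <- s$counts[s$counts$characteristic == "frailty" &
                   s$counts$group == "total", ]
  expect_equal(fr$pct[fr$category == "frail"], 84.4)
  expect_equal(fr$pct[fr$category == "nonfrail"], 15.6)
  expect_equal(sum(fr$n), 666)
  # percentages within a block and group sum to ~100
  sex <- s$counts[s$counts$characteristic == "sex" &
                    s$counts$group == "frail", ]
  expect_equal(sum(sex$n), 562)
  expect_lt(abs(sum(sex$pct) - 100), 0.2)
  expect_equal(nrow(s$age), 3)

  # cohort without demographic fields: only the frailty block, no zero rows
  bare <- coh[, c("record_id", tfi_items(), "frail")]
  sb <- summarize_cohort(bare)
  expect_setequal(unique(sb$counts$characteristic), "frailty")
  expect_true(all(sb$counts$n > 0))
  expect_null(sb$age)
})
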