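# Complete-case filtering, randomized train/validation/test split, and
# cohort-level descriptive summaries.

#' Drop records with any missing TFI item
#'
#' Complete-case filtering: only records with all 15 items present are kept,
#' in their original order.  Frailty labels are never missing by contract, so
#' completeness is decided on the items alone.
#'
#' @param cohort A `tfi_cohort`.
#' @return The complete-case cohort.  Errors if no complete record remains,
#'   since the downstream split would be undefined.
#' @export
drop_incomplete <- function(cohort) {
  validate_cohort(cohort)
  keep <- stats::complete.cases(cohort[, tfi_items()])
  if (!any(keep)) {
    stop("no complete-case records remain after dropping missing items",
         call. = FALSE)
  }
  cohort[keep, , drop = FALSE]
}

#' Randomized train/validation/test split
#'
#' Splits a complete-case cohort into train, validation and test subsets
#' (default fractions 4/6, 1/6, 1/6).  The train size is
#' `round(f_train * n)`; validation and test partition the remainder as
#' evenly as possible, with any odd record going to validation.  Returned
#' indices are 1-based row positions into the cohort.
#'
#' @param cohort A complete-case `tfi_cohort`.
#' @param fractions Positive numeric triple summing to 1.
#' @param seed Integer seed for the randomized assignment.
#' @param stratify Logical; if `TRUE`, the random assignment is performed
#'   within each frailty class, so the class balance is preserved across
#'   subsets.  Default `FALSE` (simple random split).
#' @return An object of class `tfi_split`: a list with integer index vectors
#'   `train`, `validation`, `test`, plus `seed` and `fractions`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 612, missing_rate = 0, seed = 7))
#' sp <- split_dataset(coh, seed = 7)
#' lengths(sp[c("train", "validation", "test")]) # 408, 102, 102
split_dataset <- function(cohort, fractions = c(4, 1, 1) / 6, seed = 1L,
                          stratify = FALSE) {
  validate_cohort(cohort)
  if (anyNA(cohort[, tfi_items()])) {
    stop("cohort must be complete-case; call drop_incomplete() first",
         call. = FALSE)
  }
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be a positive triple summing to 1", call. = FALSE)
  }
  n <- nrow(cohort)
  sizes <- split_sizes(n, fractions)
  if (any(sizes == 0)) {
    stop("split would produce an empty subset (n = ", n, ")", call. = FALSE)
  }
  assign_groups <- function(idx) {
    s <- split_sizes(length(idx), fractions)
    shuffled <- sample(idx)
    list(train = shuffled[seq_len(s[1])],
         validation = shuffled[s[1] + seq_len(s[2])],
         test = shuffled[s[1] + s[2] + seq_len(s[3])])
  }
  parts <- with_seed(seed, {
    if (stratify) {
      by_class <- lapply(c(0L, 1L), function(cl) {
        assign_groups(which(cohort$frail == cl))
      })
      list(train = c(by_class[[1]]$train, by_class[[2]]$train),
           validation = c(by_class[[1]]$validation, by_class[[2]]$validation),
           test = c(by_class[[1]]$test, by_class[[2]]$test))
    } else {
      assign_groups(seq_len(n))
    }
  })
  parts <- lapply(parts, function(x) sort(as.integer(x)))
  if (any(lengths(parts) == 0)) {
    stop("split would produce an empty subset", call. = FALSE)
  }
  structure(
    c(parts, list(seed = seed, fractions = fractions)),
    class = "tfi_split"
  )
}

# Deterministic subset sizes: train = round(f1 * n); validation takes the
# larger half of the remainder.
split_sizes <- function(n, fractions) {
  n_train <- round(fractions[1] * n)
  rest <- n - n_train
  n_val <- ceiling(rest * fractions[2] / (fractions[2] + fractions[3]))
  c(train = n_train, validation = n_val, test = rest - n_val)
}

#' Serialize / deserialize a split to JSON
#'
#' @param split A `tfi_split`.
#' @param path File path.
#' @return `write_split()` returns `path` invisibly; `read_split()` returns
#'   the `tfi_split`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "tfi_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$train <- as.integer(x$train)
  x$validation <- as.integer(x$validation)
  x$test <- as.integer(x$test)
  structure(x, class = "tfi_split")
}

#' Per-item positive-response profile by frailty class
#'
#' For each TFI item, the within-class fraction of responses coded 1 among
#' frail and non-frail participants, and the absolute difference between the
#' two.  The absolute difference is the informative scale because the three
#' reverse-coded items (TFI11, TFI22, TFI25) are deliberately left unrecoded,
#' so their class means order the other way round.
#'
#' @param cohort A `tfi_cohort` containing at least one record of each class.
#'   Missing item values are ignored item-wise.
#' @return Data frame with one row per item in TFI11..TFI25 order and columns
#'   `item_id`, `mean_frail`, `mean_nonfrail`, `abs_difference`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 2000, missing_rate = 0, seed = 3))
#' positive_response_profile(coh)
positive_response_profile <- function(cohort) {
  validate_cohort(cohort)
  classes <- c(frail = 1L, `non-frail` = 0L)
  for (nm in names(classes)) {
    if (!any(cohort$frail == classes[[nm]])) {
      stop("cohort contains no ", nm,
           " records; class means are undefined", call. = FALSE)
    }
  }
  frail <- cohort$frail == 1L
  rows <- lapply(tfi_items(), function(id) {
    mf <- mean(cohort[[id]][frail], na.rm = TRUE)
    mn <- mean(cohort[[id]][!frail], na.rm = TRUE)
    data.frame(item_id = id, mean_frail = mf, mean_nonfrail = mn,
               abs_difference = abs(mf - mn))
  })
  do.call(rbind, rows)
}

#' Sample-characteristics summary
#'
#' Per-class and total counts with percentages for each categorical
#' demographic (percentages against the column total), plus per-class mean
#' and SD of age.  The first block summarises the frailty label itself, so
#' e.g. 562 frail of 666 is reported as 84.4%.
#'
#' @param cohort A `tfi_cohort`.
#' @return A list of class `tfi_summary` with elements `counts` (long data
#'   frame: `characteristic`, `category`, `group`, `n`, `pct`) and `age`
#'   (data frame: `group`, `mean`, `sd`).  Zero-count categories are omitted.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  groups <- list(
    total = rep(TRUE, nrow(cohort)),
    frail = cohort$frail == 1L,
    nonfrail = cohort$frail == 0L
  )
  count_block <- function(characteristic, values) {
    out <- list()
    for (g in names(groups)) {
      sel <- values[groups[[g]]]
      denom <- sum(groups[[g]])
      if (denom == 0) next
      tab <- table(sel, useNA = "no")
      tab <- tab[tab > 0]
      if (length(tab) == 0) next
      out[[g]] <- data.frame(
        characteristic = characteristic,
        category = names(tab),
        group = g,
        n = as.integer(tab),
        pct = round(100 * as.integer(tab) / denom, 1)
      )
    }
    do.call(rbind, out)
  }
  blocks <- list(
    count_block("frailty", ifelse(cohort$frail == 1L, "frail", "nonfrail"))
  )
  for (ch in c("sex", "relationship", "education", "income_band",
               "diabetes", "hypertension")) {
    if (ch %in% names(cohort)) {
      blocks[[length(blocks) + 1L]] <- count_block(ch, cohort[[ch]])
    }
  }
  counts <- do.call(rbind, blocks)
  rownames(counts) <- NULL
  age <- NULL
  if ("age" %in% names(cohort)) {
    age <- do.call(rbind, lapply(names(groups), function(g) {
      sel <- cohort$age[groups[[g]]]
      if (length(sel) == 0) return(NULL)
      data.frame(group = g, mean = mean(sel, na.rm = TRUE),
                 sd = stats::sd(sel, na.rm = TRUE))
    }))
  }
  structure(list(counts = counts, age = age), class = "tfi_summary")
}
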