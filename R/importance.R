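# Permutation feature importance with a one-tailed z significance test.
#
# Importance is measured as the decrease in classification accuracy when one
# item column is randomly permuted within the evaluation subset (labels and
# all other columns untouched), repeated R times.  The z statistic is a
# one-sample z on the mean drop, z = mu * sqrt(R) / sigma, so it grows with
# the number of permutations; sigma itself is reported unscaled.  The
# standard deviation uses the population (divide-by-R) convention.

#' z statistic for a mean accuracy drop
#'
#' `z = mu * sqrt(R) / sigma`: the mean permutation accuracy drop divided by
#' its standard error over `R` permutations.
#'
#' @param mu Mean accuracy drop.
#' @param sigma Standard deviation of the drops (unscaled).
#' @param R Number of permutations.
#' @return The z value (vectorised).
#' @export
#' @examples
#' importance_z(0.082, 0.036, 10000) # about 227.8
importance_z <- function(mu, sigma, R) {
  mu * sqrt(R) / sigma
}

# Summary statistics for a drops vector, with the all-zero (feature unused)
# convention: z undefined, p = 1.
importance_stats <- function(drops) {
  R <- length(drops)
  mu <- mean(drops)
  sigma <- sqrt(mean((drops - mu)^2))
  zero <- all(drops == 0)
  if (zero) {
    z <- NA_real_
    p <- 1
  } else if (sigma == 0) {
    z <- sign(mu) * Inf
    p <- if (mu > 0) 0 else 1
  } else {
    z <- importance_z(mu, sigma, R)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(mu = mu, sigma = sigma, z = z, p_one_tailed = p,
       zero_importance = zero)
}

#' Permutation importance of one TFI item
#'
#' Computes the baseline accuracy of `model` on `data` once, then for each of
#' `R` repeats permutes the `feature` column within the subset, recomputes
#' accuracy, and records the drop (baseline minus permuted accuracy).
#' Features the model never consults give all-zero drops; these carry an
#' undefined z and `p_one_tailed = 1` rather than NaN.
#'
#' @param model A fitted `tfi_model`.
#' @param data Labelled evaluation data (typically the validation or test
#'   subset), complete-case.
#' @param feature One of `tfi_items()`.
#' @param R Number of permutations, at least 2.  Default 10000.
#' @param seed Integer seed for the permutations.
#' @param subset Label recorded in the result (e.g. `"validation"` or
#'   `"test"`); purely descriptive.
#' @return Object of class `tfi_importance`: list with `feature`, `subset`,
#'   `R`, `drops` (length-R vector), `mu`, `sigma`, `z`, `p_one_tailed`,
#'   `zero_importance`, `baseline_accuracy`.
#' @export
permutation_importance <- function(model, data, feature, R = 10000L,
                                   seed = 1L, subset = "test") {
  stopifnot(inherits(model, "tfi_model"))
  if (!is.numeric(R) || length(R) != 1L || R < 2) {
    stop("`R` must be at least 2 (the drop SD is undefined otherwise)",
         call. = FALSE)
  }
  R <- as.integer(R)
  if (!feature %in% tfi_items()) {
    stop("`feature` must be one of tfi_items()", call. = FALSE)
  }
  mf <- model_frame(data)
  n <- nrow(mf$X)
  bits <- pattern_bits(mf$X)
  baseline <- mean(table_predict(model, bits) == mf$y)

  j <- match(feature, tfi_items())
  xj <- mf$X[[feature]]
  weight <- 2^(j - 1L)
  base_bits <- bits - xj * weight

  drops <- with_seed(seed, {
    vapply(seq_len(R), function(r) {
      perm_bits <- base_bits + xj[sample.int(n)] * weight
      baseline - mean(table_predict(model, perm_bits) == mf$y)
    }, numeric(1))
  })

  st <- importance_stats(drops)
  structure(
    c(list(feature = feature, subset = subset, R = R, drops = drops,
           baseline_accuracy = baseline), st),
    class = "tfi_importance"
  )
}

#' Permutation importance of all 15 items
#'
#' One [permutation_importance()] result per item, all against the same
#' baseline and subset, ordered TFI11..TFI25.  Each feature uses an
#' independent permutation sub-stream derived from `seed`, so results do not
#' depend on evaluation order.
#'
#' @inheritParams permutation_importance
#' @return Data frame of class `tfi_importance_table` with columns `feature`,
#'   `subset`, `R`, `mu`, `sigma`, `z`, `p_one_tailed`, `zero_importance`;
#'   the full per-feature result objects (including drops) are in
#'   `attr(x, "results")`.
#' @export
importance_table <- function(model, data, R = 10000L, seed = 1L,
                             subset = "test") {
  results <- lapply(seq_along(tfi_items()), function(j) {
    permutation_importance(model, data, tfi_items()[j], R = R,
                           seed = sub_seed(seed, 100L + j), subset = subset)
  })
  names(results) <- tfi_items()
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(feature = r$feature, subset = r$subset, R = r$R, mu = r$mu,
               sigma = r$sigma, z = r$z, p_one_tailed = r$p_one_tailed,
               zero_importance = r$zero_importance)
  }))
  rownames(tab) <- NULL
  attr(tab, "results") <- results
  class(tab) <- c("tfi_importance_table", "data.frame")
  tab
}
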