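# Pairwise relative-importance inference: differences between mean drops,
# two-tailed z tests on pooled permutation variance, and Bonferroni-corrected
# comparison matrices.

#' Two-sample z for a difference of mean accuracy drops
#'
#' `z = (mu_a - mu_b) * sqrt(R) / sqrt(sigma_a^2 + sigma_b^2)`: an unpaired
#' two-sample z on the two importance distributions, with the pooled variance
#' scaled by 1/R.
#'
#' @param mu_a,sigma_a Mean and SD of feature a's drops.
#' @param mu_b,sigma_b Mean and SD of feature b's drops.
#' @param R Number of permutations (shared).
#' @return The z value (vectorised).
#' @export
#' @examples
#' pairwise_z(0.082, 0.036, 0.062, 0.025, 10000) # about 45.6
pairwise_z <- function(mu_a, sigma_a, mu_b, sigma_b, R) {
  (mu_a - mu_b) * sqrt(R) / sqrt(sigma_a^2 + sigma_b^2)
}

#' Bonferroni per-comparison threshold
#'
#' @param alpha Family-wise significance level in (0,1).
#' @param m Number of comparisons, at least 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 3)   # 0.0167 at four decimals
#' bonferroni_alpha(0.05, 105) # all pairs of 15 items
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0,1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("`m` must be at least 1", call. = FALSE)
  }
  alpha / m
}

#' Number of hypothesis-driven cross-domain comparisons
#'
#' The study design compares every psychosocial item against a set of
#' selected physical items, giving `|psychosocial| x |physical|` comparisons
#' (7 x 3 = 21 for the TFI psychosocial domain against walking difficulty,
#' hand strength and physical fatigue).
#'
#' @param psychosocial_items,physical_items Disjoint nonempty character
#'   vectors of item ids.
#' @return Integer count of pairwise comparisons.
#' @export
count_hypothesis_comparisons <- function(psychosocial_items, physical_items) {
  if (length(psychosocial_items) == 0 || length(physical_items) == 0) {
    stop("both item sets must be nonempty", call. = FALSE)
  }
  if (length(intersect(psychosocial_items, physical_items)) > 0) {
    stop("item sets must be disjoint", call. = FALSE)
  }
  length(psychosocial_items) * length(physical_items)
}

#' Compare the importance of two features
#'
#' Tests the difference `delta = mu_a - mu_b` between two permutation
#' importance distributions with the pooled two-sample z of [pairwise_z()]
#' and a two-tailed p-value.  A positive delta means feature a is
#' diagnostically more important.  If exactly one feature has undefined
#' (all-zero) importance, the other is declared more important whenever its
#' own one-tailed importance test clears `alpha_corrected`, mirroring how a
#' variable that never entered the model is dominated by every used
#' variable.
#'
#' @param a,b `tfi_importance` results computed with the same `R` on the
#'   same subset.
#' @param alpha_corrected Per-comparison significance threshold (typically
#'   from [bonferroni_alpha()]).
#' @return Object of class `tfi_pairwise`: list with `feature_a`,
#'   `feature_b`, `delta`, `z`, `p_two_tailed`, `alpha_corrected`,
#'   `significant`, `direction` (`"a"`, `"b"` or `NA` when not significant).
#' @export
pairwise_compare <- function(a, b, alpha_corrected = 0.05) {
  stopifnot(inherits(a, "tfi_importance"), inherits(b, "tfi_importance"))
  if (a$R != b$R) stop("results were computed with different R", call. = FALSE)
  if (!identical(a$subset, b$subset)) {
    stop("results come from different data subsets", call. = FALSE)
  }
  delta <- a$mu - b$mu
  denom <- sqrt(a$sigma^2 + b$sigma^2)
  if (denom == 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- pairwise_z(a$mu, a$sigma, b$mu, b$sigma, a$R)
  }
  p <- 2 * stats::pnorm(-abs(z))
  if (xor(a$zero_importance, b$zero_importance)) {
    used <- if (a$zero_importance) b else a
    significant <- used$p_one_tailed <= alpha_corrected
  } else {
    significant <- p <= alpha_corrected
  }
  direction <- if (!significant || delta == 0) {
    NA_character_
  } else if (delta > 0) "a" else "b"
  structure(
    list(feature_a = a$feature, feature_b = b$feature, delta = delta, z = z,
         p_two_tailed = p, alpha_corrected = alpha_corrected,
         significant = significant, direction = direction),
    class = "tfi_pairwise"
  )
}

#' Bonferroni-corrected matrix of relative importances
#'
#' Evaluates all k(k-1)/2 unordered feature pairs with [pairwise_compare()]
#' at the per-comparison threshold `bonferroni_alpha(alpha, m)`.  The delta
#' and z matrices are antisymmetric with zero diagonal; the significance
#' mask is symmetric and the diagonal is never significant.
#'
#' @param results A `tfi_importance_table` (from [importance_table()]) or a
#'   list of `tfi_importance` objects sharing model, subset and `R`.
#' @param alpha Family-wise level, default 0.05.
#' @param m Correction family size; default `choose(k, 2)` over the supplied
#'   features.  Configurable because the family may instead be the model's
#'   used-variable pairs or a hypothesis-driven subset.
#' @return Object of class `tfi_comparison`: list with `features`, matrices
#'   `delta`, `z`, `significant`, the long-form `pairs` data frame, `alpha`,
#'   `alpha_corrected`, `m`, `subset`, and `zero_importance_features`.
#' @export
comparison_matrix <- function(results, alpha = 0.05, m = NULL) {
  if (inherits(results, "tfi_importance_table")) {
    results <- attr(results, "results")
  }
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, logical(1), "tfi_importance")))
  feats <- vapply(results, `[[`, character(1), "feature")
  names(results) <- feats
  k <- length(feats)
  m <- m %||% choose(k, 2)
  alpha_c <- bonferroni_alpha(alpha, m)

  delta <- matrix(0, k, k, dimnames = list(feats, feats))
  zmat <- matrix(0, k, k, dimnames = list(feats, feats))
  sig <- matrix(FALSE, k, k, dimnames = list(feats, feats))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (jj in (i + 1):k) {
      pc <- pairwise_compare(results[[i]], results[[jj]], alpha_c)
      delta[i, jj] <- pc$delta
      delta[jj, i] <- -pc$delta
      zmat[i, jj] <- pc$z
      zmat[jj, i] <- -pc$z
      sig[i, jj] <- sig[jj, i] <- pc$significant
      pairs[[length(pairs) + 1L]] <- data.frame(
        feature_a = pc$feature_a, feature_b = pc$feature_b,
        delta = pc$delta, z = pc$z, p_two_tailed = pc$p_two_tailed,
        alpha_corrected = pc$alpha_corrected,
        significant = pc$significant,
        direction = if (is.na(pc$direction)) NA_character_ else
          if (pc$direction == "a") pc$feature_a else pc$feature_b
      )
    }
  }
  structure(
    list(features = feats, delta = delta, z = zmat, significant = sig,
         pairs = do.call(rbind, pairs), alpha = alpha,
         alpha_corrected = alpha_c, m = m,
         subset = results[[1]]$subset,
         zero_importance_features =
           feats[vapply(results, `[[`, logical(1), "zero_importance")]),
    class = "tfi_comparison"
  )
}
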