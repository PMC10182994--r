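# Shared fixtures, all generated in code.

# A small complete-case cohort with a few strongly informative items.
make_complete_cohort <- function(n = 300, prevalence = 0.5, seed = 101) {
  generate_cohort(cohort_spec(n = n, prevalence = prevalence,
                              missing_rate = 0, seed = seed))
}

# A cohort where exactly one item carries (strong) signal and the rest are
# pure class-independent noise.
one_signal_spec <- function(n = 1000, signal_item = "TFI17",
                            p_signal = c(0.95, 0.05), seed = 7,
                            prevalence = 0.5) {
  overrides <- stats::setNames(
    rep(list(c(0.3, 0.3)), 15), tfi_items()
  )
  overrides[[signal_item]] <- p_signal
  cohort_spec(n = n, prevalence = prevalence,
              profiles = default_profiles(overrides),
              missing_rate = 0, seed = seed)
}

# Deterministic toy frame where TFI13 equals the label and everything else
# alternates; perfectly separable.
separable_frame <- function(n = 60) {
  X <- as.data.frame(matrix(rep(c(0L, 1L), length.out = n * 15), n, 15))
  names(X) <- tfi_items()
  y <- rep(c(0L, 1L), length.out = n)
  X$TFI13 <- y
  X$frail <- y
  X$record_id <- sprintf("S%03d", seq_len(n))
  X
}

# Build a tfi_importance object directly from a drops vector (for formula
# and comparison tests that need controlled distributions).
importance_from_drops <- function(feature, drops, subset = "test") {
  st <- tfiperm:::importance_stats(drops)
  structure(
    c(list(feature = feature, subset = subset, R = length(drops),
           drops = drops, baseline_accuracy = NA_real_), st),
    class = "tfi_importance"
  )
}
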