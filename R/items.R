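# TFI item metadata and class-conditional response profiles.

#' The fifteen Tilburg Frailty Indicator item identifiers
#'
#' The TFI frailty-components part has 15 self-report items, conventionally
#' numbered TFI11 to TFI25: physical domain TFI11-TFI18, psychological domain
#' TFI19-TFI22, social domain TFI23-TFI25.
#'
#' @return Character vector of length 15, `"TFI11"` ... `"TFI25"`.
#' @export
#' @examples
#' tfi_items()
tfi_items <- function() paste0("TFI", 11:25)

#' TFI domain membership
#'
#' @return Named character vector mapping each item to `"physical"`,
#'   `"psychological"` or `"social"`.
#' @export
tfi_domains <- function() {
  stats::setNames(
    c(rep("physical", 8), rep("psychological", 4), rep("social", 3)),
    tfi_items()
  )
}

# Items phrased so that a "yes" indicates absence of a deficit.  They are
# deliberately left unrecoded, which is why downstream profile summaries use
# absolute differences.
reverse_coded_items <- function() c("TFI11", "TFI22", "TFI25")

#' Construct a class-conditional item response profile
#'
#' An `item_profile` holds, for one TFI item, the probability of a positive
#' (coded-1) response given frailty and given non-frailty, plus the
#' reverse-coding flag.  These pairs are the generative unit of the synthetic
#' cohort and the descriptive unit of the positive-response profile.
#'
#' @param item_id One of `tfi_items()`.
#' @param p_frail Probability in `[0,1]` of a positive response given frail.
#' @param p_nonfrail Probability in `[0,1]` given non-frail.
#' @param reverse_coded Logical; defaults to the standard TFI flag for the
#'   item (TRUE for TFI11, TFI22, TFI25).
#' @return An object of class `item_profile`.
#' @export
item_profile <- function(item_id, p_frail, p_nonfrail,
                         reverse_coded = item_id %in% reverse_coded_items()) {
  if (!is.character(item_id) || length(item_id) != 1L ||
      !item_id %in% tfi_items()) {
    stop("`item_id` must be one of tfi_items()", call. = FALSE)
  }
  stop_if_not_prob(p_frail, "p_frail")
  stop_if_not_prob(p_nonfrail, "p_nonfrail")
  structure(
    list(item_id = item_id, p_frail = p_frail, p_nonfrail = p_nonfrail,
         reverse_coded = isTRUE(reverse_coded)),
    class = "item_profile"
  )
}

#' Default class-conditional response profiles for the 15 TFI items
#'
#' Two pairs are the reference values reported in the motivating clinical
#' study of heart-failure patients: TFI17 (lack of hand strength) with
#' positive-response means 0.61 (frail) vs 0.07 (non-frail), and TFI23
#' (living alone) with 0.31 vs 0.16.  The remaining 13 pairs are
#' implementation defaults chosen to be clinically plausible: on
#' non-reverse-coded items the frail mean exceeds the non-frail mean, and on
#' the three reverse-coded items (TFI11, TFI22, TFI25, where "yes" signals
#' good function) the ordering is inverted.  All pairs can be overridden.
#'
#' @param overrides Optional named list mapping item ids to
#'   `c(p_frail, p_nonfrail)` pairs (or `item_profile` objects) replacing the
#'   defaults.
#' @return Named list of 15 `item_profile` objects in TFI11..TFI25 order.
#' @export
#' @examples
#' p <- default_profiles()
#' p$TFI17$p_frail    # 0.61
#' p$TFI23$p_nonfrail # 0.16
default_profiles <- function(overrides = NULL) {
  base <- list(
    TFI11 = c(0.25, 0.80), # feel physically healthy (reverse-coded)
    TFI12 = c(0.35, 0.15), # unintentional weight loss
    TFI13 = c(0.55, 0.20), # difficulty walking
    TFI14 = c(0.45, 0.15), # difficulty keeping balance
    TFI15 = c(0.40, 0.20), # poor hearing
    TFI16 = c(0.35, 0.18), # poor vision
    TFI17 = c(0.61, 0.07), # lack of strength in hands (reported pair)
    TFI18 = c(0.65, 0.25), # physical tiredness
    TFI19 = c(0.30, 0.15), # memory problems
    TFI20 = c(0.55, 0.12), # felt down last month
    TFI21 = c(0.50, 0.15), # felt nervous or anxious
    TFI22 = c(0.60, 0.85), # able to cope with problems (reverse-coded)
    TFI23 = c(0.31, 0.16), # living alone (reported pair)
    TFI24 = c(0.45, 0.25), # missing having people around
    TFI25 = c(0.70, 0.90)  # enough support from others (reverse-coded)
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% tfi_items())) {
      stop("`overrides` must be a named list keyed by TFI item ids",
           call. = FALSE)
    }
    for (id in names(overrides)) {
      ov <- overrides[[id]]
      base[[id]] <- if (inherits(ov, "item_profile")) {
        c(ov$p_frail, ov$p_nonfrail)
      } else {
        ov
      }
    }
  }
  out <- lapply(tfi_items(), function(id) {
    item_profile(id, base[[id]][1], base[[id]][2])
  })
  stats::setNames(out, tfi_items())
}

# Validate a profile list: 15 unique items covering TFI11..TFI25.
validate_profiles <- function(profiles) {
  if (length(profiles) != 15L ||
      !all(vapply(profiles, inherits, logical(1), "item_profile"))) {
    stop("`profiles` must be a list of 15 item_profile objects", call. = FALSE)
  }
  ids <- vapply(profiles, `[[`, character(1), "item_id")
  if (anyDuplicated(ids) || !setequal(ids, tfi_items())) {
    stop("profiles must cover TFI11..TFI25 with unique item_ids",
         call. = FALSE)
  }
  profiles[order(match(ids, tfi_items()))]
}
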