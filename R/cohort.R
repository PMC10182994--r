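# Synthetic TFI cohort generation and cohort CSV input/output.
#
# The generator emulates the structure of the motivating heart-failure study
# population: N = 666 with 562 frail (84.4%) and 104 non-frail, 15 binary TFI
# items drawn class-conditionally (Bernoulli), class-conditional demographics,
# and record-level missingness that reduces 666 records to about 612 complete
# cases.

#' Default class-conditional demographic model
#'
#' Parameters approximate the sample-characteristics table of the motivating
#' study: age means 72.88 (frail) / 67.68 (non-frail) with SDs 10.97 / 10.79,
#' and per-class category probabilities for sex, relationship status,
#' education, income band and comorbidities.  Demographics are generated but
#' never used by the classifiers (which see only the 15 items); they exist to
#' exercise sample-characteristics reporting.
#'
#' @return Named list of per-class parameters; each entry is a vector
#'   `c(frail = ..., nonfrail = ...)` or, for education, a 2-row matrix of
#'   category probabilities.
#' @export
default_demographics <- function() {
  list(
    age_mean = c(frail = 72.88, nonfrail = 67.68),
    age_sd = c(frail = 10.97, nonfrail = 10.79),
    p_male = c(frail = 0.525, nonfrail = 0.615),
    p_lonely = c(frail = 0.528, nonfrail = 0.365),
    p_education = rbind(
      frail = c(primary = 0.338, basic_vocational = 0.096,
                high_school = 0.430, university = 0.135),
      nonfrail = c(primary = 0.163, basic_vocational = 0.058,
                   high_school = 0.510, university = 0.269)
    ),
    p_income_high = c(frail = 0.210, nonfrail = 0.288),
    p_diabetes = c(frail = 0.446, nonfrail = 0.279),
    p_hypertension = c(frail = 0.786, nonfrail = 0.683)
  )
}

#' Specify a synthetic TFI cohort
#'
#' @param n Number of participants (>= 2, with at least one expected member
#'   per class).
#' @param prevalence Frail fraction in (0,1).  Default 562/666 (84.4%), the
#'   class balance of the motivating study.
#' @param profiles List of 15 [item_profile()] objects; default
#'   [default_profiles()].
#' @param missing_rate Record-level missingness probability in `[0,1)`: each
#'   record is independently selected with this probability to have one
#'   uniformly chosen item blanked.  Default 54/666, which gives an expected
#'   612 complete cases out of 666.
#' @param seed Integer master seed; label, item, demographic and missingness
#'   draws use independent sub-streams derived from it.
#' @param demographics Class-conditional demographic parameters; default
#'   [default_demographics()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 666L, prevalence = 562 / 666,
                        profiles = default_profiles(),
                        missing_rate = 54 / 666, seed = 1L,
                        demographics = default_demographics()) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n * prevalence < 1 || n * (1 - prevalence) < 1) {
    stop("`n` and `prevalence` must give at least one expected member per class",
         call. = FALSE)
  }
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0,1)", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence,
         profiles = validate_profiles(profiles),
         missing_rate = missing_rate, seed = seed,
         demographics = demographics),
    class = "cohort_spec"
  )
}

#' Generate a synthetic TFI cohort
#'
#' Each record's frailty label is drawn Bernoulli(prevalence); each item is
#' drawn independently Bernoulli with the class-conditional probability of
#' its profile; demographics come from the class-conditional models.  If
#' `spec$missing_rate > 0` the record-level missingness mechanism of
#' [inject_missingness()] is then applied with a seed derived from
#' `spec$seed`.  The same spec (including seed) always yields the identical
#' cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A `tfi_cohort`: a data frame with columns `record_id`,
#'   `TFI11`..`TFI25` (0/1, possibly `NA`), `frail` (0/1, never `NA`), and
#'   demographics (`age`, `sex`, `relationship`, `education`, `income_band`,
#'   `diabetes`, `hypertension`).  The generating spec is attached as
#'   attribute `spec_provenance`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 100, seed = 42))
#' table(coh$frail)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("`spec` must be a cohort_spec object", call. = FALSE)
  }
  n <- spec$n
  frail <- with_seed(sub_seed(spec$seed, 1L),
                     stats::rbinom(n, 1L, spec$prevalence))

  items <- with_seed(sub_seed(spec$seed, 2L), {
    cols <- lapply(spec$profiles, function(pr) {
      p <- ifelse(frail == 1L, pr$p_frail, pr$p_nonfrail)
      stats::rbinom(n, 1L, p)
    })
    stats::setNames(as.data.frame(cols), tfi_items())
  })

  dm <- spec$demographics
  cls <- ifelse(frail == 1L, "frail", "nonfrail")
  demo <- with_seed(sub_seed(spec$seed, 3L), {
    edu_levels <- colnames(dm$p_education)
    edu <- vapply(cls, function(cl) {
      sample(edu_levels, 1L, prob = dm$p_education[cl, ])
    }, character(1), USE.NAMES = FALSE)
    data.frame(
      age = round(stats::rnorm(n, dm$age_mean[cls], dm$age_sd[cls]), 1),
      sex = ifelse(stats::rbinom(n, 1L, dm$p_male[cls]) == 1L,
                   "male", "female"),
      relationship = ifelse(stats::rbinom(n, 1L, dm$p_lonely[cls]) == 1L,
                            "lonely", "in_relationship"),
      education = edu,
      income_band = ifelse(stats::rbinom(n, 1L, dm$p_income_high[cls]) == 1L,
                           "high", "low"),
      diabetes = stats::rbinom(n, 1L, dm$p_diabetes[cls]),
      hypertension = stats::rbinom(n, 1L, dm$p_hypertension[cls])
    )
  })

  cohort <- cbind(
    data.frame(record_id = sprintf("R%05d", seq_len(n))),
    items,
    data.frame(frail = frail),
    demo
  )
  class(cohort) <- c("tfi_cohort", "data.frame")
  attr(cohort, "spec_provenance") <- spec
  if (spec$missing_rate > 0) {
    cohort <- inject_missingness(cohort, spec$missing_rate,
                                 seed = sub_seed(spec$seed, 4L))
  }
  cohort
}

#' Blank one item in a random subset of records
#'
#' Implements record-level missing-completely-at-random: each record is
#' independently selected with probability `missing_rate`; a selected record
#' has exactly one uniformly chosen TFI item set to `NA`.  Frailty labels are
#' never blanked.
#'
#' @param cohort A `tfi_cohort` (or data frame with the cohort columns).
#' @param missing_rate Probability in `[0,1)`.
#' @param seed Integer seed.
#' @return The cohort with injected missing values; the input is unchanged.
#' @export
inject_missingness <- function(cohort, missing_rate, seed = 1L) {
  validate_cohort(cohort)
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0,1)", call. = FALSE)
  }
  if (missing_rate == 0) return(cohort)
  n <- nrow(cohort)
  with_seed(seed, {
    hit <- which(stats::runif(n) < missing_rate)
    which_item <- sample(tfi_items(), length(hit), replace = TRUE)
    for (i in seq_along(hit)) {
      cohort[hit[i], which_item[i]] <- NA_integer_
    }
  })
  cohort
}

# Minimal structural validation shared by all modules.
validate_cohort <- function(cohort) {
  required <- c("record_id", tfi_items(), "frail")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("cohort has no records", call. = FALSE)
  if (anyDuplicated(cohort$record_id)) {
    stop("cohort record_ids must be unique", call. = FALSE)
  }
  if (anyNA(cohort$frail)) {
    stop("`frail` labels must never be missing", call. = FALSE)
  }
  if (!all(cohort$frail %in% c(0L, 1L))) {
    stop("`frail` must be coded 0/1", call. = FALSE)
  }
  it <- as.matrix(cohort[, tfi_items()])
  if (!all(it %in% c(0L, 1L, NA))) {
    stop("every present item value must be exactly 0 or 1", call. = FALSE)
  }
  invisible(cohort)
}

#' Write / read a cohort CSV
#'
#' One row per record, header required, missing items written as empty
#' fields, UTF-8.
#'
#' @param cohort A `tfi_cohort`.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a validated `tfi_cohort` with `spec_provenance = "external"`.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8",
                        colClasses = c(record_id = "character"))
  validate_cohort(df)
  for (id in tfi_items()) df[[id]] <- as.integer(df[[id]])
  df$frail <- as.integer(df$frail)
  class(df) <- c("tfi_cohort", "data.frame")
  attr(df, "spec_provenance") <- "external"
  df
}
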