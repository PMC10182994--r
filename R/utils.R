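# Internal helpers: scoped RNG and derived sub-seeds.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' package functions never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive an independent sub-stream seed from a master seed.  Keeps results
# reproducible from a single top-level seed while decoupling the label, item,
# demographic and missingness draws.  Always < 2^31.
sub_seed <- function(seed, k) {
  ((as.numeric(seed) %% 195225786) * 11 + k * 7919 + 13) %% 2147483647
}

stop_if_not_prob <- function(x, name, allow_one = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(if (allow_one) x <= 1 else x < 1)
  if (!ok) {
    stop(sprintf("`%s` must be a probability in [0,%s]", name,
                 if (allow_one) "1" else "1)"), call. = FALSE)
  }
  invisible(x)
}
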