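# Reserved (non-feature) columns of a cohort tibble, in canonical order.
COHORT_RESERVED <- c("id", "fall_label", "provenance", "split")

FALL_LABELS <- c("non_faller", "faller")
PROVENANCES <- c("real", "synthetic")
SPLITS <- c("train", "validation", "test", "unassigned")
STRATA <- c("low", "medium", "high")
DIRECTIONS <- c("higher_is_riskier", "lower_is_riskier")

#' Names of the feature columns of a cohort
#'
#' A cohort tibble carries four reserved columns (`id`, `fall_label`,
#' `provenance`, `split`); every other column is a feature.
#'
#' @param cohort A cohort tibble.
#' @return Character vector of feature column names, in column order.
#' @export
feature_names <- function(cohort) {
  setdiff(names(cohort), COHORT_RESERVED)
}

#' Ordered risk stratum factor
#'
#' Builds the ordered factor `low < medium < high` used throughout the
#' package for risk strata.
#'
#' @param x Character vector of stratum names (subset of
#'   `"low"`, `"medium"`, `"high"`).
#' @return An ordered factor with levels `low < medium < high`.
#' @export
stratum_factor <- function(x = character()) {
  bad <- setdiff(unique(as.character(x)), c(STRATA, NA))
  if (length(bad) > 0) {
    abort(paste0("unknown stratum value(s): ", paste(bad, collapse = ", ")))
  }
  factor(as.character(x), levels = STRATA, ordered = TRUE)
}

# Spawn `n` independent substream seeds from one master seed without
# disturbing the caller's RNG state. Seeds stay below 2^31.
spawn_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

assert_cohort <- function(cohort, arg = "cohort") {
  if (!is.data.frame(cohort)) {
    abort(paste0("`", arg, "` must be a data frame"))
  }
  missing <- setdiff(COHORT_RESERVED, names(cohort))
  if (length(missing) > 0) {
    abort(paste0(
      "`", arg, "` is missing reserved column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(cohort)
}
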