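#' Assign a single feature value to a risk stratum
#'
#' Applies one threshold rule. Boundary values belong to the extreme
#' strata (closed extreme intervals, open medium interval): for a
#' `higher_is_riskier` rule, `value <= threshold_low` is low and
#' `value >= threshold_high` is high; mirrored for `lower_is_riskier`.
#' Every finite value maps to exactly one stratum. In the degenerate case
#' of equal thresholds the high stratum takes precedence, consistent with
#' the pipeline's resolve-to-higher-risk convention.
#'
#' @param value Numeric vector of feature values (finite).
#' @param direction `"higher_is_riskier"` or `"lower_is_riskier"`.
#' @param threshold_low Boundary value of the low stratum.
#' @param threshold_high Boundary value of the high stratum.
#' @return Ordered factor of strata (`low < medium < high`), same length
#'   as `value`.
#' @export
assign_feature_stratum <- function(value, direction, threshold_low, threshold_high) {
  if (!all(is.finite(value))) abort("feature values must be finite to be stratified")
  if (!direction %in% DIRECTIONS) abort(paste0("invalid direction: ", direction))
  out <- rep("medium", length(value))
  if (direction == "higher_is_riskier") {
    out[value <= threshold_low] <- "low"
    out[value >= threshold_high] <- "high"
  } else {
    out[value >= threshold_low] <- "low"
    out[value <= threshold_high] <- "high"
  }
  stratum_factor(out)
}

#' Combine per-feature strata by the mode
#'
#' Returns the most frequent stratum; when several strata tie for the
#' highest frequency the highest-risk tied stratum wins (medium over low,
#' high over medium; a three-way tie gives high).
#'
#' @param strata Nonempty vector of strata (character or stratum factor).
#' @return A length-1 ordered stratum factor.
#' @export
combine_strata <- function(strata) {
  if (length(strata) == 0) abort("cannot combine an empty stratum list")
  s <- stratum_factor(as.character(strata))
  counts <- table(s)
  top <- names(counts)[counts == max(counts)]
  stratum_factor(STRATA[max(match(top, STRATA))])
}

#' Classify subjects with a risk scale
#'
#' Per subject, each scale feature value is mapped to a preliminary
#' stratum by its rule ([assign_feature_stratum()]); the final stratum is
#' the mode of the preliminary assignments with ties resolved to higher
#' risk ([combine_strata()]).
#'
#' @param cohort Cohort tibble of the subjects to classify (any split).
#' @param scale A `risk_scale` tibble.
#' @param min_features Minimum number of scale features a subject must
#'   carry; defaults to all of them (complete records required). Setting
#'   a smaller value permits classification over the available features.
#' @return A tibble with `id`, `fall_label`, one ordered-factor column
#'   per scale feature, `final` and `n_features_used`.
#' @export
classify_patients <- function(cohort, scale, min_features = NULL) {
  assert_cohort(cohort)
  feats <- scale$feature
  present <- intersect(feats, names(cohort))
  missing <- setdiff(feats, names(cohort))
  need <- min_features %||% length(feats)
  if (length(present) < need) {
    abort(paste0(
      "cohort carries ", length(present), " of ", length(feats),
      " scale features but ", need, " are required; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (length(missing) > 0) {
    inform(paste0("classifying over ", length(present),
                  " available scale features; missing: ",
                  paste(missing, collapse = ", ")))
  }
  rules <- scale[scale$feature %in% present, ]
  per_feature <- purrr::pmap(
    rules[, c("feature", "direction", "threshold_low", "threshold_high")],
    function(feature, direction, threshold_low, threshold_high) {
      assign_feature_stratum(cohort[[feature]], direction,
                             threshold_low, threshold_high)
    }
  )
  names(per_feature) <- rules$feature
  mat <- do.call(cbind, purrr::map(per_feature, as.character))
  final <- apply(mat, 1, function(r) as.character(combine_strata(r)))
  out <- tibble(id = cohort$id, fall_label = cohort$fall_label)
  for (f in rules$feature) out[[f]] <- per_feature[[f]]
  out$final <- stratum_factor(final)
  out$n_features_used <- length(present)
  out
}

#' Literature threshold rules for the clinical comparator scales
#'
#' Loads the bundled three-stratum rules for the eight single-feature
#' clinical comparators (Mini-BESTest, FIM total and motor, POMA-B, TUG
#' total duration, FES-I, Conley, 10-metre walk speed). The thresholds
#' are literature constants shipped as an editable CSV fixture in
#' `inst/extdata/clinical_rules.csv`; each rule maps a score to
#' low/medium/high with boundary values in the extreme strata.
#'
#' @param path Optional path to an alternative rules CSV with columns
#'   `scale`, `feature`, `direction`, `threshold_low`, `threshold_high`,
#'   `reference`.
#' @return A tibble of clinical rules.
#' @export
clinical_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "clinical_rules.csv",
                                package = "fallrisk", mustWork = TRUE)
  rules <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             scale = "c", feature = "c", direction = "c",
                             threshold_low = "d", threshold_high = "d",
                             reference = "c"
                           ))
  bad <- setdiff(rules$direction, DIRECTIONS)
  if (length(bad) > 0) abort(paste0("invalid direction in rules file: ", bad))
  rules
}

#' Stratify subjects with the clinical comparator scales
#'
#' Each clinical scale is a single-feature rule evaluated independently.
#' Scales whose feature is absent from the cohort are skipped with a
#' message rather than failing the whole call.
#'
#' @param cohort Cohort tibble carrying the clinical feature columns.
#' @param rules Clinical rules tibble (default [clinical_rules()]).
#' @return A long tibble: `id`, `fall_label`, `scale`, `stratum`.
#' @export
clinical_stratify <- function(cohort, rules = clinical_rules()) {
  assert_cohort(cohort)
  out <- purrr::pmap_dfr(
    rules[, c("scale", "feature", "direction", "threshold_low", "threshold_high")],
    function(scale, feature, direction, threshold_low, threshold_high) {
      if (!feature %in% names(cohort)) {
        inform(paste0("skipping clinical scale '", scale,
                      "': feature '", feature, "' not in cohort"))
        return(NULL)
      }
      tibble(
        id = cohort$id,
        fall_label = cohort$fall_label,
        scale = scale,
        stratum = assign_feature_stratum(cohort[[feature]], direction,
                                         threshold_low, threshold_high)
      )
    }
  )
  out
}
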