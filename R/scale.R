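#' Infer the risk direction of a feature
#'
#' Returns the registry hint when one is recorded; otherwise compares the
#' training group means: the direction is `higher_is_riskier` iff the
#' faller mean exceeds the non-faller mean, `lower_is_riskier` otherwise.
#' An exact tie resolves to `higher_is_riskier` with a warning.
#'
#' @param train Training-split cohort tibble with both labels present.
#' @param feature Feature name.
#' @param hint Optional direction (`"higher_is_riskier"` or
#'   `"lower_is_riskier"`), typically the registry's `direction_hint`.
#' @return One of `"higher_is_riskier"`, `"lower_is_riskier"`.
#' @export
infer_direction <- function(train, feature, hint = NULL) {
  if (!is.null(hint) && !is.na(hint)) {
    if (!hint %in% DIRECTIONS) abort(paste0("invalid direction hint: ", hint))
    return(hint)
  }
  assert_cohort(train, "train")
  if (!feature %in% names(train)) abort(paste0("unknown feature: ", feature))
  v <- train[[feature]]
  m_f <- mean(v[train$fall_label == "faller"])
  m_n <- mean(v[train$fall_label == "non_faller"])
  if (is.na(m_f) || is.na(m_n)) abort(paste0("both labels must be present to infer a direction for ", feature))
  if (m_f == m_n) {
    warn(paste0("group means tie exactly for '", feature,
                "'; defaulting to higher_is_riskier"))
    return("higher_is_riskier")
  }
  if (m_f > m_n) "higher_is_riskier" else "lower_is_riskier"
}

#' Tertile thresholds of a feature over the training split
#'
#' Sorts the n training values in risk-increasing order (ascending for
#' `higher_is_riskier`, descending for `lower_is_riskier`) and stores the
#' observed values at ranks `ceiling(n/3)` and `ceiling(2n/3)` — for
#' n = 93, the 31st and 62nd ranked subjects — as the boundaries of the
#' low and high strata. Thresholds are always actual training values,
#' never interpolated.
#'
#' @inheritParams infer_direction
#' @param direction Risk direction of the feature.
#' @return A one-row tibble: `feature`, `direction`, `threshold_low`
#'   (boundary of the low stratum), `threshold_high` (boundary of the
#'   high stratum), `n_train`.
#' @export
derive_thresholds <- function(train, feature, direction = c("higher_is_riskier", "lower_is_riskier")) {
  direction <- match.arg(direction)
  assert_cohort(train, "train")
  if (!feature %in% names(train)) abort(paste0("unknown feature: ", feature))
  v <- train[[feature]]
  n <- length(v)
  if (n < 3) abort("at least 3 training subjects are needed to place tertile cuts")
  ranked <- sort(v, decreasing = (direction == "lower_is_riskier"))
  k1 <- ceiling(n / 3)
  k2 <- ceiling(2 * n / 3)
  tibble(
    feature = feature,
    direction = direction,
    threshold_low = ranked[k1],
    threshold_high = ranked[k2],
    n_train = n
  )
}

#' Build a three-stratum risk scale from a selection result
#'
#' Assembles one threshold rule per selected feature: the risk direction
#' via [infer_direction()] (registry hints take precedence) and the
#' tertile cut-points via [derive_thresholds()]. Rules are ordered by
#' descending selection fraction — the scale's "discerning power" order —
#' with lexicographic tie-break on the feature name.
#'
#' @param train Training-split cohort tibble.
#' @param selection A `fallrisk_selection` object from [run_selection()],
#'   or a tibble with columns `feature` and `fraction` listing the
#'   features to include.
#' @param registry Optional registry tibble supplying `direction_hint`s;
#'   defaults to the registry attached to `train`.
#' @return A `risk_scale` tibble: `feature`, `direction`,
#'   `threshold_low`, `threshold_high`, `selection_fraction`, with the
#'   training size in attribute `"training_size"`.
#' @export
build_scale <- function(train, selection, registry = NULL) {
  assert_cohort(train, "train")
  registry <- registry %||% attr(train, "registry", exact = TRUE)
  if (inherits(selection, "fallrisk_selection")) {
    sel <- dplyr::filter(selection$counts,
                         .data$feature %in% selection$selected_features)
  } else {
    sel <- as_tibble(selection)
    if (!all(c("feature", "fraction") %in% names(sel))) {
      abort("selection must be a fallrisk_selection or a tibble with columns feature, fraction")
    }
  }
  if (nrow(sel) == 0) abort("no selected features: cannot build a scale")
  sel <- dplyr::arrange(sel, dplyr::desc(.data$fraction), .data$feature)
  hints <- if (!is.null(registry)) {
    setNames(registry$direction_hint, registry$name)
  } else {
    NULL
  }
  rules <- purrr::map2_dfr(sel$feature, sel$fraction, function(f, frac) {
    dir <- infer_direction(train, f, hint = hints[[f]] %||% NULL)
    r <- derive_thresholds(train, f, dir)
    r$selection_fraction <- frac
    r
  })
  rules$n_train <- NULL
  out <- as_tibble(rules)
  attr(out, "training_size") <- nrow(train)
  class(out) <- c("risk_scale", class(out))
  out
}

#' @export
print.risk_scale <- function(x, ...) {
  cat(sprintf("Three-stratum risk scale: %d feature rule(s), trained on %s subjects\n",
              nrow(x), attr(x, "training_size") %||% "?"))
  NextMethod()
}

#' Render a scale as a human-readable threshold table
#'
#' Formats each rule as the three printed intervals of the scale layout
#' (low / medium / high risk) plus the selection percentage.
#'
#' @param scale A `risk_scale` tibble.
#' @return A tibble with columns `feature`, `low_risk`, `medium_risk`,
#'   `high_risk`, `pct_selections`.
#' @export
scale_table <- function(scale) {
  fmt <- function(v) format(v, digits = 4, trim = TRUE)
  purrr::pmap_dfr(
    scale[, c("feature", "direction", "threshold_low", "threshold_high",
              "selection_fraction")],
    function(feature, direction, threshold_low, threshold_high, selection_fraction) {
      if (direction == "lower_is_riskier") {
        tibble(
          feature = feature,
          low_risk = paste0("x >= ", fmt(threshold_low)),
          medium_risk = paste0(fmt(threshold_high), " < x < ", fmt(threshold_low)),
          high_risk = paste0("x <= ", fmt(threshold_high)),
          pct_selections = paste0(round(100 * selection_fraction), "%")
        )
      } else {
        tibble(
          feature = feature,
          low_risk = paste0("x <= ", fmt(threshold_low)),
          medium_risk = paste0(fmt(threshold_low), " < x < ", fmt(threshold_high)),
          high_risk = paste0("x >= ", fmt(threshold_high)),
          pct_selections = paste0(round(100 * selection_fraction), "%")
        )
      }
    }
  )
}

#' Serialize / deserialize a risk scale as JSON
#'
#' @param scale A `risk_scale` tibble.
#' @param path Destination (or source) JSON path.
#' @return `write_scale()` returns `path` invisibly; `read_scale()`
#'   returns the `risk_scale` tibble.
#' @export
write_scale <- function(scale, path) {
  payload <- list(
    training_size = attr(scale, "training_size"),
    rules = as_tibble(scale)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(payload$rules)
  attr(out, "training_size") <- payload$training_size
  class(out) <- c("risk_scale", class(out))
  out
}

#' @describeIn build_scale Plot each rule's medium-risk band on the
#'   feature's value axis, ordered by selection fraction.
#' @param object A `risk_scale` tibble.
#' @param ... Unused.
#' @method autoplot risk_scale
#' @export
autoplot.risk_scale <- function(object, ...) {
  d <- as_tibble(object)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  d$lo <- pmin(d$threshold_low, d$threshold_high)
  d$hi <- pmax(d$threshold_low, d$threshold_high)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$feature)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                         colour = .data$direction),
                            linewidth = 2, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$threshold_low), shape = "|", size = 4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$threshold_high), shape = "|", size = 4) +
    ggplot2::labs(x = "feature value (medium-risk band between tertile cuts)",
                  y = NULL, colour = NULL,
                  title = "Risk-scale threshold rules") +
    ggplot2::theme_minimal()
}
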