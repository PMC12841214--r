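#' Draw one balanced training subset
#'
#' A subset keeps every training faller fixed and draws
#' `subset_nonfallers` non-fallers uniformly without replacement, giving a
#' label-balanced subsample when `subset_nonfallers` equals the faller
#' count (the default).
#'
#' @param train Training-split cohort tibble.
#' @param subset_nonfallers Number of non-fallers per subset; defaults to
#'   the number of training fallers.
#' @param seed Master seed.
#' @param draw_index 1-based index of the draw; together with `seed` it
#'   fully determines the subset, independent of execution order.
#' @param n_draws Total number of distinct subsets the caller intends to
#'   draw; used for the feasibility check against the combinatorial bound.
#' @return Character vector of subject ids (all fallers first).
#' @export
sample_balanced_subset <- function(train, subset_nonfallers = NULL, seed = 1L,
                                   draw_index = 1L, n_draws = draw_index) {
  assert_cohort(train, "train")
  fallers <- train$id[train$fall_label == "faller"]
  nonfallers <- train$id[train$fall_label == "non_faller"]
  k <- subset_nonfallers %||% length(fallers)
  if (k > length(nonfallers)) {
    abort(paste0("subset_nonfallers = ", k, " but only ",
                 length(nonfallers), " training non-fallers available"))
  }
  n_possible <- choose(length(nonfallers), k)
  if (n_draws > n_possible) {
    abort(paste0(
      "cannot draw ", n_draws, " distinct subsets: only choose(",
      length(nonfallers), ", ", k, ") = ", format(n_possible, big.mark = ","),
      " non-faller combinations exist"
    ))
  }
  s <- spawn_seeds(seed, draw_index)[draw_index]
  drawn <- with_seed(s, nonfallers[sample.int(length(nonfallers), k)])
  c(fallers, drawn)
}

subset_fingerprint <- function(train, ids) {
  nf <- sort(intersect(ids, train$id[train$fall_label == "non_faller"]))
  paste(nf, collapse = "|")
}

#' Accuracy of the SVM gate for one subset
#'
#' Trains a radial-basis-function support-vector machine on the subset
#' (features standardized to zero mean / unit SD using subset statistics;
#' the same transform applied to the validation split) and returns plain
#' classification accuracy on the validation split. The caller retains
#' the subset iff the accuracy strictly exceeds the gate.
#'
#' @param subset Cohort tibble of the training subset.
#' @param validation Validation-split cohort tibble (disjoint from
#'   `subset`).
#' @param cost SVM regularization constant (default 1); the kernel width
#'   is the e1071 default `1 / n_features` on standardized data.
#' @return Accuracy in `[0, 1]`.
#' @export
gate_subset <- function(subset, validation, cost = 1) {
  assert_cohort(subset, "subset")
  assert_cohort(validation, "validation")
  if (nrow(validation) == 0) abort("validation split is empty")
  feats <- feature_names(subset)
  xs <- as.matrix(subset[, feats])
  xv <- as.matrix(validation[, feats, drop = FALSE])
  mu <- colMeans(xs)
  sdv <- apply(xs, 2, sd)
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero)) {
    warn(paste0("feature(s) with zero SD in subset standardized to zero: ",
                paste(feats[zero], collapse = ", ")))
    sdv[zero] <- 1
    # centring by mu maps the constant column to exactly zero
  }
  xs <- sweep(sweep(xs, 2, mu), 2, sdv, "/")
  xv <- sweep(sweep(xv, 2, mu), 2, sdv, "/")
  y <- factor(subset$fall_label, levels = FALL_LABELS)
  fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, scale = FALSE)
  pred <- stats::predict(fit, xv)
  mean(as.character(pred) == validation$fall_label)
}

#' Mark the features that separate fallers from non-fallers in a subset
#'
#' Per feature, Shapiro-Wilk normality is tested separately in the faller
#' and non-faller groups. When both groups are compatible with normality
#' at `alpha_normality`, the groups are compared with a two-sided Welch
#' t-test; otherwise with a two-sided Wilcoxon rank-sum test. A feature is
#' marked relevant iff the comparison p-value is below `alpha_relevance`.
#' Features constant within both groups are never marked (the tests are
#' undefined); a group that is constant on its own routes to the rank-sum
#' branch.
#'
#' @param subset Cohort tibble with at least 3 subjects per label.
#' @param alpha_relevance Significance level of the group comparison
#'   (default 0.05).
#' @param alpha_normality Significance level of the Shapiro-Wilk routing
#'   test (default 0.05).
#' @return Character vector of feature names marked relevant.
#' @export
mark_relevant <- function(subset, alpha_relevance = 0.05, alpha_normality = 0.05) {
  assert_cohort(subset, "subset")
  is_f <- subset$fall_label == "faller"
  if (sum(is_f) < 3 || sum(!is_f) < 3) {
    abort("mark_relevant needs at least 3 subjects per label")
  }
  feats <- feature_names(subset)
  marked <- vapply(feats, function(f) {
    a <- subset[[f]][is_f]
    b <- subset[[f]][!is_f]
    p <- group_test_p(a, b, alpha_normality)
    !is.na(p) && p < alpha_relevance
  }, logical(1))
  feats[marked]
}

# Normality-routed two-group comparison; NA when the test is undefined
# (both groups constant).
group_test_p <- function(a, b, alpha_normality) {
  const_a <- length(unique(a)) == 1
  const_b <- length(unique(b)) == 1
  if (const_a && const_b) return(NA_real_)
  normal_a <- !const_a && shapiro.test(a)$p.value > alpha_normality
  normal_b <- !const_b && shapiro.test(b)$p.value > alpha_normality
  if (normal_a && normal_b) {
    t.test(a, b, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
}

#' Consensus feature selection over repeated balanced subsets
#'
#' Runs the full selection loop: `n_iterations` distinct balanced
#' training subsets are drawn ([sample_balanced_subset()]); each subset
#' is gated by SVM validation accuracy ([gate_subset()], retained iff
#' accuracy strictly exceeds `accuracy_gate`); in retained subsets every
#' feature is tested for group separation ([mark_relevant()]). Features
#' marked relevant in at least `consensus_fraction` of the consensus
#' denominator (all iterations by default) are selected, ordered by descending
#' relevance count with lexicographic tie-break.
#'
#' @inheritParams sample_balanced_subset
#' @inheritParams mark_relevant
#' @param validation Validation-split cohort tibble.
#' @param n_iterations Number of distinct subsets to draw (default 1000).
#' @param accuracy_gate Retention threshold; a subset is retained iff its
#'   validation accuracy is strictly greater (default 0.8).
#' @param consensus_fraction Minimum relevance fraction for selection
#'   (default 0.5).
#' @param consensus_denominator `"iterations"` (default) divides
#'   relevance counts by `n_iterations` — the "marked in at least 50% of
#'   the iterations" reading — so a handful of lucky-gated subsets in a
#'   signal-free cohort cannot promote features to full consensus;
#'   `"retained"` divides by the number of retained subsets instead. The
#'   two near-coincide whenever most subsets pass the gate.
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `fallrisk_selection`: a list with elements
#'   `counts` (tibble `feature`, `n_relevant`, `fraction`),
#'   `selected_features`, `n_iterations`, `n_retained`, `log`
#'   (per-iteration tibble with subset fingerprint, gate accuracy and
#'   retention flag), and `config`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_selection <- function(train, validation, n_iterations = 1000L,
                          subset_nonfallers = NULL, accuracy_gate = 0.8,
                          alpha_relevance = 0.05, alpha_normality = 0.05,
                          consensus_fraction = 0.5,
                          consensus_denominator = c("iterations", "retained"),
                          cost = 1, seed = 1L) {
  assert_cohort(train, "train")
  assert_cohort(validation, "validation")
  consensus_denominator <- match.arg(consensus_denominator)
  fallers <- train$id[train$fall_label == "faller"]
  nonfallers <- train$id[train$fall_label == "non_faller"]
  k <- subset_nonfallers %||% length(fallers)
  if (k > length(nonfallers)) {
    abort(paste0("subset_nonfallers = ", k, " exceeds the ",
                 length(nonfallers), " training non-fallers"))
  }
  n_possible <- choose(length(nonfallers), k)
  if (n_iterations > n_possible) {
    abort(paste0(
      "cannot draw ", n_iterations, " distinct subsets: only choose(",
      length(nonfallers), ", ", k, ") = ", format(n_possible, big.mark = ","),
      " non-faller combinations exist"
    ))
  }
  feats <- feature_names(train)
  counts <- setNames(integer(length(feats)), feats)
  iter_seeds <- spawn_seeds(seed, n_iterations)
  seen <- new.env(parent = emptyenv())
  log_rows <- vector("list", n_iterations)
  n_retained <- 0L

  for (i in seq_len(n_iterations)) {
    # redraw on fingerprint collision so all n_iterations subsets are distinct
    draw <- NULL
    sub_seeds <- with_seed(iter_seeds[i], sample.int(.Machine$integer.max - 1L, 1000L))
    for (try in seq_along(sub_seeds)) {
      cand <- with_seed(sub_seeds[try], nonfallers[sample.int(length(nonfallers), k)])
      fp <- paste(sort(cand), collapse = "|")
      if (!exists(fp, envir = seen, inherits = FALSE)) {
        assign(fp, TRUE, envir = seen)
        draw <- cand
        break
      }
    }
    if (is.null(draw)) {
      abort("exhausted redraw attempts while enforcing subset distinctness")
    }
    subset <- train[train$id %in% c(fallers, draw), ]
    acc <- suppressWarnings(gate_subset(subset, validation, cost = cost))
    retained <- acc > accuracy_gate
    if (retained) {
      n_retained <- n_retained + 1L
      rel <- mark_relevant(subset, alpha_relevance, alpha_normality)
      counts[rel] <- counts[rel] + 1L
    }
    log_rows[[i]] <- tibble(iteration = i, fingerprint = fp,
                            accuracy = acc, retained = retained)
  }

  if (n_retained == 0L) {
    abort(paste0(
      "no subset passed the accuracy gate (", accuracy_gate,
      ") in ", n_iterations, " iterations; consider relaxing the gate"
    ), class = "fallrisk_empty_selection")
  }

  denom <- if (consensus_denominator == "retained") n_retained else n_iterations
  count_tbl <- tibble(feature = feats, n_relevant = as.integer(counts),
                      fraction = as.numeric(counts) / denom)
  count_tbl <- dplyr::arrange(count_tbl, dplyr::desc(.data$n_relevant), .data$feature)
  selected <- count_tbl$feature[count_tbl$fraction >= consensus_fraction]

  structure(
    list(
      counts = count_tbl,
      selected_features = selected,
      n_iterations = n_iterations,
      n_retained = n_retained,
      log = dplyr::bind_rows(log_rows),
      config = list(
        subset_nonfallers = k, accuracy_gate = accuracy_gate,
        alpha_relevance = alpha_relevance, alpha_normality = alpha_normality,
        consensus_fraction = consensus_fraction,
        consensus_denominator = consensus_denominator,
        cost = cost, seed = as.integer(seed)
      )
    ),
    class = "fallrisk_selection"
  )
}

#' @export
print.fallrisk_selection <- function(x, ...) {
  cat("Consensus feature selection\n")
  cat(sprintf("  iterations: %d, retained: %d (gate > %.2f)\n",
              x$n_iterations, x$n_retained, x$config$accuracy_gate))
  cat(sprintf("  selected: %d feature(s) at consensus >= %.0f%% of %s subsets\n",
              length(x$selected_features), 100 * x$config$consensus_fraction,
              x$config$consensus_denominator))
  if (length(x$selected_features) > 0) {
    cat("  top features:",
        paste(utils::head(x$selected_features, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn run_selection Per-feature relevance counts and fractions as
#'   a tibble, with a `selected` flag.
#' @param x A `fallrisk_selection` object.
#' @param ... Unused.
#' @method tidy fallrisk_selection
#' @export
tidy.fallrisk_selection <- function(x, ...) {
  dplyr::mutate(x$counts, selected = .data$feature %in% x$selected_features)
}

#' @describeIn run_selection One-row run summary (iterations, retained
#'   subsets, gate pass rate, number of selected features).
#' @method glance fallrisk_selection
#' @export
glance.fallrisk_selection <- function(x, ...) {
  tibble(
    n_iterations = x$n_iterations,
    n_retained = x$n_retained,
    gate_pass_rate = x$n_retained / x$n_iterations,
    mean_gate_accuracy = mean(x$log$accuracy),
    n_selected = length(x$selected_features)
  )
}

#' @describeIn run_selection Lollipop chart of per-feature selection
#'   fractions with the consensus threshold marked.
#' @param object A `fallrisk_selection` object.
#' @param top_n Number of highest-ranking features to display.
#' @method autoplot fallrisk_selection
#' @export
autoplot.fallrisk_selection <- function(object, top_n = 30, ...) {
  d <- utils::head(tidy(object), top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$feature,
                                  colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$fraction,
                                       yend = .data$feature)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$config$consensus_fraction,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "relevance fraction over retained subsets", y = NULL,
                  colour = "selected",
                  title = "Consensus feature selection") +
    ggplot2::theme_minimal()
}
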