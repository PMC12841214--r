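#' Run the full stratification pipeline on a simulated cohort
#'
#' Convenience driver that chains the whole workflow: simulate a cohort,
#' assign the canonical 93/17/32 splits (training faller quota reduced by
#' `k`), augment the faller group from training templates, run
#' consensus feature selection, build the risk scale on the training
#' split, classify the test split, and evaluate the scale (plus the
#' clinical comparators when the simulated clinical features are present)
#' against fall status with the exact test. One master seed drives named
#' substreams per stage, so the run is reproducible end to end.
#'
#' @param n_iterations Selection iterations (default 200).
#' @param n_informative,effect_size Simulation parameters passed to
#'   [simulate_cohort()].
#' @param k Synthetic fallers to add (default 15).
#' @param accuracy_gate SVM gate threshold (default 0.8).
#' @param include_clinical Also evaluate the eight clinical comparator
#'   rules on the test split (default TRUE).
#' @param seed Master seed.
#' @param ... Further arguments forwarded to [run_selection()].
#' @return A list of class `fallrisk_pipeline`: `cohort`, `selection`,
#'   `scale`, `assessments` (test split), `evaluation` (report tibble),
#'   `seed`.
#' @export
run_pipeline <- function(n_iterations = 200L, n_informative = 22L,
                         effect_size = 1, k = 15L, accuracy_gate = 0.8,
                         include_clinical = TRUE, seed = 1L, ...) {
  seeds <- spawn_seeds(seed, 4L)
  cohort <- simulate_cohort(n_informative = n_informative,
                            effect_size = effect_size, seed = seeds[1])
  # split first, then augment from training fallers: no validation or test
  # subject may have a near-copy in the training set
  design <- split_design()
  design$n[design$split == "train" & design$fall_label == "faller"] <-
    design$n[design$split == "train" & design$fall_label == "faller"] - k
  cohort <- assign_splits(cohort, design, seed = seeds[2])
  cohort <- augment_fallers(cohort, k = k, seed = seeds[3])
  train <- cohort[cohort$split == "train", ]
  validation <- cohort[cohort$split == "validation", ]
  test <- cohort[cohort$split == "test", ]
  attr(train, "registry") <- cohort_registry(cohort)

  selection <- run_selection(train, validation, n_iterations = n_iterations,
                             accuracy_gate = accuracy_gate, seed = seeds[4], ...)
  scale <- build_scale(train, selection)
  assessments <- classify_patients(test, scale)
  long <- tibble(
    scale = "ITUG scale",
    fall_label = assessments$fall_label,
    stratum = assessments$final
  )
  if (include_clinical) {
    clin <- clinical_stratify(test)
    long <- dplyr::bind_rows(long, clin[, c("scale", "fall_label", "stratum")])
  }
  evaluation <- evaluate_scales(long)

  structure(
    list(cohort = cohort, selection = selection, scale = scale,
         assessments = assessments, evaluation = evaluation,
         seed = as.integer(seed)),
    class = "fallrisk_pipeline"
  )
}

#' @export
print.fallrisk_pipeline <- function(x, ...) {
  cat("fallrisk pipeline run (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  cohort: %d subjects (%d fallers / %d non-fallers)\n",
              nrow(x$cohort), sum(x$cohort$fall_label == "faller"),
              sum(x$cohort$fall_label == "non_faller")))
  cat(sprintf("  selection: %d/%d subsets retained, %d features selected\n",
              x$selection$n_retained, x$selection$n_iterations,
              length(x$selection$selected_features)))
  cat(sprintf("  scale: %d rules; test-split evaluation:\n", nrow(x$scale)))
  print(as.data.frame(x$evaluation[, c("scale", "p_value")]), row.names = FALSE)
  invisible(x)
}
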