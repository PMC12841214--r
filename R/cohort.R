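#' Read a feature registry
#'
#' The registry describes every feature of a cohort: its name, units,
#' family (`clinical` or `itug`) and an optional prior on its relationship
#' with fall risk (`direction_hint`). CSV (columns `name`, `units`,
#' `family`, `direction_hint`) and YAML (a list of records with the same
#' fields) are both accepted; the format is chosen by file extension.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` registry file.
#' @return A tibble with columns `name`, `units`, `family`,
#'   `direction_hint` (`NA` where no hint is recorded).
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) abort(paste0("registry file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    recs <- yaml::read_yaml(path)
    reg <- purrr::map_dfr(recs, function(r) {
      tibble(
        name = as.character(r$name),
        units = as.character(r$units %||% ""),
        family = as.character(r$family),
        direction_hint = as.character(r$direction_hint %||% NA_character_)
      )
    })
  } else {
    reg <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  }
  validate_registry(reg)
}

#' Write a feature registry
#'
#' @param registry A registry tibble (see [read_registry()]).
#' @param path Destination `.csv`, `.yml` or `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    recs <- purrr::pmap(registry, function(name, units, family, direction_hint) {
      r <- list(name = name, units = units, family = family)
      if (!is.na(direction_hint)) r$direction_hint <- direction_hint
      r
    })
    yaml::write_yaml(recs, path)
  } else {
    readr::write_csv(registry, path)
  }
  invisible(path)
}

validate_registry <- function(registry) {
  if (!is.data.frame(registry)) abort("registry must be a data frame")
  needed <- c("name", "family")
  missing <- setdiff(needed, names(registry))
  if (length(missing) > 0) {
    abort(paste0("registry is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"units" %in% names(registry)) registry$units <- ""
  registry$units[is.na(registry$units)] <- ""
  if (!"direction_hint" %in% names(registry)) {
    registry$direction_hint <- NA_character_
  }
  registry <- as_tibble(registry)[, c("name", "units", "family", "direction_hint")]
  if (anyDuplicated(registry$name)) {
    abort(paste0(
      "duplicate feature name(s) in registry: ",
      paste(unique(registry$name[duplicated(registry$name)]), collapse = ", ")
    ))
  }
  bad_fam <- setdiff(unique(registry$family), c("clinical", "itug"))
  if (length(bad_fam) > 0) {
    abort(paste0("registry family must be 'clinical' or 'itug', got: ",
                 paste(bad_fam, collapse = ", ")))
  }
  bad_dir <- setdiff(unique(registry$direction_hint),
                     c(DIRECTIONS, "unknown", NA))
  if (length(bad_dir) > 0) {
    abort(paste0("invalid direction_hint: ", paste(bad_dir, collapse = ", ")))
  }
  registry$direction_hint[registry$direction_hint %in% "unknown"] <- NA_character_
  registry
}

#' Read a cohort table
#'
#' Ingests a subjects-by-features CSV. The file must carry the reserved
#' columns `id`, `fall_label`, `provenance` and `split` plus one numeric
#' column per registry feature. Ingest is strict: unparseable or missing
#' feature values are rejected (set `on_missing = "drop"` to instead drop
#' incomplete rows with a message), every registry feature must be
#' present, and subject ids must be unique.
#'
#' @param path Path to the cohort CSV.
#' @param registry A registry tibble or a path readable by
#'   [read_registry()]. When `NULL`, every non-reserved column is taken as
#'   an ITUG feature with no direction hint.
#' @param on_missing `"error"` (default) or `"drop"`: what to do with rows
#'   containing missing/non-finite feature values.
#' @return A cohort tibble with the registry attached as attribute
#'   `"registry"` (also retrievable with [cohort_registry()]).
#' @export
read_cohort <- function(path, registry = NULL, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_res <- setdiff(COHORT_RESERVED, names(raw))
  if (length(missing_res) > 0) {
    abort(paste0("cohort file is missing reserved column(s): ",
                 paste(missing_res, collapse = ", ")))
  }
  if (is.character(registry) && length(registry) == 1) {
    registry <- read_registry(registry)
  }
  feats <- setdiff(names(raw), COHORT_RESERVED)
  if (is.null(registry)) {
    registry <- tibble(name = feats, units = "", family = "itug",
                       direction_hint = NA_character_)
  } else {
    registry <- validate_registry(registry)
    missing_feats <- setdiff(registry$name, feats)
    if (length(missing_feats) > 0) {
      abort(paste0("cohort file is missing registry feature(s): ",
                   paste(missing_feats, collapse = ", ")))
    }
    extra <- setdiff(feats, registry$name)
    if (length(extra) > 0) {
      abort(paste0("cohort file has feature column(s) absent from the registry: ",
                   paste(extra, collapse = ", ")))
    }
    feats <- registry$name
  }
  if (anyDuplicated(raw$id)) {
    abort(paste0("duplicate subject id(s): ",
                 paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")))
  }
  cohort <- raw[, c(COHORT_RESERVED, feats)]
  for (f in feats) {
    v <- suppressWarnings(as.numeric(cohort[[f]]))
    bad <- !is.finite(v)
    if (any(bad)) {
      if (on_missing == "error") {
        abort(paste0("non-finite or unparseable value for feature '", f,
                     "' in row(s) with id: ",
                     paste(cohort$id[bad], collapse = ", ")))
      }
    }
    cohort[[f]] <- v
  }
  if (on_missing == "drop") {
    ok <- stats::complete.cases(cohort[, feats]) &
      purrr::reduce(purrr::map(feats, ~ is.finite(cohort[[.x]])), `&`)
    if (any(!ok)) {
      inform(paste0("dropped ", sum(!ok), " row(s) with missing feature values"))
      cohort <- cohort[ok, ]
    }
  }
  cohort <- validate_cohort_labels(cohort)
  attr(cohort, "registry") <- registry
  cohort
}

validate_cohort_labels <- function(cohort) {
  bad <- setdiff(unique(cohort$fall_label), FALL_LABELS)
  if (length(bad) > 0) {
    abort(paste0("fall_label must be one of ",
                 paste(FALL_LABELS, collapse = "/"),
                 "; got: ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(cohort$provenance), PROVENANCES)
  if (length(bad) > 0) {
    abort(paste0("provenance must be one of ",
                 paste(PROVENANCES, collapse = "/"),
                 "; got: ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(cohort$split), SPLITS)
  if (length(bad) > 0) {
    abort(paste0("split must be one of ", paste(SPLITS, collapse = "/"),
                 "; got: ", paste(bad, collapse = ", ")))
  }
  off <- cohort$provenance == "synthetic" & !cohort$split %in% c("train", "unassigned")
  if (any(off)) {
    abort(paste0("synthetic subjects must sit in the training split: ",
                 paste(cohort$id[off], collapse = ", ")))
  }
  cohort
}

#' Registry attached to a cohort
#'
#' @param cohort A cohort tibble produced by [read_cohort()] or
#'   [simulate_cohort()].
#' @return The registry tibble, or a default all-ITUG registry when none
#'   is attached (dplyr/tidyr operations can drop attributes).
#' @export
cohort_registry <- function(cohort) {
  reg <- attr(cohort, "registry", exact = TRUE)
  if (is.null(reg)) {
    reg <- tibble(name = feature_names(cohort), units = "", family = "itug",
                  direction_hint = NA_character_)
  }
  reg
}

#' Write a cohort table
#'
#' Serializes a cohort to CSV at full double precision so that
#' `read_cohort(write_cohort(x))` reproduces the numeric matrix
#' bit-exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  assert_cohort(cohort)
  out <- as_tibble(cohort)
  for (f in feature_names(out)) {
    # 17 significant digits round-trips IEEE doubles exactly
    out[[f]] <- sprintf("%.17g", out[[f]])
  }
  tryCatch(
    readr::write_csv(out, path),
    error = function(e) abort(paste0("cannot write cohort to '", path, "': ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' The canonical 142-subject split design
#'
#' The reference design allocates 93 subjects to training (39 fallers,
#' 54 non-fallers, synthetic subjects included), 17 to validation
#' (5 fallers, 12 non-fallers) and 32 to test (10 fallers,
#' 22 non-fallers).
#'
#' @return A tibble with columns `split`, `fall_label`, `n`.
#' @export
split_design <- function() {
  tibble(
    split = rep(c("train", "validation", "test"), each = 2),
    fall_label = rep(c("faller", "non_faller"), times = 3),
    n = c(39L, 54L, 5L, 12L, 10L, 22L)
  )
}

#' Assign train/validation/test splits
#'
#' Performs a label-stratified uniform draw without replacement under a
#' per-(split, label) count design. Synthetic subjects are only ever
#' allocated to the training split; the design is infeasible if the
#' training quota for a label is smaller than the number of synthetic
#' subjects carrying it.
#'
#' @param cohort A cohort tibble.
#' @param design A tibble with columns `split`, `fall_label`, `n` whose
#'   per-label totals equal the cohort's label counts. Defaults to
#'   [split_design()].
#' @param seed Integer seed; the same seed reproduces the same assignment.
#' @return The cohort with its `split` column filled in (row order
#'   preserved).
#' @export
assign_splits <- function(cohort, design = split_design(), seed = 1L) {
  assert_cohort(cohort)
  reg <- attr(cohort, "registry", exact = TRUE)
  if (!all(c("split", "fall_label", "n") %in% names(design))) {
    abort("design must have columns split, fall_label, n")
  }
  if (any(!design$split %in% c("train", "validation", "test"))) {
    abort("design splits must be train/validation/test")
  }
  new_split <- rep(NA_character_, nrow(cohort))
  labs <- sort(unique(cohort$fall_label))
  lab_seeds <- spawn_seeds(seed, length(labs))
  for (lab in labs) {
    idx <- which(cohort$fall_label == lab)
    d <- design[design$fall_label == lab, ]
    if (sum(d$n) != length(idx)) {
      abort(paste0("infeasible design: ", sum(d$n), " subjects requested for label '",
                   lab, "' but ", length(idx), " available"))
    }
    syn <- idx[cohort$provenance[idx] == "synthetic"]
    n_train <- sum(d$n[d$split == "train"])
    if (length(syn) > n_train) {
      abort(paste0("infeasible design: ", length(syn), " synthetic '", lab,
                   "' subjects cannot fit a training quota of ", n_train))
    }
    # synthetic subjects are pinned to train; real subjects fill the rest
    real <- setdiff(idx, syn)
    new_split[syn] <- "train"
    quotas <- setNames(d$n, d$split)
    if ("train" %in% names(quotas)) quotas["train"] <- quotas["train"] - length(syn)
    shuffled <- real[with_seed(lab_seeds[match(lab, labs)], sample.int(length(real)))]
    pos <- 1L
    for (s in names(quotas)) {
      k <- quotas[[s]]
      if (k > 0) {
        new_split[shuffled[pos:(pos + k - 1L)]] <- s
        pos <- pos + k
      }
    }
  }
  cohort$split <- new_split
  if (!is.null(reg)) attr(cohort, "registry") <- reg
  cohort
}

#' Subject counts by split and fall label
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `split`, `fall_label`, `n`.
#' @export
cohort_counts <- function(cohort) {
  assert_cohort(cohort)
  dplyr::count(as_tibble(cohort), .data$split, .data$fall_label, name = "n")
}
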