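#' Simulate a post-stroke fall-risk cohort
#'
#' Generates a subjects-by-features cohort with the statistical structure
#' the stratification pipeline assumes: a minority faller group, a small
#' set of informative features whose group means differ by a standardized
#' effect size, and exchangeable null features. The default shape mirrors
#' the reference cohort: 39 fallers, 88 non-fallers, 108 features of which
#' 8 are clinical comparator scores and 100 are ITUG-derived measures.
#'
#' Informative features (drawn among the ITUG family) receive a group-mean
#' shift of `effect_size` standard deviations in a randomly chosen risk
#' direction, which is recorded in the registry's `direction_hint`.
#' `within_class_correlation` induces an equicorrelated block across the
#' informative features via a shared per-subject factor;
#' `heavy_tail_fraction` draws that fraction of features from a
#' standardized log-normal instead of a normal.
#'
#' @param n_fallers,n_nonfallers Group sizes (defaults 39 and 88).
#' @param n_features Total feature count (default 108; the first 8 are
#'   clinical scores named after the comparator scales, provided
#'   `n_features >= 8`, otherwise all features are ITUG).
#' @param n_informative Number of features carrying a true group
#'   difference (default 22).
#' @param effect_size Standardized mean difference (Cohen's d) planted on
#'   informative features; must be `>= 0`. Default 1.
#' @param within_class_correlation Equicorrelation in `[0, 1)` among
#'   informative features within each subject. Default 0.
#' @param heavy_tail_fraction Fraction of features drawn log-normal.
#'   Default 0.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A cohort tibble (all subjects `provenance = "real"`,
#'   `split = "unassigned"`) with the matching registry attached as
#'   attribute `"registry"`.
#' @export
simulate_cohort <- function(n_fallers = 39L, n_nonfallers = 88L,
                            n_features = 108L, n_informative = 22L,
                            effect_size = 1, within_class_correlation = 0,
                            heavy_tail_fraction = 0, seed = 1L) {
  if (n_informative > n_features) abort("n_informative must not exceed n_features")
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (within_class_correlation < 0 || within_class_correlation >= 1) {
    abort("within_class_correlation must be in [0, 1)")
  }
  if (heavy_tail_fraction < 0 || heavy_tail_fraction > 1) {
    abort("heavy_tail_fraction must be in [0, 1]")
  }
  n <- n_fallers + n_nonfallers
  registry <- simulate_registry(n_features)
  with_seed(seed, {
    feats <- registry$name
    itug <- registry$name[registry$family == "itug"]
    pool <- if (length(itug) >= n_informative) itug else feats
    informative <- sort(sample(pool, n_informative))
    dir <- sample(DIRECTIONS, n_informative, replace = TRUE)
    registry$direction_hint[match(informative, registry$name)] <- dir
    heavy <- sample(feats, round(heavy_tail_fraction * n_features))

    loc <- registry$location
    scl <- registry$scale
    is_faller <- c(rep(TRUE, n_fallers), rep(FALSE, n_nonfallers))
    rho <- within_class_correlation
    u <- rnorm(n) # shared factor for the equicorrelated informative block

    x <- matrix(NA_real_, nrow = n, ncol = n_features,
                dimnames = list(NULL, feats))
    ln_mean <- exp(0.5)
    ln_sd <- sqrt((exp(1) - 1) * exp(1))
    for (j in seq_len(n_features)) {
      f <- feats[j]
      z <- if (f %in% heavy) (exp(rnorm(n)) - ln_mean) / ln_sd else rnorm(n)
      if (f %in% informative) {
        z <- sqrt(rho) * u + sqrt(1 - rho) * z
        shift <- effect_size *
          ifelse(dir[match(f, informative)] == "higher_is_riskier", 1, -1)
        z[is_faller] <- z[is_faller] + shift
      }
      x[, j] <- loc[j] + scl[j] * z
    }

    cohort <- dplyr::bind_cols(
      tibble(
        id = sprintf("S%03d", seq_len(n)),
        fall_label = ifelse(is_faller, "faller", "non_faller"),
        provenance = "real",
        split = "unassigned"
      ),
      as_tibble(x)
    )
    registry$location <- NULL
    registry$scale <- NULL
    attr(cohort, "registry") <- registry
    cohort
  })
}

# Registry for simulated cohorts: 8 clinical comparator scores (realistic
# locations/scales for a post-stroke rehabilitation population) followed by
# generic ITUG features.
simulate_registry <- function(n_features) {
  clinical <- tibble(
    name = c("mb", "fim_total", "fim_motor", "poma_b",
             "tug_ttd", "fes_i", "conley", "mwt10_speed"),
    units = c("score", "score", "score", "score", "s", "score", "score", "m/s"),
    family = "clinical",
    direction_hint = NA_character_,
    location = c(20, 105, 60, 12, 16.5, 24, 3, 0.95),
    scale = c(5, 15, 12, 4, 7, 8, 2, 0.3)
  )
  if (n_features >= nrow(clinical)) {
    n_itug <- n_features - nrow(clinical)
    itug <- tibble(
      name = sprintf("itug_%03d", seq_len(n_itug)),
      units = "",
      family = "itug",
      direction_hint = NA_character_,
      location = 5,
      scale = 1.5
    )
    dplyr::bind_rows(clinical, itug)
  } else {
    tibble(
      name = sprintf("itug_%03d", seq_len(n_features)),
      units = "", family = "itug", direction_hint = NA_character_,
      location = 5, scale = 1.5
    )
  }
}

#' Augment the faller group with noisy copies
#'
#' Implements Gaussian minority-class augmentation: `k` distinct real
#' fallers are drawn without replacement as templates, and each template
#' is copied with independent zero-mean Gaussian noise added to every
#' feature. The per-feature noise standard deviation is
#' `noise_scale` times the faller-group sample standard deviation of that
#' feature (computed over real fallers), so features that are constant
#' across fallers are copied exactly. New subjects get
#' `provenance = "synthetic"`, `fall_label = "faller"` and
#' `split = "train"`; existing records are never modified.
#'
#' When the cohort's splits are already assigned, templates are drawn from
#' training-split fallers only, so that no validation or test subject has a
#' near-copy in training; on an unsplit cohort any real faller can serve as
#' a template.
#'
#' @param cohort A cohort tibble containing at least `k` eligible real
#'   fallers.
#' @param k Number of synthetic fallers to append (default 15, which
#'   takes a 39-faller/88-non-faller cohort to 54/88).
#' @param noise_scale Multiplier on the per-feature faller-group SD
#'   (default 0.1).
#' @param seed Integer seed.
#' @return The cohort with `k` rows appended.
#' @export
augment_fallers <- function(cohort, k = 15L, noise_scale = 0.1, seed = 1L) {
  assert_cohort(cohort)
  if (k < 0) abort("k must be >= 0")
  if (noise_scale <= 0) abort("noise_scale must be > 0")
  reg <- attr(cohort, "registry", exact = TRUE)
  if (k == 0) return(cohort)
  feats <- feature_names(cohort)
  eligible <- cohort$fall_label == "faller" & cohort$provenance == "real"
  if (any(cohort$split != "unassigned")) {
    eligible <- eligible & cohort$split == "train"
  }
  real_fallers <- which(eligible)
  if (length(real_fallers) < k) {
    abort(paste0("cannot augment: ", k, " synthetic fallers requested but only ",
                 length(real_fallers), " eligible real fallers available as templates"))
  }
  faller_sd <- vapply(feats, function(f) {
    s <- sd(cohort[[f]][real_fallers])
    if (is.na(s)) 0 else s
  }, numeric(1))
  with_seed(seed, {
    templates <- real_fallers[sample.int(length(real_fallers), k)]
    new_rows <- cohort[templates, ]
    new_rows$id <- sprintf("%s_syn%02d", cohort$id[templates], seq_len(k))
    new_rows$provenance <- "synthetic"
    new_rows$fall_label <- "faller"
    new_rows$split <- "train"
    for (f in feats) {
      new_rows[[f]] <- new_rows[[f]] + rnorm(k, 0, noise_scale * faller_sd[[f]])
    }
    out <- dplyr::bind_rows(as_tibble(cohort), new_rows)
    if (!is.null(reg)) attr(out, "registry") <- reg
    out
  })
}
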