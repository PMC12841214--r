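# Small cohort builders used across the suite.

# A minimal valid cohort tibble with explicit feature values.
make_cohort <- function(values, fall_label, id = NULL,
                        provenance = "real", split = "train") {
  values <- as.data.frame(values)
  n <- nrow(values)
  out <- tibble::tibble(
    id = id %||% sprintf("P%03d", seq_len(n)),
    fall_label = fall_label,
    provenance = rep_len(provenance, n),
    split = rep_len(split, n)
  )
  dplyr::bind_cols(out, tibble::as_tibble(values))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A cohort where fallers and non-fallers are perfectly separated on every
# feature (fallers shifted by `gap` SDs).
make_separable_cohort <- function(n_f, n_nf, n_feat = 3, gap = 10, seed = 1,
                                  split = "train") {
  withr::with_seed(seed, {
    x <- matrix(rnorm((n_f + n_nf) * n_feat), ncol = n_feat)
    x[seq_len(n_f), ] <- x[seq_len(n_f), ] + gap
    colnames(x) <- sprintf("f%02d", seq_len(n_feat))
    make_cohort(x, c(rep("faller", n_f), rep("non_faller", n_nf)),
                split = split)
  })
}

# Independent brute-force oracle for the exact test on 2x3 tables:
# enumerates every nonnegative matrix with the observed margins and sums
# the classical factorial-formula probabilities of tables no more probable
# than the observed one.
ffh_oracle <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  log_const <- sum(lfactorial(r)) + sum(lfactorial(cs)) - lfactorial(n)
  prob_of <- function(m) exp(log_const - sum(lfactorial(m)))
  p_obs <- prob_of(tab)
  total <- 0
  for (a in 0:min(r[1], cs[1])) {
    for (b in 0:min(r[1] - a, cs[2])) {
      cc <- r[1] - a - b
      if (cc < 0 || cc > cs[3]) next
      m <- rbind(c(a, b, cc), cs - c(a, b, cc))
      if (any(m < 0)) next
      p <- prob_of(m)
      if (p <= p_obs * (1 + 1e-7)) total <- total + p
    }
  }
  min(total, 1)
}

# Closed-form two-sided 2x2 hypergeometric p-value (probability ordering),
# written directly from dhyper.
hyper2x2_p <- function(tab) {
  stopifnot(ncol(tab) == 2)
  m <- colSums(tab)[1]; nn <- colSums(tab)[2]; kk <- rowSums(tab)[1]
  support <- max(0, kk - nn):min(kk, m)
  d <- stats::dhyper(support, m, nn, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, nn, kk)
  sum(d[d <= p_obs * (1 + 1e-7)])
}
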