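test_that("balanced subsets keep all fallers and draw distinct non-faller sets", {
  co <- simulate_cohort(seed = 8)
  design <- split_design()
  design$n[design$split == "train" & design$fall_label == "faller"] <- 24L
  co <- assign_splits(co, design, seed = 8)
  co <- augment_fallers(co, k = 15, seed = 8)
  co <- co[co$split == "train", ] # 39 fallers + 54 non-fallers
  ids1 <- sample_balanced_subset(co, seed = 1, draw_index = 1)
  ids2 <- sample_balanced_subset(co, seed = 1, draw_index = 2)
  fallers <- co$id[co$fall_label == "faller"]
  expect_length(ids1, 78) # 39 fallers + 39 of 54 non-fallers
  expect_true(all(fallers %in% ids1))
  expect_false(setequal(ids1, ids2))
  # deterministic in (seed, draw_index)
  expect_identical(sample_balanced_subset(co, seed = 1, draw_index = 2), ids2)
})

test_that("requesting more distinct subsets than combinations errors with the bound", {
  co <- make_separable_cohort(3, 4)
  expect_error(
    sample_balanced_subset(co, subset_nonfallers = 4, seed = 1,
                           draw_index = 2, n_draws = 2),
    "choose\\(4, 4\\)"
  )
  va <- make_separable_cohort(2, 3, split = "validation", seed = 99)
  expect_error(
    run_selection(co, va, n_iterations = 2, subset_nonfallers = 4, seed = 1),
    "choose\\(4, 4\\)"
  )
})

test_that("the SVM gate scores plain validation accuracy under subset standardization", {
  # perfectly separated classes: identically distributed validation is
  # classified without error
  tr <- make_separable_cohort(12, 12, gap = 10, seed = 2)
  va <- make_separable_cohort(6, 8, gap = 10, seed = 3, split = "validation")
  expect_equal(gate_subset(tr, va), 1.0)

  # swapping labels on a known fraction of validation subjects pins the
  # accuracy exactly: 3 of 17 wrong -> 14/17, 2 of 10 wrong -> 0.8
  flip_some <- function(va, k) {
    va$fall_label[seq_len(k)] <- ifelse(va$fall_label[seq_len(k)] == "faller",
                                        "non_faller", "faller")
    va
  }
  va17 <- make_separable_cohort(8, 9, gap = 10, seed = 4, split = "validation")
  acc <- gate_subset(tr, flip_some(va17, 3))
  expect_equal(acc, 14 / 17)
  expect_true(acc > 0.8) # retained under the strict gate

  va10 <- make_separable_cohort(5, 5, gap = 10, seed = 5, split = "validation")
  acc <- gate_subset(tr, flip_some(va10, 2))
  expect_equal(acc, 0.8)
  expect_false(acc > 0.8) # exactly at the gate: NOT retained
})

test_that("zero-variance features are standardized to zero with a warning", {
  tr <- make_separable_cohort(10, 10, gap = 10, seed = 6)
  tr$f01 <- 5 # constant
  va <- make_separable_cohort(4, 4, gap = 10, seed = 7, split = "validation")
  va$f01 <- 5
  expect_warning(acc <- gate_subset(tr, va), "zero SD.*f01")
  expect_equal(acc, 1.0)
})

test_that("relevance marking routes by normality and flags separated groups", {
  # fully separated small groups: the exact rank-sum p-value is the oracle
  a <- c(1, 2, 3, 4, 5, 6) + 10
  b <- c(1, 2, 3, 4, 5, 6)
  p_exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_lt(p_exact, 0.05)
  co <- make_cohort(data.frame(sep = c(a, b), same = rep(1, 12),
                               null = rep(c(2, 4, 6, 8, 5, 3), 2)),
                    fall_label = rep(c("faller", "non_faller"), each = 6))
  marked <- mark_relevant(co)
  expect_true("sep" %in% marked)
  expect_false("same" %in% marked)   # constant in both groups: undefined test
  expect_false("null" %in% marked)   # identical group values
  expect_error(mark_relevant(co[c(1, 2, 7, 8), ]), "at least 3")
})

test_that("run_selection is reproducible, bounded and monotone in the consensus", {
  co <- make_separable_cohort(10, 14, n_feat = 8, gap = 1.5, seed = 10)
  va <- make_separable_cohort(5, 7, n_feat = 8, gap = 1.5, seed = 11,
                              split = "validation")
  s1 <- run_selection(co, va, n_iterations = 30, accuracy_gate = 0.5, seed = 3)
  s2 <- run_selection(co, va, n_iterations = 30, accuracy_gate = 0.5, seed = 3)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$selected_features, s2$selected_features)
  # all fingerprints distinct
  expect_identical(anyDuplicated(s1$log$fingerprint), 0L)
  # counts bounded by retained subsets
  expect_lte(s1$n_retained, s1$n_iterations)
  expect_true(all(s1$counts$n_relevant <= s1$n_retained))
  # raising the consensus fraction never grows the selection
  s_hi <- run_selection(co, va, n_iterations = 30, accuracy_gate = 0.5,
                        consensus_fraction = 0.8, seed = 3)
  expect_true(all(s_hi$selected_features %in% s1$selected_features))
  # selection order: descending count, lexicographic ties
  cnt <- s1$counts
  expect_true(all(diff(cnt$n_relevant) <= 0))
})

test_that("a feature relevant in exactly half the iterations is selected", {
  co <- make_separable_cohort(10, 14, n_feat = 4, gap = 2, seed = 12)
  va <- make_separable_cohort(5, 7, n_feat = 4, gap = 2, seed = 13,
                              split = "validation")
  sel <- run_selection(co, va, n_iterations = 20, accuracy_gate = 0, seed = 5)
  half <- sel$counts$feature[sel$counts$fraction == 0.5]
  if (length(half) > 0) {
    expect_true(all(half %in% sel$selected_features))
  }
  # the >=50% rule is inclusive by construction on the counts table
  expect_setequal(
    sel$selected_features,
    sel$counts$feature[sel$counts$fraction >= 0.5]
  )
})

test_that("an impossible accuracy gate raises the documented empty-selection error", {
  co <- make_separable_cohort(8, 10, gap = 10, seed = 14)
  va <- make_separable_cohort(4, 4, gap = 10, seed = 15, split = "validation")
  expect_error(
    run_selection(co, va, n_iterations = 5, accuracy_gate = 1.01, seed = 1),
    class = "fallrisk_empty_selection"
  )
})
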