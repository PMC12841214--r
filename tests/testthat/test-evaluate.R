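test_that("contingency tables tabulate fall status by stratum with fixed layout", {
  d <- data.frame(
    fall_label = c(rep("non_faller", 22), rep("faller", 10)),
    stratum = c(rep("low", 22), rep("high", 10))
  )
  tab <- build_contingency(d)
  expect_identical(tab, matrix(c(22L, 0L, 0L, 0L, 0L, 10L), nrow = 2,
                               dimnames = list(fall_label = c("non_faller", "faller"),
                                               stratum = c("low", "medium", "high"))))
  mixed <- data.frame(fall_label = c("faller", "faller", "non_faller",
                                     "non_faller", "faller"),
                      stratum = c("low", "medium", "medium", "high", "high"))
  expect_identical(sum(build_contingency(mixed)), 5L)
  expect_error(build_contingency(mixed[0, ]), "empty")
})

test_that("the exact test reproduces the hand-checkable FIM-total value", {
  tab <- rbind(c(21, 1, 0), c(9, 1, 0))
  res <- fisher_freeman_halton(tab)
  expect_equal(signif(res$p.value, 3), 0.534)
  # hand check as a 2x2 hypergeometric sum over X = fallers among the two
  # medium-column subjects: P(X = 1) + P(X = 2) = 0.4435 + 0.0907
  expect_equal(res$p.value,
               stats::dhyper(1, 2, 30, 10) + stats::dhyper(2, 2, 30, 10),
               tolerance = 1e-12)
  expect_equal(stats::dhyper(1, 2, 30, 10), 0.4435, tolerance = 1e-3)
  expect_equal(stats::dhyper(2, 2, 30, 10), 0.0907, tolerance = 1e-3)
})

test_that("degenerate margins give p = 1 and invalid tables are rejected", {
  expect_equal(fisher_freeman_halton(rbind(c(0, 0, 0), c(3, 2, 1)))$p.value, 1)
  d <- data.frame(fall_label = rep(c("faller", "non_faller"), each = 6),
                  stratum = rep(c("low", "medium", "high"), 4))
  expect_equal(fisher_freeman_halton(build_contingency(d))$p.value, 1)
  expect_error(fisher_freeman_halton(rbind(c(1, -1, 0), c(1, 1, 1))), "nonnegative")
  expect_error(fisher_freeman_halton(rbind(c(0.5, 1, 0), c(1, 1, 1))), "nonnegative")
  expect_error(fisher_freeman_halton(rbind(c(0, 0, 0), c(0, 0, 0))), "grand total")
})

test_that("enumeration matches the brute-force oracle and the library cross-check", {
  withr::with_seed(77, {
    for (r in 1:60) {
      tab <- matrix(rpois(6, 2), nrow = 2)
      if (sum(tab) == 0) tab[1, 1] <- 1
      p <- fisher_freeman_halton(tab)$p.value
      expect_equal(p, ffh_oracle(tab), tolerance = 1e-12)
      # independent library oracle (needs two informative columns)
      nz <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(nz) >= 2) {
        expect_equal(p, stats::fisher.test(nz)$p.value, tolerance = 1e-7)
      } else {
        expect_equal(p, 1)
      }
    }
  })
})

test_that("the exact test is invariant to row swaps, column permutations and zero columns", {
  withr::with_seed(78, {
    for (r in 1:25) {
      tab <- matrix(rpois(6, 3), nrow = 2)
      if (sum(tab) == 0) tab[2, 3] <- 2
      p <- fisher_freeman_halton(tab)$p.value
      expect_equal(fisher_freeman_halton(tab[2:1, ])$p.value, p, tolerance = 1e-12)
      perm <- sample(ncol(tab))
      expect_equal(fisher_freeman_halton(tab[, perm])$p.value, p, tolerance = 1e-12)
      with_zero <- cbind(tab, c(0, 0))
      expect_equal(fisher_freeman_halton(with_zero)$p.value, p, tolerance = 1e-12)
    }
  })
})

test_that("with a zero column the test reduces to the two-sided 2x2 hypergeometric", {
  withr::with_seed(79, {
    for (r in 1:25) {
      tab22 <- matrix(rpois(4, 4), nrow = 2)
      if (sum(tab22) == 0) tab22[1, 1] <- 3
      tab23 <- cbind(tab22, c(0, 0))
      expect_equal(fisher_freeman_halton(tab23)$p.value, hyper2x2_p(tab22),
                   tolerance = 1e-12)
    }
  })
})

test_that("printed percentages reconstruct to unique integer counts", {
  expect_identical(reconstruct_counts(c(27.3, 72.7, 0.0), 22), c(6L, 16L, 0L))
  expect_identical(reconstruct_counts(c(45.4, 45.4, 9.2), 22), c(10L, 10L, 2L))
  expect_identical(reconstruct_counts(c(100, 0, 0), 10), c(10L, 0L, 0L))
  expect_identical(reconstruct_counts(c(95.4, 4.6, 0.0), 22), c(21L, 1L, 0L))
  expect_error(reconstruct_counts(c(60, 60, 60), 10), "sum")
  expect_error(reconstruct_counts(c(50, 50, 0), 0), "positive")
})

test_that("scale evaluation reports per-row percentages and exact p-values", {
  d <- tibble::tibble(
    scale = "toy",
    fall_label = c(rep("non_faller", 4), rep("faller", 4)),
    stratum = rep(c("low", "low", "medium", "high"), 2)
  )
  rep <- evaluate_scales(d)
  expect_equal(rep$p_value, 1) # identical distributions in both rows
  expect_equal(rep$nonfaller_low, 50)
  expect_equal(rep$nonfaller_low + rep$nonfaller_medium + rep$nonfaller_high,
               100, tolerance = 0.2)
  expect_equal(rep$faller_low + rep$faller_medium + rep$faller_high,
               100, tolerance = 0.2)
  expect_identical(rep$n_nonfallers, 4L)
  expect_error(evaluate_scales(d[, 1:2]), "stratum")
})

test_that("tidy and glance methods expose the fitted objects as tibbles", {
  res <- fisher_freeman_halton(rbind(c(5, 1, 0), c(1, 4, 2)))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$p.value, res$p.value)

  co <- make_separable_cohort(8, 10, n_feat = 4, gap = 3, seed = 40)
  va <- make_separable_cohort(4, 4, n_feat = 4, gap = 3, seed = 41,
                              split = "validation")
  sel <- run_selection(co, va, n_iterations = 10, accuracy_gate = 0.5, seed = 2)
  expect_s3_class(tidy(sel), "tbl_df")
  g <- glance(sel)
  expect_identical(g$n_iterations, 10)
  expect_true(g$gate_pass_rate >= 0 && g$gate_pass_rate <= 1)
})
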