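# Proteome-wide comparison statistics: paired fold changes, the CV
# cutoff, exact binomial/Fisher tests, z-scores and the time course.

mk_summary <- function(ids, means, cvs = NA_real_) {
  data.frame(protein_id = ids, mean_fsr = means, cv = cvs,
             stringsAsFactors = FALSE)
}

test_that("paired log2 fold changes pair shared proteins and classify
           direction", {
  con <- mk_summary(c("A", "B", "C"), c(0.05, 0.05, 0.02))
  cr <- mk_summary(c("A", "B", "D"), c(0.05, 0.025, 0.04))
  cmp <- paired_log2fc(con, cr)
  expect_equal(cmp$protein_id, c("A", "B"))  # C and D unpaired
  expect_equal(attr(cmp, "n_unpaired"), 2L)
  expect_equal(cmp$log2fc, c(0, -1))
  expect_equal(cmp$direction, c("Tie", "Down"))
  expect_equal(cmp$percent_change, c(0, -50))
  # non-positive means are excluded with a count
  cr2 <- mk_summary(c("A", "B"), c(0, 0.1))
  cmp2 <- paired_log2fc(con, cr2)
  expect_equal(cmp2$protein_id, "B")
  expect_equal(attr(cmp2, "n_nonpositive"), 1L)
})

test_that("swapping arms negates every log2fc and swaps Up/Down", {
  set.seed(3)
  a <- mk_summary(sprintf("P%02d", 1:30), runif(30, 0.01, 0.5))
  b <- mk_summary(sprintf("P%02d", 1:30), runif(30, 0.01, 0.5))
  ab <- paired_log2fc(a, b); ba <- paired_log2fc(b, a)
  expect_equal(ab$log2fc, -ba$log2fc)
  pa <- flux_proportions(ab); pb <- flux_proportions(ba)
  expect_equal(pa$n_down, pb$n_up)
  expect_equal(pa$n_up, pb$n_down)
  expect_equal(pa$p_binomial, pb$p_binomial)
})

test_that("the averaged-CV threshold pools all defined CVs", {
  expect_equal(average_cv_threshold(c(10, 20)), 15)
  expect_equal(average_cv_threshold(12), 12)
  expect_equal(average_cv_threshold(c(10, NA), c(20, NaN)), 15)
  expect_equal(average_cv_threshold(c(0, 0)), 0)
  expect_error(average_cv_threshold(NA_real_), "no defined CVs")
})

test_that("the CV cutoff compares absolute percent change", {
  cmp <- data.frame(log2fc = c(-0.3, -0.1, 0),
                    percent_change = (2^c(-0.3, -0.1, 0) - 1) * 100,
                    direction = c("Down", "Down", "Tie"),
                    stringsAsFactors = FALSE)
  out <- classify_flux_change(cmp, 15)
  expect_equal(out$percent_change[1], -18.77, tolerance = 1e-3)
  expect_equal(out$above_cv, c(TRUE, FALSE, FALSE))
  # zero threshold: every nonzero change is above the cutoff
  expect_equal(classify_flux_change(cmp, 0)$above_cv,
               c(TRUE, TRUE, FALSE))
})

test_that("two-tailed binomial doubles the smaller tail and caps at 1", {
  expect_equal(binomial_two_tailed(6, 10), 0.75390625)
  expect_equal(binomial_two_tailed(5, 10), 1)
  expect_equal(binomial_two_tailed(10, 10), 2 / 1024)
  expect_equal(binomial_two_tailed(0, 10), 2 / 1024)
  expect_error(binomial_two_tailed(1, 0), "positive")
  # the minimum-likelihood switch matches stats::binom.test
  for (n in c(7, 11)) {
    for (k in 0:n) {
      expect_equal(binomial_two_tailed(k, n, method = "minlik"),
                   binom.test(k, n)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("two-tailed Fisher matches its closed cases and fisher.test", {
  expect_equal(fisher_exact_two_tailed(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_two_tailed(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_error(fisher_exact_two_tailed(matrix(c(0, 0, 3, 4), 2)),
               "degenerate")
  set.seed(9)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_two_tailed(tab),
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("proportions account for every compared protein", {
  cmp <- data.frame(direction = c(rep("Down", 6), rep("Up", 3), "Tie"),
                    stringsAsFactors = FALSE)
  pr <- flux_proportions(cmp)
  expect_equal(pr$n_down + pr$n_up + pr$n_tie, nrow(cmp))
  expect_equal(pr$n_total, 9)  # ties excluded from the test
  expect_equal(pr$pct_down, 100 * 6 / 9)
  expect_equal(pr$p_binomial, binomial_two_tailed(6, 9))
})

test_that("arm contrasts build the Down/NotDown-by-arm Fisher table", {
  a <- data.frame(direction = c(rep("Down", 10), rep("Up", 2)))
  b <- data.frame(direction = c(rep("Down", 3), rep("Up", 9)))
  ct <- arm_contrast(a, b)
  expect_equal(unname(ct$table), matrix(c(10, 2, 3, 9), 2))
  expect_equal(ct$p_fisher,
               fisher_exact_two_tailed(matrix(c(10, 2, 3, 9), 2)))
})

test_that("z-scores standardize to mean 0, SD 1 and are affine-invariant", {
  expect_equal(zscore_by_timepoint(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(20)
  expect_equal(zscore_by_timepoint(3 * x + 7), zscore_by_timepoint(x),
               tolerance = 1e-12)
  expect_error(zscore_by_timepoint(rep(0.3, 5)), "zero variance")
  expect_error(zscore_by_timepoint(1), "at least two")
})

test_that("time-course log2 ratios use the reference day", {
  pts <- data.frame(day = c(0, 25, 31), pct_down = c(54, 52, 85))
  tc <- timecourse_summary(pts)
  expect_equal(tc$points$log2_rel_ref[tc$points$day == 31],
               log2(85 / 54), tolerance = 1e-4)
  expect_equal(tc$points$log2_rel_ref[tc$points$day == 31], 0.6543,
               tolerance = 1e-3)
  expect_equal(tc$points$neg_log2_rel_ref, -tc$points$log2_rel_ref)
  expect_error(timecourse_summary(pts, reference_day = 5), "missing")
})

test_that("a flat series reports no transition", {
  pts <- data.frame(day = c(0, 10, 20, 30), pct_down = rep(54, 4))
  tc <- timecourse_summary(pts)
  expect_true(is.na(tc$transition$logistic_midpoint))
  expect_true(is.na(tc$transition$first_day_above_threshold))
})

test_that("a step series near day 27 yields a logistic midpoint in the
           transition window", {
  days <- c(0, 9, 14, 20, 25, 27, 28, 29, 30, 31, 40)
  pct <- ifelse(days < 27, 55, 80)
  tc <- timecourse_summary(data.frame(day = days, pct_down = pct))
  expect_gte(tc$transition$logistic_midpoint, 25)
  expect_lte(tc$transition$logistic_midpoint, 30)
  expect_equal(tc$transition$first_day_above_threshold, 27)
})
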