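test_that("pearson chi-square has no association on a balanced table", {
  r <- pearson_chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1L)
})

test_that("chi-square matches the 2x2 algebraic identity", {
  withr::local_seed(111)
  for (rep in 1:200) {
    cells <- sample(1:50, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    n <- a + b + c + d
    identity <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    got <- pearson_chi_square(matrix(c(a, c, b, d), 2))$chi2
    expect_equal(got, identity, tolerance = 1e-9)
  }
})

test_that("chi-square is invariant to transposition and validates input", {
  tab <- matrix(c(15, 4, 282, 256), 2)
  expect_equal(pearson_chi_square(tab)$chi2,
               pearson_chi_square(t(tab))$chi2)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(pearson_chi_square(matrix(1:3, 1)), "2 x 2")
  expect_error(pearson_chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  # a Fisher p is reported alongside when expected cells are small
  sparse <- matrix(c(2, 1, 30, 40), 2)
  expect_false(is.na(pearson_chi_square(sparse)$fisher_p))
})

test_that("odds ratios follow the Wald closed form and invert on swap", {
  r <- odds_ratio_wald(10, 10, 10, 10)
  expect_equal(r$or, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(r$ci_high), -log(r$ci_low))

  a <- 12; b <- 30; c <- 7; d <- 44
  r <- odds_ratio_wald(a, b, c, d)
  expect_equal(r$or, a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_equal(r$ci_low, exp(log(a * d / (b * c)) - 1.959964 * se),
               tolerance = 1e-6)

  # swapping exposure rows inverts the OR and swaps/inverts the CI
  sw <- odds_ratio_wald(b, a, d, c)
  expect_equal(sw$or, 1 / r$or)
  expect_equal(sw$ci_low, 1 / r$ci_high)
  expect_equal(sw$ci_high, 1 / r$ci_low)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  r <- odds_ratio_wald(0, 50, 50, 50)
  expect_true(r$correction_applied)
  expect_equal(r$or, (0.5 * 50.5) / (50.5 * 50.5))
  expect_error(odds_ratio_wald(0, 0, 5, 5), "undefined")
  expect_error(odds_ratio_wald(0, 5, 0, 5), "undefined")
})

test_that("unadjusted logistic exposure OR equals the closed form", {
  cohort <- expand_counts_to_cohort(15, 282, 4, 256)
  fit <- fit_logistic_regression(cohort, "status", "carrier")
  closed <- odds_ratio_wald(15, 282, 4, 256)
  expect_equal(round(fit$exposure_or$or, 4), round(closed$or, 4))
  expect_equal(round(fit$exposure_or$ci_low, 4), round(closed$ci_low, 4))
  expect_equal(round(fit$exposure_or$ci_high, 4),
               round(closed$ci_high, 4))
  expect_true(fit$converged)
})

test_that("degenerate designs are flagged rather than fit", {
  cohort <- expand_counts_to_cohort(15, 282, 4, 256)
  cohort$status <- factor("case", levels = c("control", "case"))
  fit <- fit_logistic_regression(cohort, "status", "carrier")
  expect_true(fit$separation)
  expect_false(fit$converged)

  cohort2 <- expand_counts_to_cohort(15, 282, 4, 256)
  cohort2$dup <- cohort2$carrier  # perfectly collinear covariate
  expect_error(
    fit_logistic_regression(cohort2, "status", "carrier", "dup"),
    "collinear")
  expect_error(
    fit_logistic_regression(cohort2, "status", "missing_col"),
    "not in cohort")
})

test_that("adjusted and unadjusted ORs agree when covariates are noise", {
  cohort <- simulate_cohort_table(200, 200, 0.4, 0.2, seed = 17)
  un <- fit_logistic_regression(cohort, "status", "carrier")
  ad <- fit_logistic_regression(cohort, "status", "carrier",
                                c("gender", "age"))
  # independent covariates leave the exposure estimate nearly unchanged
  expect_equal(ad$exposure_or$or, un$exposure_or$or, tolerance = 0.1)
})

test_that("Mann-Whitney U handles ties, separation and identity", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_equal(same$U, 4.5)  # at its null mean n1*n2/2

  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation tracks exact enumeration", {
  # tie-free groups of 6-8; at smaller sizes the normal approximation is
  # known to be crude and the exact test is what one would use
  withr::local_seed(222)
  for (rep in 1:30) {
    n1 <- sample(6:8, 1); n2 <- sample(6:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.5)
    approx_p <- mann_whitney_u(a, b)$p
    exact_p <- exact_mw_p(a, b)
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("approximate p matches wilcox.test's corrected normal p", {
  withr::local_seed(333)
  for (rep in 1:20) {
    a <- rnorm(sample(5:15, 1))
    b <- rnorm(sample(5:15, 1), mean = 0.5)
    got <- mann_whitney_u(a, b)
    want <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(got$p, want$p.value, tolerance = 1e-10)
    expect_equal(got$U, unname(want$statistic))
  }
})

test_that("printed exposure percentages use half-up rounding", {
  expect_equal(proportion_pct(15, 297), 5.1)
  expect_equal(proportion_pct(4, 260), 1.5)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("associate_exposure assembles the full 2x2 report", {
  cohort <- expand_counts_to_cohort(15, 282, 4, 256)
  r <- associate_exposure(cohort)
  expect_equal(unname(r$table[1, ]), c(15, 4))
  expect_equal(unname(r$table[2, ]), c(282, 256))
  expect_equal(r$or, 15 * 256 / (282 * 4))
  expect_equal(r$pct_exposed_cases, 5.1)
  expect_equal(r$pct_exposed_controls, 1.5)
  expect_null(r$adjusted)
})
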