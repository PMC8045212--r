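#' Pearson chi-square test for an r x c contingency table
#'
#' Plain (uncorrected) Pearson chi-square: `sum((O - E)^2 / E)` with
#' `E = row_total * col_total / N`, compared against the chi-square
#' distribution on `(r - 1)(c - 1)` degrees of freedom. No continuity
#' correction is applied by default -- published case/control tables are
#' almost always the uncorrected statistic -- but Yates' correction is
#' available for 2 x 2 tables via `correct = TRUE`. When any expected
#' cell is below 5 a Fisher exact p-value is reported alongside (never
#' silently substituted).
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @param correct apply Yates' continuity correction (2 x 2 only;
#'   default `FALSE`).
#' @return A list: `chi2`, `df`, `p`, `expected`, `correction_applied`,
#'   `fisher_p` (`NA` unless some expected cell < 5).
#' @examples
#' pearson_chi_square(matrix(c(15, 4, 282, 256), 2))$chi2  # 5.19
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  check_contingency(table)
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  fisher_p <- NA_real_
  if (any(res$expected < 5) && nrow(table) == 2L && ncol(table) == 2L) {
    fisher_p <- stats::fisher.test(table)$p.value
  }
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), expected = res$expected,
       correction_applied = correct, fisher_p = fisher_p)
}

check_contingency <- function(table) {
  if (nrow(table) < 2L || ncol(table) < 2L) {
    abort("contingency table must be at least 2 x 2")
  }
  if (any(table < 0) || any(table != floor(table))) {
    abort("counts must be non-negative integers")
  }
  if (sum(table) == 0) abort("empty contingency table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("all-zero row or column margin")
  }
  invisible(table)
}

#' Odds ratio with Wald confidence interval for a 2 x 2 table
#'
#' `OR = (a d) / (b c)` with `a` the exposed cases, and a Wald interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` using
#' `z = 1.959964` for 95% coverage. When any cell is zero the
#' Haldane-Anscombe correction (add 0.5 to every cell) is applied and
#' flagged; two zero cells in one margin leave the odds ratio undefined.
#'
#' @param a,b,c,d cell counts: exposed cases, unexposed cases, exposed
#'   controls, unexposed controls. Alternatively pass a 2 x 2 matrix as
#'   `a` (rows = exposure, columns = case/control; `a[1,1]` exposed
#'   cases, `a[2,1]` unexposed cases).
#' @param conf_level confidence level (default 0.95).
#' @return A list: `or`, `ci_low`, `ci_high`, `se_log_or`,
#'   `correction_applied`.
#' @examples
#' odds_ratio_wald(15, 282, 4, 256)  # OR 3.40, CI 1.12-10.39
#' @export
odds_ratio_wald <- function(a, b = NULL, c = NULL, d = NULL,
                            conf_level = 0.95) {
  if (is.matrix(a)) {
    m <- a
    if (!all(dim(m) == 2L)) abort("odds ratio needs a 2 x 2 table")
    a <- m[1, 1]; b <- m[2, 1]; c <- m[1, 2]; d <- m[2, 2]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("negative cell count")
  corrected <- any(cells == 0)
  if (corrected) {
    # two zeros sharing a margin: both odds in that margin vanish
    if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
        (a == 0 && c == 0) || (b == 0 && d == 0)) {
      abort("OR undefined: two zero cells share a margin")
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or),
       ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
       se_log_or = se, correction_applied = corrected)
}

#' Unconditional logistic regression for case/control exposure
#'
#' Maximum-likelihood logistic regression (fit by iteratively reweighted
#' least squares via [stats::glm()]) of case status on an exposure plus
#' optional covariates, reporting each term's adjusted odds ratio
#' `exp(coefficient)` with a Wald confidence interval. Categorical
#' covariates use their first factor level as reference. A coefficient
#' beyond +/-15 on the log scale signals (quasi-)complete separation and
#' the fit is flagged non-converged.
#'
#' @param cohort data.frame of one row per subject.
#' @param outcome name of the binary outcome column (factor; second
#'   level is the event, i.e. case).
#' @param exposure name of the exposure column.
#' @param covariates character vector of adjustment columns (default
#'   none).
#' @param conf_level confidence level for the Wald intervals
#'   (default 0.95).
#' @return A list: `terms` (data.frame with `term`, `estimate`, `se`,
#'   `or`, `ci_low`, `ci_high`, `z`, `p`), `exposure_or` (the first
#'   non-reference exposure term's row), `converged`, `separation`,
#'   `n_iterations`, `log_likelihood`, `fit` (the underlying glm).
#' @export
fit_logistic_regression <- function(cohort, outcome, exposure,
                                    covariates = character(),
                                    conf_level = 0.95) {
  for (col in c(outcome, exposure, covariates)) {
    if (!col %in% names(cohort)) abort("column '%s' not in cohort", col)
  }
  y <- cohort[[outcome]]
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(droplevels(y)) != 2L) {
    if (nlevels(droplevels(y)) == 1L) {
      return(list(terms = NULL, exposure_or = NULL, converged = FALSE,
                  separation = TRUE, n_iterations = 0L,
                  log_likelihood = NA_real_, fit = NULL))
    }
    abort("outcome must be binary")
  }
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  dat <- cohort[, c(exposure, covariates), drop = FALSE]
  dat$y <- y

  # rank check on the model matrix before fitting
  mm <- stats::model.matrix(form, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    drop_cols <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort("rank-deficient design; collinear column(s): %s",
          paste(drop_cols, collapse = ", "))
  }

  fit <- stats::glm(form, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  coefs <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(term = rownames(coefs),
                      estimate = coefs[, 1], se = coefs[, 2],
                      or = exp(coefs[, 1]),
                      ci_low = exp(coefs[, 1] - z * coefs[, 2]),
                      ci_high = exp(coefs[, 1] + z * coefs[, 2]),
                      z = coefs[, 3], p = coefs[, 4],
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  separation <- any(abs(coefs[-1, 1]) > 15)
  exp_rows <- terms[startsWith(terms$term, exposure), , drop = FALSE]
  list(terms = terms,
       exposure_or = if (nrow(exp_rows)) exp_rows[1, ] else NULL,
       converged = fit$converged && !separation,
       separation = separation,
       n_iterations = fit$iter,
       log_likelihood = as.numeric(stats::logLik(fit)),
       fit = fit)
}

#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum U statistic with midranks for ties, a tie-corrected variance,
#' and a 0.5 continuity correction; the two-sided p-value comes from the
#' normal approximation. The p-value matches
#' `wilcox.test(exact = FALSE, correct = TRUE)`.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @return A list: `U` (for `group_a`), `z`, `p`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$U  # 0: complete separation
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  ranks <- rank(c(group_a, group_b))  # midranks for ties
  r1 <- sum(ranks[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 == 0) {
    # all observations identical: no evidence either way
    return(list(U = u, z = 0, p = 1))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  if (u == mu) z <- 0
  list(U = u, z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Case/control association report for a cohort table
#'
#' Builds the exposure-by-status contingency table, reports the
#' uncorrected chi-square, the unadjusted Wald odds ratio, the printed
#' per-group exposure percentages, and (when covariates are given) the
#' covariate-adjusted logistic odds ratio.
#'
#' @param cohort a `CohortTable` data.frame (see
#'   [simulate_cohort_table()]).
#' @param outcome outcome column (default `"status"`, second factor
#'   level = case).
#' @param exposure exposure column (default `"carrier"`, second factor
#'   level = exposed).
#' @param covariates adjustment columns for the logistic model
#'   (default none).
#' @return A list: `table` (2 x 2 counts, rows exposed/unexposed, columns
#'   case/control), `chi2`, `df`, `p`, `or`, `ci_low`, `ci_high`,
#'   `pct_exposed_cases`, `pct_exposed_controls`, `adjusted` (logistic
#'   fit result or `NULL`).
#' @export
associate_exposure <- function(cohort, outcome = "status",
                               exposure = "carrier",
                               covariates = character()) {
  y <- cohort[[outcome]]
  x <- cohort[[exposure]]
  if (!is.factor(y)) y <- factor(y)
  if (!is.factor(x)) x <- factor(x)
  if (nlevels(y) != 2L || nlevels(x) != 2L) {
    abort("outcome and exposure must both be binary")
  }
  case <- levels(y)[2]; exposed <- levels(x)[2]
  tab <- matrix(c(sum(x == exposed & y == case),
                  sum(x == exposed & y != case),
                  sum(x != exposed & y == case),
                  sum(x != exposed & y != case)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("exposed", "unexposed"),
                                c("case", "control")))
  chi <- pearson_chi_square(tab)
  or <- odds_ratio_wald(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
  adjusted <- if (length(covariates)) {
    fit_logistic_regression(cohort, outcome, exposure, covariates)
  }
  list(table = tab, chi2 = chi$chi2, df = chi$df, p = chi$p,
       or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
       pct_exposed_cases = proportion_pct(tab[1, 1], sum(tab[, 1])),
       pct_exposed_controls = proportion_pct(tab[1, 2], sum(tab[, 2])),
       adjusted = adjusted)
}
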