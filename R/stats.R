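#' Nonparametric two-group comparison with bootstrap CI
#'
#' Mann–Whitney/Wilcoxon rank-sum comparison of a value between two
#' groups, plus a percentile bootstrap confidence interval on the
#' difference of group means. The null distribution is exact when the
#' smaller group has at most 8 observations and the pooled values are
#' tie-free; otherwise the midrank normal approximation with tie and
#' continuity correction is used. The reported `statistic` is U for the
#' first group (number of pairs in which the first group's value exceeds
#' the second's).
#'
#' @param data A data frame.
#' @param value Column with the values to compare (tidy-eval).
#' @param group Column with the group labels; must have exactly two
#'   levels. The first level (factor order, or sorted unique values) is
#'   compared against the second.
#' @param n_boot Bootstrap resamples for the mean-difference CI.
#' @param conf_level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `pp_group_comparison`; see
#'   [tidy.pp_group_comparison()].
#' @examples
#' d <- tibble::tibble(
#'   sigma = c(1, 2, 3, 4, 5, 6),
#'   group = rep(c("a", "b"), each = 3)
#' )
#' tidy(compare_groups(d, sigma, group, n_boot = 200, seed = 1))
#' @export
compare_groups <- function(data, value, group, n_boot = 1e4,
                           conf_level = 0.95, seed = NULL) {
  vals <- dplyr::pull(data, {{ value }})
  grp <- dplyr::pull(data, {{ group }})
  if (!is.factor(grp)) grp <- factor(grp)
  grp <- droplevels(grp)
  if (nlevels(grp) != 2L) {
    abort(sprintf("`group` must have exactly 2 levels, got %d.", nlevels(grp)))
  }
  keep <- !is.na(vals) & !is.na(grp)
  vals <- vals[keep]
  grp <- grp[keep]
  x <- vals[grp == levels(grp)[1]]
  y <- vals[grp == levels(grp)[2]]
  if (length(x) < 1L || length(y) < 1L) abort("both groups must be non-empty.")

  use_exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y,
      alternative = "two.sided",
      exact = use_exact, correct = TRUE
    )
  )

  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- with_seed_if(seed, {
    bx <- matrix(sample(x, length(x) * n_boot, replace = TRUE), nrow = n_boot)
    by <- matrix(sample(y, length(y) * n_boot, replace = TRUE), nrow = n_boot)
    quantile(rowMeans(bx) - rowMeans(by), probs, names = FALSE)
  })

  structure(
    list(
      groups = levels(grp), n = c(length(x), length(y)),
      mean_difference = mean(x) - mean(y),
      conf_low = ci[1], conf_high = ci[2], conf_level = conf_level,
      statistic = unname(wt$statistic), p_value = wt$p.value,
      exact = use_exact, n_boot = n_boot
    ),
    class = "pp_group_comparison"
  )
}

#' @export
print.pp_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group comparison> %s (n=%d) vs %s (n=%d)\n",
    x$groups[1], x$n[1], x$groups[2], x$n[2]
  ))
  cat(sprintf(
    "  mean difference %.3f [%g%% CI %.3f, %.3f]; U = %g, p = %.3g (%s null)\n",
    x$mean_difference, 100 * x$conf_level, x$conf_low, x$conf_high,
    x$statistic, x$p_value, if (x$exact) "exact" else "approximate"
  ))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `pp_group_comparison`.
#' @param ... Unused.
#' @return One-row tibbles: `tidy()` with the estimate, CI, U statistic
#'   and p-value; `glance()` with sample sizes and bootstrap settings.
#' @export
tidy.pp_group_comparison <- function(x, ...) {
  tibble::tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    mean_difference = x$mean_difference,
    conf_low = x$conf_low, conf_high = x$conf_high,
    statistic = x$statistic, p_value = x$p_value
  )
}

#' @rdname tidy.pp_group_comparison
#' @export
glance.pp_group_comparison <- function(x, ...) {
  tibble::tibble(
    n1 = x$n[1], n2 = x$n[2], exact = x$exact,
    n_boot = x$n_boot, conf_level = x$conf_level
  )
}

# Simple-regression slopes for a set of bootstrap resamples, by the
# closed-form least-squares arithmetic (vectorised; resamples whose
# covariate is constant yield NA and are dropped from the percentiles).
boot_slopes <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  xb <- matrix(x[idx], nrow = n_boot)
  yb <- matrix(y[idx], nrow = n_boot)
  xc <- xb - rowMeans(xb)
  sxx <- rowSums(xc^2)
  slope <- rowSums(xc * yb) / sxx
  slope[sxx == 0] <- NA_real_
  intercept <- rowMeans(yb) - slope * rowMeans(xb)
  list(slope = slope, intercept = intercept)
}

#' Least-squares regression with bootstrap confidence intervals
#'
#' Ordinary least squares of an outcome on a single covariate, with
#' percentile confidence intervals from case (row) resampling — the
#' robust-to-non-normal-residuals inference route for small cohorts.
#' Homoskedasticity is assumed; no heteroskedasticity-consistent
#' covariance is applied.
#'
#' @param data A data frame.
#' @param formula A two-sided formula `outcome ~ covariate` with exactly
#'   one covariate.
#' @param n_boot Number of case resamples.
#' @param conf_level Confidence level.
#' @param seed Optional integer seed.
#' @return An object of class `pp_ols_boot`; see [tidy.pp_ols_boot()].
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
#' tidy(ols_bootstrap(d, y ~ x, n_boot = 200, seed = 1))
#' @export
ols_bootstrap <- function(data, formula, n_boot = 1e4,
                          conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(formula, "formula"))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  if (ncol(mf) != 2L) {
    abort("`formula` must have exactly one covariate (y ~ x).")
  }
  y <- mf[[1]]
  x <- mf[[2]]
  if (!is.numeric(x) || !is.numeric(y)) abort("both variables must be numeric.")
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete observations.")

  fit <- lm(formula, data = data)
  sm <- summary(fit)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  boots <- with_seed_if(seed, boot_slopes(x, y, n_boot))
  ci_slope <- quantile(boots$slope, probs, names = FALSE, na.rm = TRUE)
  ci_int <- quantile(boots$intercept, probs, names = FALSE, na.rm = TRUE)

  structure(
    list(
      terms = c("(Intercept)", attr(stats::terms(fit), "term.labels")),
      estimate = unname(coef(fit)),
      conf_low = c(ci_int[1], ci_slope[1]),
      conf_high = c(ci_int[2], ci_slope[2]),
      statistic = unname(sm$coefficients[, "t value"]),
      p_value = unname(sm$coefficients[, "Pr(>|t|)"]),
      r_squared = sm$r.squared, n = n,
      n_boot = n_boot, n_boot_dropped = sum(is.na(boots$slope)),
      conf_level = conf_level, fit = fit
    ),
    class = "pp_ols_boot"
  )
}

#' @export
print.pp_ols_boot <- function(x, ...) {
  cat(sprintf(
    "<bootstrap OLS> %s: beta = %.3f [%g%% CI %.3f, %.3f], R2 = %.3f, t(%d) = %.3f, p = %.3g\n",
    x$terms[2], x$estimate[2], 100 * x$conf_level,
    x$conf_low[2], x$conf_high[2], x$r_squared, x$n - 2L,
    x$statistic[2], x$p_value[2]
  ))
  invisible(x)
}

#' Tidy a bootstrap OLS fit
#'
#' @param x A `pp_ols_boot`.
#' @param ... Unused.
#' @return `tidy()`: one row per term with estimate, percentile CI,
#'   t statistic and p-value. `glance()`: R-squared, sample size and
#'   bootstrap settings.
#' @export
tidy.pp_ols_boot <- function(x, ...) {
  tibble::tibble(
    term = x$terms, estimate = x$estimate,
    conf_low = x$conf_low, conf_high = x$conf_high,
    statistic = x$statistic, p_value = x$p_value
  )
}

#' @rdname tidy.pp_ols_boot
#' @export
glance.pp_ols_boot <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, n = x$n, n_boot = x$n_boot,
    n_boot_dropped = x$n_boot_dropped, conf_level = x$conf_level
  )
}

#' Read a participant covariate table
#'
#' Comma-separated table keyed by a `participant` column, e.g. clinical
#' scores to regress psychophysical parameters on.
#'
#' @param path File path.
#' @return A tibble with a `participant` column.
#' @export
read_covariates <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"participant" %in% names(out)) {
    abort("covariate table must have a `participant` column.")
  }
  out
}
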