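#' Double-pass response consistency and bias
#'
#' Summarises the repeated trials of a log: `prob_agree` is the fraction
#' of repeated pairs answered identically on both passes (response
#' consistency); `prob_first` is the fraction of interval-1 choices over
#' the `2 * n_repeats` responses involved (response bias).
#'
#' @param log An experiment log with at least one trial whose `repeat_of`
#'   is set.
#' @return A one-row tibble: `prob_agree`, `prob_first`, `n_repeats`.
#' @examples
#' log <- simulate_experiment(make_sequence(seed = 1),
#'   observer_params(final_rise_template(6), sigma_internal = 1),
#'   seed = 2
#' )
#' double_pass_summary(log)
#' @export
double_pass_summary <- function(log) {
  one <- log[log$interval == 1L, c("trial", "repeat_of", "response")]
  one <- one[order(one$trial), ]
  reps <- one[!is.na(one$repeat_of), ]
  if (nrow(reps) == 0L) {
    abort("`log` contains no repeated (double-pass) trials.",
      class = "pp_no_repeats"
    )
  }
  first_pass <- one$response[match(reps$repeat_of, one$trial)]
  if (anyNA(first_pass)) {
    abort("`repeat_of` refers to trials missing from the log.")
  }
  second_pass <- reps$response
  tibble::tibble(
    prob_agree = mean(first_pass == second_pass),
    prob_first = mean(c(first_pass, second_pass) == 1L),
    n_repeats = nrow(reps)
  )
}

#' Forward double-pass model: Monte Carlo
#'
#' The idealised double-pass participant: per repeated pair the sensory
#' evidence `e ~ N(0, sqrt(2))` (difference of two unit-projected
#' stimuli, in stimulus-noise SD units) is fixed across the two passes,
#' while two independent internal-noise draws `z1, z2 ~ N(0, sigma)`
#' perturb the decision; pass `i` responds "interval 1" iff
#' `e + z_i > criterion`. Returns the empirical agreement and
#' first-option rates over `n_mc` simulated pairs.
#'
#' @param sigma Internal-noise SD, `>= 0`.
#' @param criterion Decision criterion.
#' @param n_mc Number of Monte Carlo double-pass pairs.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `prob_agree`, `prob_first`.
#' @examples
#' predict_consistency_bias(0, 0, 1000, seed = 1) # prob_agree exactly 1
#' @export
predict_consistency_bias <- function(sigma, criterion = 0, n_mc = 1e5,
                                     seed = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0, is_count(n_mc))
  with_seed_if(seed, {
    e <- rnorm(n_mc, 0, sqrt(2))
    z1 <- rnorm(n_mc, 0, sigma)
    z2 <- rnorm(n_mc, 0, sigma)
    r1 <- (e + z1) > criterion
    r2 <- (e + z2) > criterion
    tibble::tibble(
      prob_agree = mean(r1 == r2),
      prob_first = mean(c(r1, r2))
    )
  })
}

#' Forward double-pass model: numerical integration
#'
#' Closed-form counterpart of [predict_consistency_bias()], integrating
#' over the evidence distribution: with `p(e) = Phi((e - c) / sigma)`,
#' consistency is `E[p^2 + (1 - p)^2]` and bias is `E[p]`,
#' `e ~ N(0, sqrt(2))`. Used as an independent check of the Monte Carlo
#' route; exact at `sigma = 0`.
#'
#' @inheritParams predict_consistency_bias
#' @return A one-row tibble: `prob_agree`, `prob_first`.
#' @export
predict_consistency_bias_exact <- function(sigma, criterion = 0) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  s_e <- sqrt(2)
  if (sigma == 0) {
    pf <- 1 - pnorm(criterion / s_e)
    return(tibble::tibble(prob_agree = 1, prob_first = pf))
  }
  pa <- integrate(
    function(e) {
      p <- pnorm((e - criterion) / sigma)
      (p^2 + (1 - p)^2) * dnorm(e, 0, s_e)
    },
    -Inf, Inf, rel.tol = 1e-10
  )$value
  pf <- integrate(
    function(e) pnorm((e - criterion) / sigma) * dnorm(e, 0, s_e),
    -Inf, Inf, rel.tol = 1e-10
  )$value
  tibble::tibble(prob_agree = pa, prob_first = pf)
}

#' Simulate a double-pass session at the decision stage
#'
#' Draws `n_repeats` double-pass pairs from the forward model (fresh
#' evidence per pair, two internal-noise draws) and summarises them —
#' the generator used for parameter-recovery studies of the inversion.
#'
#' @inheritParams predict_consistency_bias
#' @param n_repeats Number of repeated pairs.
#' @return A one-row tibble: `prob_agree`, `prob_first`, `n_repeats`.
#' @export
simulate_double_pass <- function(sigma, criterion = 0, n_repeats = 50,
                                 seed = NULL) {
  out <- predict_consistency_bias(sigma, criterion, n_mc = n_repeats, seed = seed)
  dplyr::mutate(out, n_repeats = as.integer(n_repeats))
}

#' Precompute the inversion lookup grid
#'
#' Tabulates the forward model's (consistency, bias) predictions over the
#' exhaustive (sigma, criterion) search grid, using common random numbers:
#' one set of `n_mc` evidence and standard-normal internal-noise draws is
#' shared by every grid point (internal noise scaled by sigma), which
#' reduces Monte Carlo variance between neighbouring points and keeps the
#' error surface smooth. The grid is seed-stamped and reusable across
#' participants.
#'
#' At `sigma = 0` the internal-noise draws vanish, so `prob_agree` is
#' exactly 1 on that grid row.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed stamped into the grid.
#' @return An object of class `pp_noise_grid`: sigma and criterion grids
#'   plus `pa` and `pf` prediction matrices (sigma x criterion).
#' @examples
#' g <- noise_grid(grid_spec(n_mc = 1000), seed = 1)
#' dim(g$pa)
#' @export
noise_grid <- function(spec = grid_spec(), seed = 20201) {
  stopifnot(inherits(spec, "pp_grid_spec"))
  sigma <- seq(0, spec$sigma_max, by = spec$sigma_step)
  criterion <- seq(spec$criterion_min, spec$criterion_max,
    by = spec$criterion_step
  )
  n_mc <- spec$n_mc
  ns <- length(sigma)
  nc <- length(criterion)
  pa <- matrix(NA_real_, ns, nc)
  pf <- matrix(NA_real_, ns, nc)
  withr::with_seed(as.integer(seed), {
    e <- rnorm(n_mc, 0, sqrt(2))
    z1 <- rnorm(n_mc)
    z2 <- rnorm(n_mc)
    for (i in seq_len(ns)) {
      a1 <- e + sigma[i] * z1
      a2 <- e + sigma[i] * z2
      # response r = a > c; counts of a <= c via findInterval on sorted draws
      n_le_a1 <- findInterval(criterion, sort(a1))
      n_le_a2 <- findInterval(criterion, sort(a2))
      n_le_lo <- findInterval(criterion, sort(pmin(a1, a2)))
      n_le_hi <- findInterval(criterion, sort(pmax(a1, a2)))
      # disagreement iff min(a1,a2) <= c < max(a1,a2)
      pa[i, ] <- 1 - (n_le_lo - n_le_hi) / n_mc
      pf[i, ] <- 1 - (n_le_a1 + n_le_a2) / (2 * n_mc)
    }
  })
  # tie-break order for the argmin: smaller sigma, then smaller |criterion|
  sig_v <- rep(sigma, times = nc)
  crit_v <- rep(criterion, each = ns)
  structure(
    list(
      sigma = sigma, criterion = criterion, pa = pa, pf = pf,
      order = order(sig_v, abs(crit_v), crit_v),
      spec = spec, seed = as.integer(seed)
    ),
    class = "pp_noise_grid"
  )
}

#' @export
print.pp_noise_grid <- function(x, ...) {
  cat(sprintf(
    "<inversion grid> sigma [0, %g] step %g x criterion [%g, %g] step %g; %d MC pairs/point (seed %d)\n",
    x$spec$sigma_max, x$spec$sigma_step, x$spec$criterion_min,
    x$spec$criterion_max, x$spec$criterion_step, x$spec$n_mc, x$seed
  ))
  invisible(x)
}

# Default grid, built once per session and cached; the fixed seed stamp
# makes estimates deterministic functions of the observed summaries.
default_noise_grid <- function() {
  if (is.null(.pp_env$default_grid)) {
    .pp_env$default_grid <- noise_grid(grid_spec(), seed = 20201)
  }
  .pp_env$default_grid
}

#' Estimate internal noise and criterion from a double-pass summary
#'
#' Inverts the forward double-pass model by exhaustive search: over the
#' (sigma, criterion) grid, minimises the unweighted squared error
#' between the observed and predicted (consistency, bias) pair. Ties are
#' broken toward smaller sigma, then smaller absolute criterion. Internal
#' noise is searched conservatively in `[0, sigma_max]` (default 5 SD of
#' stimulus noise) because double-pass inversion is unreliable at large
#' values; estimates at or above `censor_at` are flagged `censored` —
#' they may be the true value or stand in for a larger one.
#'
#' @param summary A one-row tibble or list with `prob_agree`,
#'   `prob_first` (and optionally `n_repeats`), as from
#'   [double_pass_summary()].
#' @param grid A [noise_grid()]; `NULL` uses a cached default
#'   (sigma step 0.05 on `[0, 5]`, criterion step 0.05 on `[-3, 3]`,
#'   1e5 Monte Carlo pairs per point).
#' @param censor_at Censoring threshold on sigma.
#' @return An object of class `pp_noise_fit` with fields `sigma`,
#'   `criterion`, `fit_error`, `censored`, plus the observed summary;
#'   see [tidy.pp_noise_fit()].
#' @examples
#' estimate_internal_noise(list(prob_agree = 1, prob_first = 0.5),
#'   grid = noise_grid(grid_spec(n_mc = 1000), seed = 1)
#' )
#' @export
estimate_internal_noise <- function(summary, grid = NULL, censor_at = 4.8) {
  pa_obs <- summary$prob_agree
  pf_obs <- summary$prob_first
  if (!is_num1(pa_obs) || !is_num1(pf_obs) ||
    pa_obs < 0 || pa_obs > 1 || pf_obs < 0 || pf_obs > 1) {
    abort("`summary` must carry prob_agree and prob_first in [0, 1].")
  }
  grid <- grid %||% default_noise_grid()
  stopifnot(inherits(grid, "pp_noise_grid"))

  err <- (grid$pa - pa_obs)^2 + (grid$pf - pf_obs)^2
  best <- grid$order[which.min(err[grid$order])]
  ij <- arrayInd(best, dim(err))
  sigma <- grid$sigma[ij[1]]
  criterion <- grid$criterion[ij[2]]

  structure(
    list(
      sigma = sigma, criterion = criterion,
      fit_error = err[best],
      censored = sigma >= censor_at,
      prob_agree = pa_obs, prob_first = pf_obs,
      n_repeats = if (!is.null(summary[["n_repeats"]])) {
        as.integer(summary[["n_repeats"]])
      } else {
        NA_integer_
      },
      censor_at = censor_at,
      grid_seed = grid$seed, n_mc = grid$spec$n_mc
    ),
    class = "pp_noise_fit"
  )
}

#' @export
print.pp_noise_fit <- function(x, ...) {
  cat(sprintf(
    "<internal-noise fit> sigma = %.2f%s, criterion = %.2f (fit error %.2e)\n",
    x$sigma, if (x$censored) " [censored]" else "", x$criterion, x$fit_error
  ))
  cat(sprintf(
    "  observed: consistency %.3f, bias %.3f over %s repeats\n",
    x$prob_agree, x$prob_first,
    if (is.na(x$n_repeats)) "?" else x$n_repeats
  ))
  invisible(x)
}

#' Tidy an internal-noise fit
#'
#' @param x A `pp_noise_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row with `sigma`, `criterion`, `fit_error`,
#'   `censored`, `prob_agree`, `prob_first`, `n_repeats`. `glance()`:
#'   one row of fit metadata (grid seed, Monte Carlo size, censoring
#'   threshold).
#' @export
tidy.pp_noise_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma, criterion = x$criterion, fit_error = x$fit_error,
    censored = x$censored, prob_agree = x$prob_agree,
    prob_first = x$prob_first, n_repeats = x$n_repeats
  )
}

#' @rdname tidy.pp_noise_fit
#' @export
glance.pp_noise_fit <- function(x, ...) {
  tibble::tibble(
    fit_error = x$fit_error, censor_at = x$censor_at,
    grid_seed = x$grid_seed, n_mc = x$n_mc
  )
}

#' Estimate internal noise directly from a log
#'
#' Composition of [double_pass_summary()] and
#' [estimate_internal_noise()].
#'
#' @inheritParams double_pass_summary
#' @inheritParams estimate_internal_noise
#' @return A `pp_noise_fit`.
#' @export
estimate_from_log <- function(log, grid = NULL, censor_at = 4.8) {
  estimate_internal_noise(double_pass_summary(log),
    grid = grid, censor_at = censor_at
  )
}

#' Internal-noise estimates for a whole cohort
#'
#' @param cohort A cohort tibble with a `log` list-column, as from
#'   [generate_cohort()].
#' @inheritParams estimate_internal_noise
#' @return A tibble with one row per participant: identifiers (plus
#'   `sigma_true` when present) and the tidied fit columns.
#' @export
estimate_cohort_noise <- function(cohort, grid = NULL, censor_at = 4.8) {
  stopifnot(is.data.frame(cohort), "log" %in% names(cohort))
  grid <- grid %||% default_noise_grid()
  fits <- purrr::map(
    cohort$log,
    function(log) tidy(estimate_from_log(log, grid = grid, censor_at = censor_at))
  )
  meta <- dplyr::select(
    cohort,
    dplyr::any_of(c("participant", "group", "sigma_true"))
  )
  dplyr::bind_cols(meta, dplyr::bind_rows(fits))
}

#' Read and write internal-noise estimate tables
#'
#' Comma-separated, one row per participant with columns `participant`,
#' `sigma`, `criterion`, `fit_error`, `censored`, `n_repeats`,
#' `prob_agree`, `prob_first` (plus any extra columns present).
#'
#' @param estimates An estimates tibble, e.g. from
#'   [estimate_cohort_noise()].
#' @param path File path.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(estimates, path, progress = FALSE)
  invisible(estimates)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("censored" %in% names(out)) out$censored <- as.logical(out$censored)
  if ("n_repeats" %in% names(out)) out$n_repeats <- as.integer(out$n_repeats)
  out
}
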