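test_that("double-pass summaries hit their deterministic limits", {
  log <- sim_log(sigma = 0, seed = 22)
  s <- double_pass_summary(log)
  expect_identical(s$prob_agree, 1)
  expect_equal(s$n_repeats, 50L)

  log$response <- rep(1L, nrow(log))
  s1 <- double_pass_summary(log)
  expect_identical(s1$prob_agree, 1)
  expect_identical(s1$prob_first, 1)

  expect_error(
    double_pass_summary(log[is.na(log$repeat_of), ]),
    class = "pp_no_repeats"
  )
})

test_that("observed consistency matches the closed form for the full observer", {
  # e through the template is attenuated by the clip bound, so the oracle
  # integrates over N(0, sqrt(2 * truncated-variance ratio))
  d <- seq_design(n_blocks = 2, block_size = 3000, n_repeats = 3000)
  log <- sim_log(sigma = 1, seed = 23, design = d)
  s <- double_pass_summary(log)
  s_e <- sqrt(2 * truncnorm_var(2.2))
  pa <- integrate(function(e) {
    p <- pnorm(e / 1)
    (p^2 + (1 - p)^2) * dnorm(e, 0, s_e)
  }, -Inf, Inf)$value
  expect_lt(abs(s$prob_agree - pa), 3 * sqrt(pa * (1 - pa) / 3000))
  expect_lt(abs(s$prob_first - 0.5), 3 * sqrt(0.25 / 6000))
})

test_that("the forward model hits its analytic limits", {
  for (crit in c(-1, 0, 0.7)) {
    p <- predict_consistency_bias(0, crit, 5000, seed = 1)
    expect_identical(p$prob_agree, 1) # no internal noise, no disagreement
  }
  p <- predict_consistency_bias(1.5, 0, 2e5, seed = 2)
  expect_lt(abs(p$prob_first - 0.5), 3 * sqrt(0.25 / 4e5))
  p <- predict_consistency_bias(100, 0, 2e5, seed = 3)
  expect_lt(abs(p$prob_agree - 0.5), 3 * sqrt(0.25 / 2e5))
})

test_that("Monte Carlo and quadrature forward models agree pointwise", {
  n <- 1e5
  for (sigma in c(0.5, 1, 3)) {
    for (crit in c(-0.5, 0, 1)) {
      mc <- predict_consistency_bias(sigma, crit, n, seed = 101)
      ex <- predict_consistency_bias_exact(sigma, crit)
      expect_lt(
        abs(mc$prob_agree - ex$prob_agree),
        3 * sqrt(ex$prob_agree * (1 - ex$prob_agree) / n)
      )
      expect_lt(
        abs(mc$prob_first - ex$prob_first),
        3 * sqrt(ex$prob_first * (1 - ex$prob_first) / n)
      )
    }
  }
})

test_that("grid predictions are monotone and exact at the noise floor", {
  g <- prosodpass:::default_noise_grid()
  expect_equal(dim(g$pa), c(101, 121))
  expect_true(all(g$pa[1, ] == 1)) # sigma = 0 row: perfect consistency
  # common random numbers: consistency non-increasing in sigma (tiny MC
  # jitter tolerated), bias exactly non-increasing in criterion
  expect_true(all(apply(g$pa, 2, function(col) all(diff(col) < 2e-3))))
  expect_true(all(apply(g$pf, 1, function(row) all(diff(row) <= 0))))
  # common random numbers: a grid cell reproduces the standalone forward
  # model run at the grid's own seed, exactly
  i <- which.min(abs(g$sigma - 1.5))
  j <- which.min(abs(g$criterion - 0.5))
  p <- predict_consistency_bias(g$sigma[i], g$criterion[j], g$spec$n_mc,
    seed = g$seed
  )
  expect_equal(g$pa[i, j], p$prob_agree, tolerance = 1e-12)
  expect_equal(g$pf[i, j], p$prob_first, tolerance = 1e-12)
})

test_that("inversion recovers the noise-free symmetric observer exactly", {
  fit <- estimate_internal_noise(list(prob_agree = 1, prob_first = 0.5))
  expect_equal(fit$sigma, 0)
  expect_lte(abs(fit$criterion), 0.05)
  expect_false(fit$censored)
})

test_that("inversion is self-consistent on forward-model summaries", {
  s <- predict_consistency_bias(2.0, 0.5, 1e6, seed = 55)
  fit <- estimate_internal_noise(s)
  expect_lt(abs(fit$sigma - 2.0), 0.2)
  expect_lt(abs(fit$criterion - 0.5), 0.2)
  expect_gte(fit$sigma, 0)
  expect_lte(fit$sigma, 5)
})

test_that("estimates are deterministic given the seed-stamped grid", {
  s <- list(prob_agree = 0.7, prob_first = 0.45)
  f1 <- tidy(estimate_internal_noise(s))
  f2 <- tidy(estimate_internal_noise(s))
  expect_identical(f1, f2)
  g <- noise_grid(grid_spec(n_mc = 2e4), seed = 7)
  expect_identical(
    tidy(estimate_internal_noise(s, grid = g)),
    tidy(estimate_internal_noise(s, grid = g))
  )
})

test_that("incoherent summaries censor at the top of the search range", {
  # coin-flip consistency is unreachable at finite noise: the search runs
  # into the sigma ceiling and must flag it
  fit <- estimate_internal_noise(list(prob_agree = 0.5, prob_first = 0.5))
  expect_lte(fit$sigma, 5)
  expect_true(fit$censored)
  expect_gte(fit$sigma, 4.8)
})

test_that("estimation composes from raw logs for both repeat variants", {
  for (d in list(seq_design(), seq_design(n_repeats = 25))) {
    log <- sim_log(sigma = 0, seed = 24, design = d)
    fit <- estimate_from_log(log)
    expect_lte(fit$sigma, 0.05)
    expect_equal(fit$n_repeats, d$n_repeats)
  }
})

test_that("cohort estimation returns one tidy row per participant", {
  cohort <- generate_cohort(
    dplyr::bind_rows(
      cohort_spec("a", 2, 0.5, 0),
      cohort_spec("b", 2, 3, 0)
    ),
    seed = 25
  )
  est <- estimate_cohort_noise(cohort)
  expect_equal(nrow(est), 4)
  expect_true(all(c(
    "participant", "group", "sigma_true", "sigma", "criterion",
    "fit_error", "censored", "prob_agree", "prob_first", "n_repeats"
  ) %in% names(est)))
  expect_true(all(est$sigma >= 0 & est$sigma <= 5))
  expect_identical(est$censored, est$sigma >= 4.8)

  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, path)
  expect_equal(
    as.data.frame(read_estimates(path)),
    as.data.frame(est)
  )
})
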