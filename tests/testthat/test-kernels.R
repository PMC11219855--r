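mk_kernel <- function(w) {
  tibble::tibble(
    segment = seq_along(w), weight = w,
    n_trials = NA_integer_, normalized = FALSE
  )
}

test_that("RMS normalisation matches closed forms and is idempotent", {
  k1 <- normalize_kernel(mk_kernel(rep(1, 6)))
  expect_equal(k1$weight, rep(1, 6)) # RMS already 1

  k2 <- normalize_kernel(mk_kernel(c(2, 0, 0, 0, 0, 0)))
  expect_equal(k2$weight, c(sqrt(6), 0, 0, 0, 0, 0)) # RMS = 2/sqrt(6)

  k3 <- normalize_kernel(mk_kernel(rnorm(6)))
  expect_equal(sqrt(mean(k3$weight^2)), 1, tolerance = 1e-14)
  expect_equal(normalize_kernel(k3)$weight, k3$weight) # idempotent

  expect_error(normalize_kernel(mk_kernel(rep(0, 6))),
    class = "pp_degenerate_kernel"
  )
  expect_error(normalize_kernel(mk_kernel(rep(1e-12, 6))),
    class = "pp_degenerate_kernel"
  )
})

test_that("typicality is zero at identity, four at sign flip, and guarded", {
  k <- normalize_kernel(mk_kernel(c(0.2, -0.1, 0.5, 1, 2, 3)))
  expect_identical(typicality(k, k), 0)
  flipped <- dplyr::mutate(k, weight = -weight)
  expect_equal(typicality(k, flipped), 4, tolerance = 1e-12)

  expect_error(typicality(mk_kernel(1:6), k), class = "pp_unnormalized_kernel")
  k5 <- normalize_kernel(mk_kernel(1:5))
  expect_error(typicality(k, k5), class = "pp_dim_mismatch")
})

test_that("coin-flip responses give a flat kernel", {
  log <- big_log(10000, sigma = 0, seed = 14)
  log$response <- withr::with_seed(77, rep(sample(1:2, 10000, TRUE), each = 2))
  k <- compute_kernel(log)
  # chosen-minus-unchosen difference per trial has SD sqrt(2) x stimulus SD
  se <- sqrt(2) * sqrt(truncnorm_var(2.2)) * 70 / sqrt(10000)
  expect_true(all(abs(k$weight) < 3 * se))
})

test_that("a max-shift picker yields the max-minus-min conditional mean", {
  n <- 10000
  log <- big_log(n, sigma = 0, seed = 15)
  s6_1 <- log$s6[log$interval == 1]
  s6_2 <- log$s6[log$interval == 2]
  log$response <- rep(ifelse(s6_1 > s6_2, 1L, 2L), each = 2)
  k <- compute_kernel(log)

  # oracle: direct Monte Carlo of E[max - min] of two truncated draws,
  # independent of the kernel estimator
  o <- withr::with_seed(99, {
    a <- as.matrix(sample_profiles(5e5, stim_config()))[, 1]
    b <- as.matrix(sample_profiles(5e5, stim_config()))[, 2]
    mean(pmax(a, b) - pmin(a, b))
  })
  sd_d <- sqrt(2) * sqrt(truncnorm_var(2.2)) * 70
  expect_lt(abs(k$weight[6] - o), 3 * sd_d / sqrt(n))
  expect_true(all(abs(k$weight[1:5]) < 3 * sd_d / sqrt(n)))
})

test_that("the kernel of a noise-free observer converges to its template", {
  k <- compute_kernel(big_log(1e5, sigma = 0, seed = 16))
  expect_gt(kernel_cosine(k, tmpl6), 0.99)
})

test_that("kernel amplitude attenuates monotonically with internal noise", {
  u <- tmpl6 / sqrt(sum(tmpl6^2))
  proj <- vapply(c(0, 1, 2, 4), function(sigma) {
    k <- compute_kernel(big_log(2e4, sigma = sigma, seed = 17))
    sum(k$weight * u)
  }, numeric(1))
  expect_true(all(diff(proj) < 0))
  expect_true(all(proj > 0))
})

test_that("group averaging and leave-one-out typicality behave consistently", {
  cohort <- generate_cohort(cohort_spec("control", 4, 0, 0), seed = 18)
  kern <- cohort_kernels(cohort)
  expect_equal(nrow(kern), 4 * 6)
  expect_true(all(kern$normalized))

  avg <- group_average_kernel(kern)
  expect_equal(sqrt(mean(avg$weight^2)), 1, tolerance = 1e-14)

  # leave-one-out excludes exactly the named participant
  loo <- group_average_kernel(kern, leave_out = "control_01")
  manual <- group_average_kernel(
    dplyr::filter(kern, participant != "control_01")
  )
  expect_equal(loo$weight, manual$weight)

  # zero-noise observers sharing a template: leave-one-out typicality at
  # 150 trials is dominated by kernel estimation noise, whose expected
  # MSE is well under the ~0.3 scale (it vanishes with n_trials; see the
  # convergence test below)
  scores <- typicality_scores(kern)
  expect_equal(nrow(scores), 4)
  expect_true(all(scores$typicality < 0.3))

  # explicit reference route agrees with a hand computation
  ref <- group_average_kernel(kern)
  s2 <- typicality_scores(kern, reference = ref)
  k1 <- dplyr::filter(kern, participant == "control_01")
  expect_equal(s2$typicality[1], typicality(k1, ref))
})

test_that("typicality of estimated kernels vanishes as trials grow", {
  # consistency of the kernel estimator: two zero-noise observers with the
  # same template get closer to each other as n_trials grows
  t_at <- vapply(c(300, 3000), function(n) {
    ka <- normalize_kernel(compute_kernel(big_log(n, 0, seed = 41)))
    kb <- normalize_kernel(compute_kernel(big_log(n, 0, seed = 42)))
    typicality(ka, kb)
  }, numeric(1))
  expect_lt(t_at[2], t_at[1])
  expect_lt(t_at[2], 0.01)
})

test_that("logs truncate to the first trials in presentation order", {
  log <- sim_log(seed = 19)
  short <- truncate_log(log, 40)
  expect_equal(unique(short$trial), 1:40)
  expect_equal(
    short[short$trial == 7, ],
    log[log$trial == 7, ],
    ignore_attr = TRUE
  )
  expect_error(truncate_log(log, 0))
})

test_that("kernels round-trip through CSV", {
  k <- normalize_kernel(compute_kernel(sim_log(seed = 20)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel(k, path)
  expect_equal(as.data.frame(read_kernel(path)), as.data.frame(k))
})
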