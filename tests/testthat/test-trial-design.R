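test_that("sampled shifts respect the clip bound and the truncated-normal SD", {
  cfg <- stim_config() # 70 cents, bound 2.2 SD -> [-154, 154]
  m <- as.matrix(sample_profiles(2e5, cfg, seed = 11))
  bound <- cfg$clip_sd * cfg$noise_sd_cents
  expect_true(all(abs(m) <= bound))
  expect_true(all(is.finite(m)))

  # oracle: numerically integrated variance of the +/- 2.2 truncated unit
  # normal, scaled by the stimulus SD
  expect_equal(
    sd(as.numeric(m)),
    sqrt(truncnorm_var(cfg$clip_sd)) * cfg$noise_sd_cents,
    tolerance = 0.01
  )

  # hard clipping piles mass on the bound and has a larger SD
  mh <- as.matrix(sample_profiles(2e5, cfg, clip_method = "hard", seed = 11))
  expect_true(all(abs(mh) <= bound))
  expect_gt(mean(abs(mh) == bound), 0)
  expect_gt(sd(as.numeric(mh)), sd(as.numeric(m)))
})

test_that("vanishing stimulus noise yields all-zero profiles in the limit", {
  m <- as.matrix(sample_profiles(100, stim_config(noise_sd_cents = 1e-9),
    seed = 3
  ))
  expect_true(all(abs(m) < 1e-8))
})

test_that("sampling and sequence assembly are seed-deterministic", {
  expect_identical(
    sample_profiles(50, seed = 7),
    sample_profiles(50, seed = 7)
  )
  s1 <- make_sequence(seed = 42)
  s2 <- make_sequence(seed = 42)
  expect_identical(s1, s2)
  expect_false(identical(
    make_sequence(seed = 1)$s1,
    make_sequence(seed = 2)$s1
  ))
})

test_that("the canonical design yields 150 trials with an exact repeated block", {
  seqn <- make_sequence(seq_design(), stim_config(), seed = 5)
  expect_equal(nrow(seqn), 300) # 150 trials x 2 intervals
  expect_equal(max(seqn$trial), 150)
  expect_equal(sort(unique(seqn$block)), 1:3)
  expect_equal(sum(!is.na(seqn$repeat_of)) / 2, 50)

  scols <- paste0("s", 1:6)
  reps <- seqn[!is.na(seqn$repeat_of), ]
  for (r in seq_len(nrow(reps))) {
    src <- seqn[seqn$trial == reps$repeat_of[r] &
      seqn$interval == reps$interval[r], ]
    expect_identical(
      as.numeric(reps[r, scols]),
      as.numeric(src[, scols])
    )
  }
  # repeats sit in block 3 and point to block 1, same within-block position
  expect_true(all(seqn$block[!is.na(seqn$repeat_of)] == 3))
  expect_equal(
    unique(reps$trial - reps$repeat_of),
    2 * 50
  )

  # fresh stimuli are pairwise distinct
  fresh <- seqn[is.na(seqn$repeat_of), scols]
  expect_equal(anyDuplicated(fresh), 0)
})

test_that("the 25-repeat variant and shuffled repeats keep repeat integrity", {
  for (args in list(
    list(design = seq_design(n_repeats = 25), shuffle = FALSE),
    list(design = seq_design(), shuffle = TRUE)
  )) {
    seqn <- make_sequence(args$design, stim_config(),
      shuffle_repeats = args$shuffle, seed = 9
    )
    n_rep <- sum(!is.na(seqn$repeat_of)) / 2
    expect_equal(n_rep, args$design$n_repeats)
    scols <- paste0("s", 1:6)
    reps <- seqn[!is.na(seqn$repeat_of), ]
    for (r in seq_len(nrow(reps))) {
      src <- seqn[seqn$trial == reps$repeat_of[r] &
        seqn$interval == reps$interval[r], ]
      expect_identical(as.numeric(reps[r, scols]), as.numeric(src[, scols]))
    }
  }
})

test_that("invalid designs and configurations are rejected with all violations", {
  expect_error(seq_design(n_repeats = 0), class = "pp_invalid_design")
  expect_error(seq_design(n_repeats = 51), class = "pp_invalid_design")
  expect_error(
    seq_design(repeat_source_block = 2, repeat_target_block = 2),
    class = "pp_invalid_design"
  )
  expect_error(seq_design(repeat_target_block = 9), class = "pp_invalid_design")
  expect_error(stim_config(noise_sd_cents = -1), class = "pp_invalid_config")
  expect_error(stim_config(n_segments = 0), class = "pp_invalid_config")
})

test_that("breakpoint files carry segment-midpoint times and round-trip values", {
  cfg <- stim_config()
  shifts <- c(-30, 10, 0, 25, 50, 100)
  tab <- bpf_table(shifts, cfg)
  expect_equal(tab$time_s, (1:6 - 0.5) * 0.071)
  expect_equal(tab$shift_cents, shifts)

  dir <- withr::local_tempdir()
  seqn <- make_sequence(seq_design(
    n_blocks = 2, block_size = 2,
    n_repeats = 1
  ), cfg, seed = 2)
  paths <- export_bpfs(seqn, dir)
  expect_length(paths, nrow(seqn))
  back <- read.delim(paths[1], header = FALSE)
  expect_equal(ncol(back), 2)
  expect_equal(back[[1]], tab$time_s)
  expect_equal(back[[2]], as.numeric(seqn[1, paste0("s", 1:6)]))
})

test_that("sequence manifests round-trip losslessly through CSV", {
  seqn <- make_sequence(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequence(seqn, path)
  back <- read_sequence(path)
  expect_equal(as.data.frame(back), as.data.frame(seqn), ignore_attr = TRUE)
})
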