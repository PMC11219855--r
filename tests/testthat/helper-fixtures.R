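# Shared fixtures: everything is generated in code under fixed seeds.

default_cfg <- stim_config()
default_design <- seq_design()
tmpl6 <- final_rise_template(6)

# One simulated session under the canonical design.
sim_log <- function(sigma = 1, criterion = 0, seed = 1,
                    design = default_design, cfg = default_cfg,
                    template = tmpl6) {
  withr::with_seed(seed, {
    seqn <- make_sequence(design, cfg)
    simulate_experiment(seqn, observer_params(template, sigma, criterion), cfg)
  })
}

# A log of exactly n fresh-ish trials (one structural repeat) for kernel
# estimation at arbitrary trial counts.
big_log <- function(n_trials, sigma = 0, seed = 1, cfg = default_cfg,
                    template = tmpl6) {
  d <- seq_design(
    n_blocks = 2, block_size = ceiling(n_trials / 2),
    n_repeats = 1
  )
  truncate_log(sim_log(sigma, 0, seed, d, cfg, template), n_trials)
}

# Variance of the unit normal truncated at +/- a, by numerical
# integration (independent oracle for the stimulus sampler and for the
# evidence scale of the full observer).
truncnorm_var <- function(a) {
  z <- integrate(function(x) dnorm(x), -a, a)$value
  integrate(function(x) x^2 * dnorm(x), -a, a)$value / z
}

# Exhaustive-permutation null of the rank-sum statistic: the independent
# oracle for U and the exact two-sided p-value.
enum_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_null <- apply(
    utils::combn(length(pooled), n1), 2,
    function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  )
  p <- min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
  list(U = u_obs, p = p)
}

# Warm the package's cached default inversion grid once per test run.
invisible(prosodpass:::default_noise_grid())
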