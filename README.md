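# prosodpass

Double-pass reverse correlation for speech prosody perception:
estimate, participant by participant, the *internal representation* an
individual uses to decide that an utterance sounds like a question, and
the *internal noise* that governs how consistently they apply it.

The package is aimed at auditory psychophysicists and clinical
researchers studying receptive aprosodia (e.g. after right-hemisphere
stroke), where the representation + noise decomposition separates
patients with distorted prosodic templates from patients who hold a
normal template but apply it erratically.

## The method

A base utterance is divided into `m` segments (default 6 × 71 ms) and the
pitch of each segment is shifted independently by
`s_k ~ N(0, 70 cents)`, bounded at ±2.2 SD ("stimulus noise"). On each
2AFC trial the listener hears two such manipulated utterances and picks
the one that sounds most interrogative; a 150-pair session is arranged
in 3 blocks of 50 with one block re-presented verbatim later in the
sequence (the *double-pass* manipulation).

Two parameters are then estimated per participant:

- **Internal representation (classification image).** Per segment, the
  mean shift of the chosen stimuli minus the mean shift of the unchosen
  stimuli, normalised by its root mean square:
  `K_k = E[s_k | chosen] − E[s_k | unchosen]`, `K ← K / RMS(K)`.
  *Representation typicality* is the mean squared error between an
  individual's normalised kernel and a (leave-one-out) reference-group
  average — higher MSE, less typical.

- **Internal noise.** The simulated two-stage observer compares each
  pair against a unit-norm template `u`, forming evidence
  `e = u·(s₁ − s₂)/σ_ext`, and adds Gaussian internal noise
  `z ~ N(0, σ)` before thresholding against a criterion `c`. Across the
  repeated pairs, response *consistency* `P(agree)` and *bias* `P(first)`
  have closed forms under `e ~ N(0, √2)`; the estimator tabulates them by
  Monte Carlo over an exhaustive grid `σ ∈ [0, 5] × c ∈ [−3, 3]` (step
  0.05) and inverts the observed (consistency, bias) pair by
  least-squares. Estimates at the top of the range (σ ≥ 4.8) are flagged
  censored: double-pass inversion cannot distinguish them from larger
  values. σ is expressed in units of the stimulus-noise SD.

Group-level tooling mirrors the typical cohort analysis: Mann–Whitney
rank-sum comparisons with percentile-bootstrap CIs on mean differences,
and OLS regressions of the psychophysical parameters on clinical
covariates with case-resampling bootstrap CIs.

## Worked example

```r
library(prosodpass)

# one participant: canonical design, sigma = 1 template-matching observer
seqn <- make_sequence(seq_design(), stim_config(), seed = 1)
obs  <- observer_params(final_rise_template(6), sigma_internal = 1)
log  <- simulate_experiment(seqn, obs, participant = "demo", seed = 2)

double_pass_summary(log)
#> # A tibble: 1 × 3
#>   prob_agree prob_first n_repeats
#>        <dbl>      <dbl>     <int>
#> 1       0.62       0.59        50

estimate_from_log(log)
#> <internal-noise fit> sigma = 2.00, criterion = -0.55 (fit error 3.52e-07)
#>   observed: consistency 0.620, bias 0.590 over 50 repeats

k <- normalize_kernel(compute_kernel(log))
kernel_cosine(k, final_rise_template(6))
#> [1] 0.9775802
```

With only 50 repeated pairs the noise estimate is itself noisy (here 2.0
for a true σ of 1 — single-session estimates have an SE of roughly
0.3–0.5 at this scale); the kernel nevertheless recovers the final-rise template
direction (cosine 0.98), with the largest weights on the last two
segments.

A full two-group study — 21 "control-like" observers with
σ ~ N(0.7, 0.37²) truncated at 0 and 22 "patient-like" observers with
σ ~ N(2.54, 1.90²), all sharing the final-rise template — runs end to
end in a few seconds:

```r
study <- run_group_study(n_boot = 2000, seed = 1)
study
#> <group study>
#>   control: n = 21, internal noise M = 0.88 (SD = 0.50)
#>   patient: n = 22, internal noise M = 3.51 (SD = 1.68)
#>   noise: U = 19.5, p = 2.14e-07 | typicality: U = 58, p = 2.78e-05
```

Both parameters separate the groups: the noisier group is estimated at
much higher internal noise, and its kernels — degraded by that noise —
score as less typical against the control average. `plot_kernels()`,
`plot_noise_estimates()` and the `autoplot()` methods visualise these
results; `tidy()`/`glance()` return the statistics as tibbles.

A command-line front end (`exec/prosodpass`) exposes the pipeline as
subcommands (`generate`, `simulate`, `kernel`, `noise`, `cohort-stats`,
`demo`); `inst/extdata/default_config.yaml` is the canonical run
configuration.

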