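---
title: "Representation + noise psychophysics for prosody: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representation + noise psychophysics for prosody: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosodpass)
```

## The model

`prosodpass` implements a two-stage account of how a listener decides
which of two pitch-manipulated utterances sounds more interrogative.

**Stimulus stage.** A base utterance is split into `n_segments` segments
(default 6, of 71 ms each) and the pitch at each segment's breakpoint is
shifted by an independent draw from `N(0, noise_sd_cents²)` (default SD
70 cents), bounded at `clip_sd` SD (default 2.2, i.e. ±154 cents). These
per-segment shifts — not any rendered audio — are the analysis objects;
`bpf_table()`/`export_bpfs()` emit the breakpoint files an external
pitch-shifting tool needs to synthesise the sounds.

**Decision stage.** The observer holds a prosodic template `t`
(normalised internally to the unit vector `u`), forms the evidence

    e = u · (s₁ − s₂) / σ_ext,

adds internal noise `z ~ N(0, σ²)`, and answers "interval 1" iff
`e + z > c`. The scale deserves emphasis because everything downstream
depends on it: dividing by the stimulus-noise SD `σ_ext` puts `e` in SD
units of the stimulus noise *as seen through the unit-norm template*, so
`σ` and `c` are dimensionless multiples of the external noise. This is
the only convention under which "internal noise in units of the
stimulus-noise SD" is well defined for a linear observer, and the
double-pass estimator below uses the identical convention — estimates
are only interpretable because the two sides agree.

For unbounded stimulus noise `e ~ N(0, √2)` exactly (difference of two
independent unit projections). The ±2.2 SD bound shrinks each
projection's variance by the truncated-variance ratio (≈ 0.839), so
evidence from the full stimulus pipeline has variance ≈ 1.68 rather
than 2. The inversion deliberately keeps the idealised `N(0, √2)`
evidence model (see *Known limitations*).

## Estimators

**Classification image.** `compute_kernel()` takes, per segment, the
mean shift of chosen minus unchosen stimuli; `normalize_kernel()`
rescales to unit RMS. For the linear observer the expected kernel is
proportional to the generating template, with amplitude shrinking as
internal noise grows — the tests verify this monotone attenuation across
σ ∈ {0, 1, 2, 4}. *Typicality* (`typicality()`) is the raw MSE between
two normalised kernels: 0 at identity, 4 at a sign flip. We keep the raw
MSE (larger = less typical) rather than folding it into a similarity,
and let analysts choose signs in regressions.

**Double-pass internal noise.** `double_pass_summary()` reduces the
repeated trials to response consistency (fraction of pairs answered
identically on both passes) and bias (fraction of "interval 1" over the
`2 × n_repeats` responses involved). `noise_grid()` tabulates the
forward model's predictions on an exhaustive grid — σ from 0 to 5 in
steps of 0.05, c from −3 to 3 in steps of 0.05, 10⁵ Monte Carlo
double-pass pairs per grid point — and `estimate_internal_noise()`
returns the grid point minimising the unweighted squared error on the
(consistency, bias) pair.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `n_segments`, `segment_ms` | 6, 71 | —, ms | segments of the base utterance's pitch contour |
| `noise_sd_cents` | 70 | cents | stimulus noise large enough to drive decisions, small enough to stay speech-like |
| `clip_sd` | 2.2 | SD | keeps extreme shifts inside a natural-sounding range |
| blocks | 3 × 50, one block repeated | trials | 150 pairs ≈ 15 min of testing; 25- and 50-repeat variants both supported |
| σ search range | [0, 5] | stimulus-noise SD | conservative cap: double-pass inversion is unreliable above it |
| censoring threshold | 4.8 | stimulus-noise SD | estimates in [4.8, 5] may stand in for larger true values; configurable |
| grid step | 0.05 | — | quantisation error (±0.025) well below the sampling error of any realistic session |
| `n_mc` | 10⁵ | pairs/grid point | Monte Carlo SE ≈ 0.0016 per prediction, below one grid step's effect |

## What the simulator emulates — and what it does not

`generate_cohort()` and `run_group_study()` are first-class simulators,
not test scaffolding: they reproduce the study conditions — iid bounded
Gaussian pitch perturbations, 150-pair sessions with a verbatim repeated
block, linear-template decisions with additive Gaussian internal noise,
and group-level noise distributions truncated-normal (0.7, 0.37) for the
control-like group and (2.54, 1.90) for the patient-like group (the
cohort means and SDs reported for those populations).

The simulator does *not* emulate: learning or fatigue across trials,
lapses, sequential dependencies, non-Gaussian or early (sensory-stage)
internal noise, template uncertainty within a participant, or any
audio-level confound (loudness, timbre). Passing tests therefore show
that the estimators invert the stated observer model at realistic sample
sizes — not that real listeners satisfy that model.

## Numerical choices

- **Truncation vs clipping.** "Bounded at ±2.2 SD" admits two readings.
  The default resamples (inverse-CDF truncated normal, a smooth density
  inside the bound); `clip_method = "hard"` instead projects onto the
  bound, piling mass at ±154 cents and slightly inflating the SD. The
  two differ in their moments; tests pin the truncated SD to a
  numerically integrated oracle.
- **Common random numbers.** One set of evidence and standard-normal
  internal-noise draws is shared across all grid points (scaled by σ).
  This makes the error surface smooth in σ, makes a grid cell exactly
  reproduce a standalone forward-model run at the grid's seed, and gives
  bias predictions that are exactly monotone in the criterion.
- **Tie-breaking.** The argmin over the grid prefers smaller σ, then
  smaller |c|: a perfectly consistent, unbiased summary maps to (0, ~0)
  rather than an arbitrary tied cell.
- **Degenerate kernels.** RMS below 10⁻⁹ cents (possible for random
  responders at tiny trial counts) raises an explicit error instead of
  silently dividing by ~0.
- **Exact vs approximate rank-sum null.** Exact enumeration when the
  smaller group has ≤ 8 tie-free observations; midrank normal
  approximation with tie and continuity correction otherwise. The test
  suite checks U and the exact p against brute-force enumeration of all
  assignments for group sizes up to 7.

## Open design choices, and why we settled them this way

- **Evidence distribution of the idealised model.** The double-pass
  literature requires fixing one; we use `N(0, √2)` at the decision
  stage, matching the observer's units contract. Estimates from
  full-pipeline simulations consequently carry a small (~9%) upward
  scale bias from the clip-induced evidence attenuation — visible in the
  recovery tests' tolerance bands, and irrelevant to between-group
  contrasts, which is what the method is used for.
- **Joint (σ, c) search.** Whether to fix the criterion from observed
  bias or search it jointly is underdetermined; we search jointly, since
  bias is explicitly part of the fitting target, and report both.
- **Reference kernel for typicality.** Members of the reference group
  are scored leave-one-out; other participants are scored against the
  full reference average. Leave-one-out avoids self-inflation of
  reference-group typicality.
- **Repeat placement.** Repeated trials keep their within-block
  positions and interval order by default (the simplest faithful
  reading of "identical pairs"); `shuffle_repeats = TRUE` scatters them
  within the target block.
- **Breakpoint times.** Segment midpoints, `(k − ½) · segment_ms`,
  in seconds; the external tool interpolates linearly between
  breakpoints, and analysis never leaves the per-segment values.
- **Bootstrap flavour.** Case resampling with percentile intervals
  (10⁴ resamples by default). BCa would be a natural extension; it is
  not implemented.

## Problem sizes used in the tests

The suite exercises the estimators at the scales where their guarantees
are claimed: 10⁶ Monte Carlo pairs for the forward-model/quadrature
agreement (3 binomial SEs on a 5 × 5 parameter grid); 20 seeded
replicates × 3000 repeats for noise recovery at σ ∈ {0.5, 1, 2, 3};
kernel recovery at 150, 10³ and 10⁴ trials (100 seeded session-scale
runs); and 200 replicate two-cohort studies (21 + 22 participants, full
pipeline) for the group-separation property. Distributional checks on
the stimulus sampler use 2 × 10⁵ profiles against numerically integrated
truncated-normal moments.

## Known limitations

- Single-session noise estimates are coarse: with 50 repeated pairs the
  sampling SE on σ is of order 0.3–0.5 around σ = 1 and grows quickly with
  σ; the method's strength is at the group level.
- Estimates at the range ceiling are lower bounds, not point estimates;
  treat `censored = TRUE` accordingly (e.g. rank-based group tests,
  which are what the package provides).
- The kernel estimator's amplitude confounds template fidelity with
  internal noise (attenuation); normalised shape and typicality are the
  comparable quantities across participants.
- The `N(0, √2)` evidence convention makes absolute σ values
  model-relative; comparisons across studies require the same
  convention.
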