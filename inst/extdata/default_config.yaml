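# Canonical run configuration: 6 x 71 ms pitch segments perturbed with
# SD 70 cents bounded at +/- 2.2 SD; 3 blocks of 50 pairs with block 1
# fully repeated as block 3; inversion grid 0-5 SD x -3..3, step 0.05.
seed: 1
stimulus:
  n_segments: 6
  segment_ms: 71
  noise_sd_cents: 70
  clip_sd: 2.2
design:
  n_blocks: 3
  block_size: 50
  repeat_source_block: 1
  repeat_target_block: 3
  n_repeats: 50
observer:
  template: final_rise
  sigma_internal: 1.0
  criterion: 0.0
grid:
  sigma_max: 5.0
  sigma_step: 0.05
  criterion_min: -3.0
  criterion_max: 3.0
  criterion_step: 0.05
  n_mc: 100000
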