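#' Stimulus configuration
#'
#' Describes how one stimulus is perturbed: the pitch contour of the base
#' utterance is divided into `n_segments` segments of `segment_ms`
#' milliseconds, and the pitch of each segment's breakpoint is shifted
#' independently by a zero-mean Gaussian draw with SD `noise_sd_cents`
#' (cents; 1 cent = 1/100 semitone), bounded at `clip_sd` standard
#' deviations.
#'
#' @param n_segments Number of pitch segments (breakpoints) per stimulus.
#' @param segment_ms Segment duration in milliseconds.
#' @param noise_sd_cents Stimulus-noise SD in cents.
#' @param clip_sd Bound on each shift, in units of `noise_sd_cents`.
#'
#' @return An object of class `pp_stim_config`.
#' @examples
#' stim_config() # the default 6 x 71 ms, SD 70 cents, bound 2.2 SD design
#' @export
stim_config <- function(n_segments = 6, segment_ms = 71,
                        noise_sd_cents = 70, clip_sd = 2.2) {
  v <- c(
    if (!is_count(n_segments)) "`n_segments` must be a positive integer.",
    if (!is_pos_num(segment_ms)) "`segment_ms` must be a positive number.",
    if (!is_pos_num(noise_sd_cents)) "`noise_sd_cents` must be > 0.",
    if (!is_pos_num(clip_sd)) "`clip_sd` must be > 0."
  )
  abort_violations("Invalid stimulus configuration.", v, "pp_invalid_config")
  structure(
    list(
      n_segments = as.integer(n_segments), segment_ms = as.numeric(segment_ms),
      noise_sd_cents = as.numeric(noise_sd_cents), clip_sd = as.numeric(clip_sd)
    ),
    class = "pp_stim_config"
  )
}

#' @export
print.pp_stim_config <- function(x, ...) {
  cat(sprintf(
    "<stimulus config> %d segments x %g ms, noise SD %g cents, bound +/- %g SD\n",
    x$n_segments, x$segment_ms, x$noise_sd_cents, x$clip_sd
  ))
  invisible(x)
}

#' Double-pass sequence design
#'
#' Describes the block structure of a trial sequence. Trials are grouped in
#' `n_blocks` blocks of `block_size` pairs; the first `n_repeats` trials of
#' block `repeat_target_block` re-present, stimulus for stimulus and in the
#' same interval order, the corresponding trials of block
#' `repeat_source_block` (the double-pass manipulation).
#'
#' @param n_blocks Number of blocks.
#' @param block_size Trials per block.
#' @param repeat_source_block,repeat_target_block 1-based block indices of
#'   the first and second pass.
#' @param n_repeats Number of repeated pairs in the target block.
#'
#' @return An object of class `pp_seq_design`.
#' @examples
#' seq_design() # 3 blocks of 50, block 1 fully repeated as block 3
#' seq_design(n_repeats = 25) # the reduced double-pass variant
#' @export
seq_design <- function(n_blocks = 3, block_size = 50,
                       repeat_source_block = 1,
                       repeat_target_block = n_blocks,
                       n_repeats = block_size) {
  v <- c(
    if (!is_count(n_blocks) || n_blocks < 2) "`n_blocks` must be an integer >= 2.",
    if (!is_count(block_size)) "`block_size` must be a positive integer.",
    if (!is_count(repeat_source_block)) "`repeat_source_block` must be a positive integer.",
    if (!is_count(repeat_target_block)) "`repeat_target_block` must be a positive integer."
  )
  abort_violations("Invalid sequence design.", v, "pp_invalid_design")
  v <- c(
    if (repeat_source_block > n_blocks) "`repeat_source_block` exceeds `n_blocks`.",
    if (repeat_target_block > n_blocks) "`repeat_target_block` exceeds `n_blocks`.",
    if (repeat_source_block == repeat_target_block) "source and target repeat blocks must differ.",
    if (!is_count(n_repeats) || n_repeats > block_size) "`n_repeats` must be in [1, block_size]."
  )
  abort_violations("Invalid sequence design.", v, "pp_invalid_design")
  structure(
    list(
      n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
      repeat_source_block = as.integer(repeat_source_block),
      repeat_target_block = as.integer(repeat_target_block),
      n_repeats = as.integer(n_repeats)
    ),
    class = "pp_seq_design"
  )
}

#' @export
print.pp_seq_design <- function(x, ...) {
  cat(sprintf(
    "<sequence design> %d blocks x %d pairs; %d repeats of block %d in block %d\n",
    x$n_blocks, x$block_size, x$n_repeats,
    x$repeat_source_block, x$repeat_target_block
  ))
  invisible(x)
}

#' Inversion grid specification
#'
#' Bounds and step sizes of the exhaustive (internal noise, criterion)
#' search used by [estimate_internal_noise()], plus the number of Monte
#' Carlo double-pass trials per grid point.
#'
#' @param sigma_max Upper bound of the internal-noise search range (SD
#'   units of stimulus noise; lower bound is 0).
#' @param sigma_step Grid step for internal noise.
#' @param criterion_min,criterion_max,criterion_step Criterion grid.
#' @param n_mc Monte Carlo trials per grid point.
#'
#' @return A `pp_grid_spec` list.
#' @export
grid_spec <- function(sigma_max = 5, sigma_step = 0.05,
                      criterion_min = -3, criterion_max = 3,
                      criterion_step = 0.05, n_mc = 1e5) {
  v <- c(
    if (!is_pos_num(sigma_max)) "`sigma_max` must be > 0.",
    if (!is_pos_num(sigma_step) || sigma_step > sigma_max) "`sigma_step` must be in (0, sigma_max].",
    if (!is_num1(criterion_min) || !is_num1(criterion_max) ||
      criterion_min > criterion_max) "criterion bounds must satisfy min <= max.",
    if (!is_pos_num(criterion_step)) "`criterion_step` must be > 0.",
    if (!is_count(n_mc)) "`n_mc` must be a positive integer."
  )
  abort_violations("Invalid grid specification.", v, "pp_invalid_grid")
  structure(
    list(
      sigma_max = sigma_max, sigma_step = sigma_step,
      criterion_min = criterion_min, criterion_max = criterion_max,
      criterion_step = criterion_step, n_mc = as.integer(n_mc)
    ),
    class = "pp_grid_spec"
  )
}

config_field <- function(x, path, field, default = NULL) {
  if (!is.null(x[[field]])) x[[field]] else default
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a full run: a `seed` (required),
#' a `stimulus` block ([stim_config()] fields), a `design` block
#' ([seq_design()] fields), an optional `observer` block (`template`,
#' either the string `"final_rise"` or a numeric vector; `sigma_internal`;
#' `criterion`) and an optional `grid` block ([grid_spec()] fields).
#' Every violation is reported with its full field path.
#'
#' @param path Path to a YAML file.
#' @return A `pp_run_config` list with elements `seed`, `stimulus`,
#'   `design`, `observer`, `grid`.
#' @examples
#' cfg <- load_config(system.file("extdata", "default_config.yaml",
#'   package = "prosodpass"
#' ))
#' cfg$stimulus
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  v <- character()
  note <- function(msg) v <<- c(v, msg)

  if (is.null(raw$seed)) {
    note("seed: missing (a seed is required for reproducibility).")
  } else if (!is_count(raw$seed + 1)) {
    note("seed: must be a single integer.")
  }

  build <- function(ctor, block, name) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    known <- names(formals(ctor))
    extra <- setdiff(names(args), known)
    for (e in extra) note(sprintf("%s.%s: unknown field.", block, e))
    tryCatch(
      do.call(ctor, args[intersect(names(args), known)]),
      error = function(cnd) {
        msgs <- cnd$body %||% conditionMessage(cnd)
        for (m in msgs) note(sprintf("%s: %s", block, m))
        NULL
      }
    )
  }

  stimulus <- build(stim_config, "stimulus")
  design <- build(seq_design, "design")
  grid <- build(grid_spec, "grid")

  observer <- NULL
  if (!is.null(raw$observer)) {
    ob <- raw$observer
    tmpl <- ob$template %||% "final_rise"
    sigma <- ob$sigma_internal %||% 1
    crit <- ob$criterion %||% 0
    if (is.character(tmpl) && length(tmpl) == 1L) {
      if (!identical(tmpl, "final_rise")) {
        note(sprintf("observer.template: unknown named template '%s'.", tmpl))
      } else if (!is.null(stimulus)) {
        tmpl <- final_rise_template(stimulus$n_segments)
      }
    } else if (!is.numeric(tmpl)) {
      note("observer.template: must be 'final_rise' or a numeric vector.")
    }
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
      note("observer.sigma_internal: must be a single number >= 0.")
    }
    if (!is_num1(crit)) note("observer.criterion: must be a single number.")
    if (length(v) == 0L && is.numeric(tmpl)) {
      observer <- tryCatch(
        observer_params(tmpl, sigma_internal = sigma, criterion = crit),
        error = function(cnd) {
          note(sprintf("observer: %s", conditionMessage(cnd)))
          NULL
        }
      )
    }
  }

  abort_violations(
    sprintf("Invalid run configuration in '%s'.", path),
    v, "pp_invalid_config"
  )
  structure(
    list(
      seed = as.integer(raw$seed), stimulus = stimulus, design = design,
      observer = observer, grid = grid, path = path
    ),
    class = "pp_run_config"
  )
}
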