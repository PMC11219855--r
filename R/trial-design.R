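# Raw draws: n x n_segments matrix of pitch shifts in cents.
# "resample" draws from the exact truncated normal (inverse-CDF form of
# rejection resampling); "hard" clips unbounded draws at the bound, which
# piles probability mass onto +/- clip_sd and changes the moments.
sample_shift_matrix <- function(n, config, clip_method = "resample") {
  k <- config$n_segments
  b <- config$clip_sd
  if (clip_method == "resample") {
    p <- pnorm(c(-b, b))
    z <- qnorm(runif(n * k, p[1], p[2]))
  } else {
    z <- pmin(pmax(rnorm(n * k), -b), b)
  }
  matrix(z * config$noise_sd_cents, nrow = n, ncol = k)
}

#' Sample stimulus pitch-shift profiles
#'
#' Draws independent per-segment pitch shifts from a zero-mean Gaussian
#' with SD `noise_sd_cents`, bounded at `clip_sd` standard deviations.
#' The default bounding (`"resample"`) samples the truncated normal
#' exactly, preserving a smooth density inside the bound; `"hard"`
#' clips unbounded draws at the bound instead (mass accumulates at the
#' edges and the resulting SD is slightly larger than the truncated one).
#'
#' @param n Number of profiles.
#' @param config A [stim_config()].
#' @param clip_method `"resample"` (truncation, default) or `"hard"`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#'
#' @return A tibble with `n` rows and columns `s1 ... s<n_segments>`,
#'   shifts in cents.
#' @examples
#' sample_profiles(3, stim_config(), seed = 1)
#' @export
sample_profiles <- function(n, config = stim_config(),
                            clip_method = c("resample", "hard"),
                            seed = NULL) {
  clip_method <- match.arg(clip_method)
  if (!is_count(n)) abort("`n` must be a positive integer.")
  m <- with_seed_if(seed, sample_shift_matrix(n, config, clip_method))
  colnames(m) <- shift_cols(config$n_segments)
  tibble::as_tibble(m)
}

#' Assemble a double-pass trial sequence
#'
#' Builds the full trial manifest for one session: `n_blocks x block_size`
#' two-interval trials, each pairing two freshly sampled pitch-shift
#' profiles, with the first `n_repeats` trials of the target block
#' re-presenting the corresponding trials of the source block verbatim
#' (same stimuli, same interval order). Repeated trials carry the 1-based
#' trial number of their source in `repeat_of`; fresh trials carry `NA`.
#'
#' @param design A [seq_design()].
#' @param config A [stim_config()].
#' @param clip_method Passed to the profile sampler; see
#'   [sample_profiles()].
#' @param shuffle_repeats If `TRUE`, the trials of the target block are
#'   presented in a random order (contents permuted; `repeat_of` follows
#'   its trial). Default `FALSE`: repeats occupy the same within-block
#'   positions as in the source block.
#' @param seed Optional integer seed.
#'
#' @return A tibble with two rows per trial (one per interval) and columns
#'   `trial`, `block`, `interval` (1 or 2), `repeat_of`, `s1 ...`.
#'   The stimulus configuration and design are attached as attributes
#'   `pp_config` and `pp_design`.
#' @examples
#' seqn <- make_sequence(seq_design(), stim_config(), seed = 1)
#' nrow(seqn) / 2 # 150 trials
#' sum(!is.na(seqn$repeat_of)) / 2 # 50 repeated pairs
#' @export
make_sequence <- function(design = seq_design(), config = stim_config(),
                          clip_method = c("resample", "hard"),
                          shuffle_repeats = FALSE, seed = NULL) {
  clip_method <- match.arg(clip_method)
  with_seed_if(seed, {
    bs <- design$block_size
    nt <- design$n_blocks * bs
    k <- config$n_segments

    rep_idx <- (design$repeat_target_block - 1L) * bs + seq_len(design$n_repeats)
    src_idx <- (design$repeat_source_block - 1L) * bs + seq_len(design$n_repeats)
    fresh <- setdiff(seq_len(nt), rep_idx)

    S1 <- S2 <- matrix(NA_real_, nrow = nt, ncol = k)
    m <- sample_shift_matrix(2L * length(fresh), config, clip_method)
    S1[fresh, ] <- m[seq_along(fresh), , drop = FALSE]
    S2[fresh, ] <- m[length(fresh) + seq_along(fresh), , drop = FALSE]

    repeat_of <- rep(NA_integer_, nt)
    repeat_of[rep_idx] <- src_idx
    S1[rep_idx, ] <- S1[src_idx, , drop = FALSE]
    S2[rep_idx, ] <- S2[src_idx, , drop = FALSE]

    if (isTRUE(shuffle_repeats)) {
      tgt <- (design$repeat_target_block - 1L) * bs + seq_len(bs)
      ord <- sample.int(bs)
      S1[tgt, ] <- S1[tgt[ord], , drop = FALSE]
      S2[tgt, ] <- S2[tgt[ord], , drop = FALSE]
      repeat_of[tgt] <- repeat_of[tgt[ord]]
    }

    shifts <- matrix(NA_real_, nrow = 2L * nt, ncol = k)
    odd <- seq(1L, 2L * nt, by = 2L)
    shifts[odd, ] <- S1
    shifts[odd + 1L, ] <- S2
    colnames(shifts) <- shift_cols(k)

    out <- dplyr::bind_cols(
      tibble::tibble(
        trial = rep(seq_len(nt), each = 2L),
        block = rep((seq_len(nt) - 1L) %/% bs + 1L, each = 2L),
        interval = rep(1:2, nt),
        repeat_of = rep(repeat_of, each = 2L)
      ),
      tibble::as_tibble(shifts)
    )
    attr(out, "pp_config") <- config
    attr(out, "pp_design") <- design
    out
  })
}

#' Breakpoint table for one pitch-shift profile
#'
#' Converts a profile to the (time, shift) breakpoint table consumed by
#' external pitch-shifting tools. Times are segment midpoints,
#' `(k - 0.5) * segment_ms / 1000` seconds for segment `k`; the external
#' tool interpolates linearly between breakpoints.
#'
#' @param shifts Numeric vector of per-segment shifts in cents.
#' @param config A [stim_config()] supplying `segment_ms`.
#' @return A tibble with columns `time_s`, `shift_cents`.
#' @export
bpf_table <- function(shifts, config = stim_config()) {
  if (!is.numeric(shifts) || length(shifts) < 1L) {
    abort("`shifts` must be a non-empty numeric vector.")
  }
  tibble::tibble(
    time_s = (seq_along(shifts) - 0.5) * config$segment_ms / 1000,
    shift_cents = as.numeric(shifts)
  )
}

#' Export a sequence as breakpoint files
#'
#' Writes one tab-separated breakpoint file (no header, columns time in
#' seconds and shift in cents) per trial and interval, named
#' `trial0001_int1.txt` etc.
#'
#' @param sequence A manifest from [make_sequence()].
#' @param dir Output directory (created if needed).
#' @param config A [stim_config()]; defaults to the one attached to
#'   `sequence`.
#' @return Invisibly, the written file paths.
#' @export
export_bpfs <- function(sequence, dir, config = NULL) {
  config <- config %||% attr(sequence, "pp_config") %||% stim_config()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scols <- shift_cols_in(sequence)
  paths <- character(nrow(sequence))
  for (i in seq_len(nrow(sequence))) {
    paths[i] <- file.path(dir, sprintf(
      "trial%04d_int%d.txt",
      sequence$trial[i], sequence$interval[i]
    ))
    readr::write_tsv(
      bpf_table(as.numeric(sequence[i, scols]), config),
      paths[i],
      col_names = FALSE, progress = FALSE
    )
  }
  invisible(paths)
}

#' Read and write sequence manifests and experiment logs
#'
#' Comma-separated, header row, one row per trial and interval. A log is a
#' manifest with `participant` and `response` columns added.
#'
#' @param x A manifest or log tibble.
#' @param path File path.
#' @return `write_sequence()` returns `x` invisibly; `read_sequence()`
#'   returns a tibble.
#' @export
write_sequence <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("trial", "block", "interval", "repeat_of", "response"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
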