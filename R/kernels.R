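#' Classification image (perceptual kernel) from an experiment log
#'
#' For each segment, the mean pitch shift of the stimuli classified as
#' interrogative (the chosen interval) minus the mean shift of the
#' stimuli classified as non-interrogative (the unchosen interval). In a
#' two-interval trial every trial contributes one stimulus to each side,
#' so both means are over `n_trials` profiles.
#'
#' @param log An experiment log (manifest plus `response`), e.g. from
#'   [simulate_experiment()] or [read_sequence()].
#' @return A kernel tibble: columns `segment`, `weight` (cents before
#'   normalisation), `n_trials`, `normalized` (`FALSE`).
#' @examples
#' log <- simulate_experiment(make_sequence(seed = 1),
#'   observer_params(final_rise_template(6), sigma_internal = 0),
#'   seed = 2
#' )
#' compute_kernel(log)
#' @export
compute_kernel <- function(log) {
  if (!is.data.frame(log) || nrow(log) == 0L) {
    abort("`log` is empty.", class = "pp_empty_log")
  }
  if (!"response" %in% names(log) || anyNA(log$response) ||
    !all(log$response %in% 1:2)) {
    abort("`log` must carry responses coded 1 or 2 on every row.")
  }
  scols <- shift_cols_in(log)
  chosen <- log$interval == log$response
  w <- colMeans(log[chosen, scols, drop = FALSE]) -
    colMeans(log[!chosen, scols, drop = FALSE])
  tibble::tibble(
    segment = seq_along(scols),
    weight = unname(w),
    n_trials = dplyr::n_distinct(log$trial),
    normalized = FALSE
  )
}

kernel_rms <- function(kernel) sqrt(mean(kernel$weight^2))

check_normalized <- function(kernel, arg = "kernel") {
  if (!isTRUE(all(kernel$normalized)) || abs(kernel_rms(kernel) - 1) > 1e-8) {
    abort(sprintf("`%s` must be RMS-normalised; see normalize_kernel().", arg),
      class = "pp_unnormalized_kernel"
    )
  }
}

#' RMS-normalise a kernel
#'
#' Divides the weights by their root mean square so that the normalised
#' kernel has RMS exactly 1; idempotent. Near-zero kernels (RMS below
#' `eps` cents — e.g. a random responder at small trial counts) raise a
#' `pp_degenerate_kernel` error rather than dividing silently.
#'
#' @param kernel A kernel tibble from [compute_kernel()].
#' @param eps Degeneracy guard on the pre-normalisation RMS, in cents.
#' @return The kernel with unit-RMS weights and `normalized = TRUE`.
#' @export
normalize_kernel <- function(kernel, eps = 1e-9) {
  rms <- kernel_rms(kernel)
  if (!is.finite(rms) || rms < eps) {
    abort(
      sprintf("kernel is degenerate: RMS %.3g is below the %.3g guard.", rms, eps),
      class = "pp_degenerate_kernel"
    )
  }
  dplyr::mutate(kernel, weight = .data$weight / rms, normalized = TRUE)
}

#' Representation typicality
#'
#' Mean squared error between two RMS-normalised kernels, segment-wise.
#' 0 iff the kernels are identical; because both kernels have unit RMS,
#' the score is bounded by 4 (attained at sign-flipped kernels). Higher
#' values mean a less typical representation; the raw MSE is returned,
#' never a relabelled similarity.
#'
#' @param kernel,reference Normalised kernel tibbles of equal length.
#' @return A single non-negative number.
#' @examples
#' k <- normalize_kernel(tibble::tibble(
#'   segment = 1:6, weight = c(0, 0, 0, 0, 1, 2),
#'   n_trials = NA_integer_, normalized = FALSE
#' ))
#' typicality(k, k) # 0
#' @export
typicality <- function(kernel, reference) {
  check_normalized(kernel, "kernel")
  check_normalized(reference, "reference")
  if (nrow(kernel) != nrow(reference)) {
    abort("kernels have different numbers of segments.", class = "pp_dim_mismatch")
  }
  mean((kernel$weight - reference$weight)^2)
}

#' Kernels for every participant of a cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or any tibble
#'   with `participant` and a `log` list-column).
#' @param normalize RMS-normalise each kernel (default `TRUE`).
#' @return A tibble with one row per participant and segment:
#'   `participant`, `group` (if present), `segment`, `weight`,
#'   `n_trials`, `normalized`.
#' @export
cohort_kernels <- function(cohort, normalize = TRUE) {
  stopifnot(is.data.frame(cohort), "log" %in% names(cohort))
  one <- function(log, participant) {
    k <- compute_kernel(log)
    if (normalize) k <- normalize_kernel(k)
    dplyr::mutate(k, participant = participant, .before = 1L)
  }
  out <- purrr::map2(cohort$log, cohort$participant, one)
  out <- dplyr::bind_rows(out)
  if ("group" %in% names(cohort)) {
    out <- dplyr::left_join(out,
      dplyr::select(cohort, "participant", "group"),
      by = "participant"
    )
    out <- dplyr::relocate(out, "group", .after = "participant")
  }
  out
}

#' Group-average kernel
#'
#' Segment-wise mean of the participants' normalised kernels,
#' re-normalised to unit RMS. With `leave_out` set, that participant is
#' excluded — used when scoring members of the reference group against
#' their own group average, to avoid self-inflation.
#'
#' @param kernels A long kernel tibble with a `participant` column, as
#'   from [cohort_kernels()]; kernels must be normalised.
#' @param leave_out Optional participant id to exclude.
#' @return A normalised kernel tibble (`n_trials` is `NA`).
#' @export
group_average_kernel <- function(kernels, leave_out = NULL) {
  stopifnot(is.data.frame(kernels), "participant" %in% names(kernels))
  if (!isTRUE(all(kernels$normalized))) {
    abort("`kernels` must be normalised per participant.",
      class = "pp_unnormalized_kernel"
    )
  }
  if (!is.null(leave_out)) {
    kernels <- dplyr::filter(kernels, .data$participant != leave_out)
    if (nrow(kernels) == 0L) abort("`leave_out` removed every kernel.")
  }
  avg <- kernels |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(weight = mean(.data$weight), .groups = "drop") |>
    dplyr::mutate(n_trials = NA_integer_, normalized = FALSE)
  normalize_kernel(avg)
}

#' Typicality scores for a set of kernels
#'
#' Scores each participant's normalised kernel against a reference. With
#' `reference = NULL` the reference is the leave-one-out group average of
#' the scored kernels themselves (the convention for scoring a reference
#' group against itself); otherwise every kernel is scored against the
#' supplied reference kernel (e.g. patients against the full control
#' average).
#'
#' @param kernels Long kernel tibble with `participant` column, normalised.
#' @param reference Optional normalised kernel tibble.
#' @return A tibble `participant`, `typicality`.
#' @export
typicality_scores <- function(kernels, reference = NULL) {
  ids <- unique(kernels$participant)
  score <- vapply(ids, function(id) {
    k <- dplyr::filter(kernels, .data$participant == id)
    ref <- reference %||% group_average_kernel(kernels, leave_out = id)
    typicality(k, ref)
  }, numeric(1))
  tibble::tibble(participant = ids, typicality = unname(score))
}

#' Keep only the first trials of a session
#'
#' Retains the first `n_trials` trials in presentation order — used to
#' match trial counts across participants or sessions before kernel
#' estimation.
#'
#' @param log An experiment log or sequence manifest.
#' @param n_trials Number of trials to keep.
#' @return The truncated tibble.
#' @export
truncate_log <- function(log, n_trials) {
  if (!is_count(n_trials)) abort("`n_trials` must be a positive integer.")
  keep <- head(sort(unique(log$trial)), n_trials)
  out <- dplyr::filter(log, .data$trial %in% keep)
  attr(out, "pp_config") <- attr(log, "pp_config")
  out
}

#' Cosine similarity between a kernel and a template
#'
#' Scale-free agreement between estimated weights and a generating
#' template; 1 means perfectly aligned shapes.
#'
#' @param kernel A kernel tibble (normalised or not).
#' @param template Numeric vector of the same length.
#' @return A number in `[-1, 1]`.
#' @export
kernel_cosine <- function(kernel, template) {
  w <- kernel$weight
  if (length(w) != length(template)) {
    abort("template length does not match the kernel.", class = "pp_dim_mismatch")
  }
  sum(w * template) / sqrt(sum(w^2) * sum(template^2))
}

#' Read and write kernel tables
#'
#' Comma-separated, one row per segment (long kernel tibbles with a
#' `participant` column round-trip the same way).
#'
#' @param kernel A kernel tibble.
#' @param path File path.
#' @export
write_kernel <- function(kernel, path) {
  readr::write_csv(kernel, path, progress = FALSE)
  invisible(kernel)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$segment <- as.integer(out$segment)
  out$n_trials <- as.integer(out$n_trials)
  out$normalized <- as.logical(out$normalized)
  out
}
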