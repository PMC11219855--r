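#' Two-stage observer parameters
#'
#' A simulated participant compares each stimulus pair against a prosodic
#' template and perturbs the resulting evidence with additive Gaussian
#' internal noise. The template is normalised internally to unit Euclidean
#' norm, so decisions are invariant to its scale.
#'
#' Units contract: for a pair with shift profiles `s1`, `s2` (cents), the
#' decision variable is `e = u . (s1 - s2) / noise_sd_cents` with `u` the
#' unit-norm template, i.e. evidence is measured in SD units of the
#' stimulus noise as seen through the template. Internal noise
#' `sigma_internal` and `criterion` live on that same scale; the
#' double-pass inversion in [estimate_internal_noise()] uses the identical
#' convention, which is what makes its estimates interpretable as "units
#' of the stimulus-noise SD".
#'
#' @param template Numeric vector, one weight per segment; any scale, not
#'   all zero.
#' @param sigma_internal Internal-noise SD, `>= 0`, in stimulus-noise SD
#'   units.
#' @param criterion Additive decision bias on the evidence scale. Positive
#'   values favour interval 2.
#'
#' @return An object of class `pp_observer`.
#' @examples
#' observer_params(final_rise_template(6), sigma_internal = 1)
#' @export
observer_params <- function(template, sigma_internal = 1, criterion = 0) {
  v <- c(
    if (!is.numeric(template) || length(template) < 1L || anyNA(template)) {
      "`template` must be a numeric vector without NAs."
    },
    if (is.numeric(template) && all(template == 0)) "`template` must not be all zero.",
    if (!is.numeric(sigma_internal) || length(sigma_internal) != 1L ||
      !is.finite(sigma_internal) || sigma_internal < 0) {
      "`sigma_internal` must be a single number >= 0."
    },
    if (!is_num1(criterion)) "`criterion` must be a single finite number."
  )
  abort_violations("Invalid observer parameters.", v, "pp_invalid_observer")
  structure(
    list(
      template = as.numeric(template),
      unit = as.numeric(template) / sqrt(sum(template^2)),
      sigma_internal = as.numeric(sigma_internal),
      criterion = as.numeric(criterion)
    ),
    class = "pp_observer"
  )
}

#' @export
print.pp_observer <- function(x, ...) {
  cat(sprintf(
    "<observer> %d-segment template, internal noise %g, criterion %g\n",
    length(x$template), x$sigma_internal, x$criterion
  ))
  invisible(x)
}

#' Final-rise prosodic template
#'
#' The canonical interrogative contour in French: flat pitch followed by a
#' terminal rise. Zero on all but the last two segments, with a ramp
#' (0.5, 1) at the end; [observer_params()] rescales to unit norm.
#'
#' @param n_segments Template length, `>= 2`.
#' @return A numeric vector of length `n_segments`.
#' @examples
#' final_rise_template(6)
#' @export
final_rise_template <- function(n_segments = 6) {
  if (!is_count(n_segments) || n_segments < 2) {
    abort("`n_segments` must be an integer >= 2.")
  }
  c(rep(0, n_segments - 2L), 0.5, 1)
}

#' Decide one two-interval trial
#'
#' Applies the two-stage rule to a single stimulus pair: evidence
#' `e = u . (s1 - s2) / noise_sd_cents` plus one internal-noise draw,
#' compared against the criterion. Interval 1 is chosen iff
#' `e + z > criterion`; exact ties (a measure-zero event) go to
#' interval 2.
#'
#' @param params An [observer_params()].
#' @param s1,s2 Shift profiles (cents) of intervals 1 and 2.
#' @param noise_sd_cents Stimulus-noise SD in cents.
#' @param seed Optional integer seed.
#' @return `1L` or `2L`.
#' @examples
#' p <- observer_params(final_rise_template(6), sigma_internal = 0)
#' decide(p, s1 = c(0, 0, 0, 0, 50, 100), s2 = rep(0, 6)) # 1: s1 matches
#' @export
decide <- function(params, s1, s2, noise_sd_cents = 70, seed = NULL) {
  stopifnot(inherits(params, "pp_observer"))
  if (length(s1) != length(params$template) || length(s2) != length(s1)) {
    abort("profile length does not match the template.", class = "pp_dim_mismatch")
  }
  e <- sum(params$unit * (s1 - s2)) / noise_sd_cents
  z <- with_seed_if(seed, rnorm(1L, 0, params$sigma_internal))
  if (e + z > params$criterion) 1L else 2L
}

#' Evidence seen by an observer over a sequence
#'
#' The noiseless decision variable per trial, before internal noise: a
#' diagnostic for checking the evidence scale (its variance is close to 2
#' for an unbounded stimulus distribution, shrunk by the truncated-variance
#' ratio under the +/- `clip_sd` bound).
#'
#' @param sequence A manifest from [make_sequence()].
#' @param params An [observer_params()].
#' @param config A [stim_config()]; defaults to the attribute attached to
#'   `sequence`.
#' @return A tibble with columns `trial`, `evidence`.
#' @export
observer_evidence <- function(sequence, params, config = NULL) {
  config <- config %||% attr(sequence, "pp_config") %||%
    abort("no `config` given and none attached to `sequence`.")
  if (config$n_segments != length(params$template)) {
    abort("template length does not match `config$n_segments`.",
      class = "pp_dim_mismatch"
    )
  }
  S1 <- shift_matrix(sequence, 1L)
  S2 <- shift_matrix(sequence, 2L)
  tibble::tibble(
    trial = sort(unique(sequence$trial)),
    evidence = drop((S1 - S2) %*% params$unit) / config$noise_sd_cents
  )
}

#' Simulate a full session
#'
#' Runs the two-stage observer over every trial of a sequence, drawing
#' fresh internal noise on every presentation — including repeated trials,
#' which is what makes the double-pass manipulation informative about
#' internal noise.
#'
#' @inheritParams observer_evidence
#' @param participant Participant identifier stored in the log.
#' @param seed Optional integer seed.
#' @return An experiment log: the sequence tibble with `participant` and
#'   `response` (1 or 2, constant across a trial's two rows) columns.
#' @examples
#' seqn <- make_sequence(seed = 1)
#' log <- simulate_experiment(seqn, observer_params(final_rise_template(6)),
#'   seed = 2
#' )
#' table(log$response[log$interval == 1])
#' @export
simulate_experiment <- function(sequence, params, config = NULL,
                                participant = "sim", seed = NULL) {
  config <- config %||% attr(sequence, "pp_config") %||%
    abort("no `config` given and none attached to `sequence`.")
  ev <- observer_evidence(sequence, params, config)
  resp <- with_seed_if(seed, {
    z <- rnorm(nrow(ev), 0, params$sigma_internal)
    ifelse(ev$evidence + z > params$criterion, 1L, 2L)
  })
  out <- dplyr::mutate(sequence,
    participant = participant,
    response = resp[match(.data$trial, ev$trial)],
    .before = 1L
  )
  attr(out, "pp_config") <- config
  attr(out, "pp_design") <- attr(sequence, "pp_design")
  out
}

# Truncated-at-zero normal draws (inverse CDF).
rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(max(mean, 0), n))
  }
  qnorm(runif(n, pnorm(0, mean, sd), 1), mean, sd)
}

#' Specify one simulated group
#'
#' @param label Group label.
#' @param n Number of participants.
#' @param sigma_mean,sigma_sd Parameters of the internal-noise
#'   distribution across participants: normal truncated at 0.
#' @param criterion Decision criterion shared by the group.
#' @param template Template shared by the group; `NULL` for the final-rise
#'   default at simulation time.
#' @return A one-row tibble consumed by [generate_cohort()].
#' @export
cohort_spec <- function(label, n, sigma_mean, sigma_sd,
                        criterion = 0, template = NULL) {
  v <- c(
    if (!is.character(label) || length(label) != 1L) "`label` must be a single string.",
    if (!is_count(n)) "`n` must be a positive integer.",
    if (!is_num1(sigma_mean)) "`sigma_mean` must be a single number.",
    if (!is.numeric(sigma_sd) || length(sigma_sd) != 1L || sigma_sd < 0) {
      "`sigma_sd` must be a single number >= 0."
    }
  )
  abort_violations("Invalid cohort specification.", v, "pp_invalid_cohort")
  tibble::tibble(
    label = label, n = as.integer(n),
    sigma_mean = sigma_mean, sigma_sd = sigma_sd,
    criterion = criterion, template = list(template)
  )
}

#' Simulate a cohort of observers
#'
#' Draws one internal-noise value per participant from the group's
#' truncated-normal distribution, generates an independent stimulus
#' sequence per participant, and simulates the session.
#'
#' @param groups One or more [cohort_spec()] rows (bind with
#'   `dplyr::bind_rows()`).
#' @param design A [seq_design()].
#' @param config A [stim_config()].
#' @param clip_method Passed to [make_sequence()].
#' @param seed Optional master seed; the whole cohort is reproduced from
#'   it.
#' @return A tibble with one row per participant: `participant`, `group`,
#'   `sigma_true`, `criterion`, and the session log in the list-column
#'   `log`.
#' @examples
#' cohort <- generate_cohort(
#'   cohort_spec("control", n = 2, sigma_mean = 0.7, sigma_sd = 0.37),
#'   seed = 1
#' )
#' cohort$sigma_true
#' @export
generate_cohort <- function(groups, design = seq_design(),
                            config = stim_config(),
                            clip_method = "resample", seed = NULL) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1L)
  with_seed_if(seed, {
    rows <- purrr::pmap(groups, function(label, n, sigma_mean, sigma_sd,
                                         criterion, template) {
      template <- template %||% final_rise_template(config$n_segments)
      sigmas <- rtrunc0(n, sigma_mean, sigma_sd)
      ids <- sprintf("%s_%02d", label, seq_len(n))
      logs <- vector("list", n)
      for (i in seq_len(n)) {
        seqn <- make_sequence(design, config, clip_method = clip_method)
        obs <- observer_params(template, sigmas[i], criterion)
        logs[[i]] <- simulate_experiment(seqn, obs, config, participant = ids[i])
      }
      tibble::tibble(
        participant = ids, group = label, sigma_true = sigmas,
        criterion = criterion, log = logs
      )
    })
    dplyr::bind_rows(rows)
  })
}
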