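#' Plot classification-image kernels
#'
#' Per-segment kernel weights as lines, one per participant when a
#' `participant` column is present, coloured by `group` when present.
#' A reference kernel (e.g. a group average) can be overlaid in black.
#'
#' @param kernels A kernel tibble ([compute_kernel()]) or long cohort
#'   kernel tibble ([cohort_kernels()]).
#' @param reference Optional kernel tibble drawn as a thick black line.
#' @return A ggplot object.
#' @export
plot_kernels <- function(kernels, reference = NULL) {
  p <- ggplot2::ggplot(
    kernels,
    ggplot2::aes(x = .data$segment, y = .data$weight)
  )
  if ("participant" %in% names(kernels)) {
    if ("group" %in% names(kernels)) {
      p <- p + ggplot2::geom_line(
        ggplot2::aes(group = .data$participant, colour = .data$group),
        alpha = 0.6
      )
    } else {
      p <- p + ggplot2::geom_line(
        ggplot2::aes(group = .data$participant),
        alpha = 0.6
      )
    }
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_line(
      data = reference, linewidth = 1.2, colour = "black"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = unique(kernels$segment)) +
    ggplot2::labs(
      x = "segment", y = "kernel weight",
      title = "Internal representations (classification images)"
    )
}

#' Plot cohort internal-noise estimates
#'
#' Dot plot of estimated internal noise per group; censored estimates
#' (at the top of the search range) are drawn as open triangles.
#'
#' @param estimates An estimates tibble from [estimate_cohort_noise()]
#'   with `group`, `sigma` and `censored` columns.
#' @return A ggplot object.
#' @export
plot_noise_estimates <- function(estimates) {
  ggplot2::ggplot(
    estimates,
    ggplot2::aes(x = .data$group, y = .data$sigma)
  ) +
    ggplot2::geom_jitter(
      ggplot2::aes(shape = .data$censored),
      width = 0.12, height = 0, size = 2
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2)) +
    ggplot2::labs(
      x = NULL, y = "internal noise (stimulus-noise SD units)",
      title = "Double-pass internal-noise estimates"
    )
}

#' @describeIn compare_groups Autoplot method: group means and the
#'   bootstrap CI of their difference.
#' @param object A `pp_group_comparison`.
#' @param ... Unused.
#' @export
autoplot.pp_group_comparison <- function(object, ...) {
  d <- tibble::tibble(
    what = sprintf("%s - %s", object$groups[1], object$groups[2]),
    estimate = object$mean_difference,
    lo = object$conf_low, hi = object$conf_high
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$what, y = .data$estimate)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      width = 0.1
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "difference of group means",
      subtitle = sprintf(
        "U = %g, p = %.3g", object$statistic, object$p_value
      )
    )
}

#' @describeIn ols_bootstrap Autoplot method: scatter with the fitted
#'   line.
#' @param object A `pp_ols_boot`.
#' @param ... Unused.
#' @export
autoplot.pp_ols_boot <- function(object, ...) {
  mf <- stats::model.frame(object$fit)
  d <- tibble::tibble(y = mf[[1]], x = mf[[2]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$estimate[1], slope = object$estimate[2]
    ) +
    ggplot2::labs(
      x = object$terms[2], y = names(mf)[1],
      subtitle = sprintf(
        "beta = %.3f [%.3f, %.3f], R2 = %.3f",
        object$estimate[2], object$conf_low[2], object$conf_high[2],
        object$r_squared
      )
    )
}
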