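#' Plot sensor-level evoked responses
#'
#' Channel-by-time traces, colored by condition.
#'
#' @param object a `sensor_erp`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sensor_erp <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time * 1000, y = .data$value,
    colour = .data$condition
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(
      x = "peristimulus time (ms)", y = "sensor amplitude (a.u.)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-population source activity
#'
#' Voltage traces of every population in every source, the
#' source-space view of a simulated evoked response.
#'
#' @param object a `source_response`.
#' @param populations which populations to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.source_response <- function(object,
                                     populations = c("ss", "sp", "dp"),
                                     ...) {
  df <- dplyr::filter(
    as_tibble(object),
    .data$population %in% populations
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time * 1000, y = .data$voltage,
    linetype = .data$population
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~source) +
    ggplot2::labs(
      x = "peristimulus time (ms)", y = "depolarization (mV)",
      linetype = "population"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Posterior model probabilities as a bar chart, plus the Bayesian
#' model average of the switchable effects with 90% credible
#' intervals.
#'
#' @param object a `cmc_comparison`.
#' @param what `"probabilities"` or `"bma"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cmc_comparison <- function(object,
                                    what = c("probabilities", "bma"),
                                    ...) {
  what <- match.arg(what)
  if (what == "probabilities") {
    ggplot2::ggplot(object$models, ggplot2::aes(
      x = factor(.data$model), y = .data$prob
    )) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "reduced model", y = "posterior probability") +
      ggplot2::theme_minimal()
  } else {
    z <- stats::qnorm(0.95)
    idx <- match(object$effects, object$bma$names)
    df <- tibble::tibble(
      effect = object$effects,
      estimate = unname(object$bma$mean[object$effects]),
      sd = sqrt(diag(object$bma$cov)[idx])
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$estimate)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_errorbar(
        ggplot2::aes(
          ymin = .data$estimate - z * .data$sd,
          ymax = .data$estimate + z * .data$sd
        ),
        width = 0.2, colour = "deeppink3"
      ) +
      ggplot2::labs(
        x = "condition effect", y = "log-scaling (BMA, 90% CI)"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a free-energy trace
#'
#' @param object a `vl_fit`.
#' @param ... unused.
#' @return a ggplot of the non-decreasing free-energy trajectory over
#'   accepted iterations.
#' @export
autoplot.vl_fit <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$trace) - 1L,
    free_energy = object$trace
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$free_energy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "accepted iteration", y = "free energy (nats)") +
    ggplot2::theme_minimal()
}
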