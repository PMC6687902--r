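#' Tidy a variational-Laplace fit
#'
#' One row per parameter: posterior mean, standard deviation, prior
#' mean, and a central credible interval.
#'
#' @param x a `vl_fit`.
#' @param conf_level credible-interval mass (default 0.90, the
#'   convention used throughout the package's reports).
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.vl_fit <- function(x, conf_level = 0.90, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  sd <- sqrt(pmax(diag(x$posterior$cov), 0))
  tibble::tibble(
    term = x$posterior$names,
    estimate = unname(x$posterior$mean),
    std.error = sd,
    conf.low = unname(x$posterior$mean) - z * sd,
    conf.high = unname(x$posterior$mean) + z * sd
  )
}

#' Glance at a variational-Laplace fit
#'
#' @param x a `vl_fit`.
#' @param ... unused.
#' @return a one-row tibble: free energy, iterations, convergence
#'   flag, noise log-precision, number of observations.
#' @export
glance.vl_fit <- function(x, ...) {
  tibble::tibble(
    free_energy = x$free_energy,
    iterations = x$iterations,
    converged = x$converged,
    noise_log_precision = x$lambda$mean,
    n_obs = x$n_obs
  )
}

#' Tidy a model comparison
#'
#' @param x a `cmc_comparison`.
#' @param ... unused.
#' @return the per-model tibble: model index, kept effects, free
#'   energy relative to the full model, posterior probability.
#' @export
tidy.cmc_comparison <- function(x, ...) {
  dplyr::select(x$models, "model", "kept", "delta_f", "prob")
}

#' Glance at a model comparison
#'
#' @param x a `cmc_comparison`.
#' @param ... unused.
#' @return one-row tibble: number of models, winning model and its
#'   probability, full-model free energy.
#' @export
glance.cmc_comparison <- function(x, ...) {
  best <- which.max(x$models$prob)
  tibble::tibble(
    n_models = nrow(x$models),
    best_model = x$models$model[best],
    best_prob = x$models$prob[best],
    free_energy_full = x$free_energy_full
  )
}

#' Tidy a recovery report
#'
#' @param x a `recovery_report`.
#' @param ... unused.
#' @return the per-effect summary tibble.
#' @export
tidy.recovery_report <- function(x, ...) x$per_effect

#' Glance at a recovery report
#'
#' @param x a `recovery_report`.
#' @param ... unused.
#' @return one-row tibble with replicate count, SNR, model hit rate
#'   and failure count.
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates,
    snr_db = x$snr_db,
    model_hit_rate = x$model_hit_rate,
    n_failures = length(x$failures)
  )
}
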