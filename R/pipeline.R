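#' Reproducible run configuration
#'
#' Bundles every switch of an end-to-end run — design choice, seed,
#' SNR, inversion tolerances — into one serializable record that is
#' written into the output directory of every pipeline command, so a
#' run directory always contains what is needed to reproduce itself.
#'
#' @param out output directory.
#' @param seed integer seed.
#' @param snr_db dataset SNR (dB; `Inf` for noiseless).
#' @param design `"two-condition"` (early/late, covariates 0/1) or
#'   `"parametric-16"` (16 sequential events, covariates 0..15).
#' @param effects number of switchable condition effects.
#' @param max_iter,tol inversion iteration cap and free-energy
#'   tolerance.
#' @param n_replicates replicates for [run_recover()].
#' @param name file-name stem for datasets.
#' @return a `run_config` list.
#' @export
run_config <- function(out = "erpdcm-run", seed = 1, snr_db = 10,
                       design = c("two-condition", "parametric-16"),
                       effects = 4, max_iter = 48, tol = 0.01,
                       n_replicates = 20, name = "erp") {
  design <- match.arg(design)
  structure(
    list(
      out = out, seed = as.integer(seed), snr_db = snr_db,
      design = design, effects = as.integer(effects),
      max_iter = as.integer(max_iter), tol = tol,
      n_replicates = as.integer(n_replicates), name = name
    ),
    class = "run_config"
  )
}

config_design <- function(config) {
  if (config$design == "parametric-16") {
    tibble::tibble(
      condition = sprintf("ev%02d", 1:16),
      covariate = parametric_design(16)
    )
  } else {
    NULL # network default: early/late
  }
}

write_config <- function(config, dir) {
  obj <- unclass(config)
  obj$snr_db <- if (is.finite(config$snr_db)) config$snr_db else "Inf"
  yaml::write_yaml(obj, file.path(dir, "config.yaml"))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file written by a previous run (or by hand) with the
#'   [run_config()] schema.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (identical(obj$snr_db, "Inf")) obj$snr_db <- Inf
  do.call(run_config, obj[intersect(names(obj), names(formals(run_config)))])
}

#' Simulate a dataset from the default scenario
#'
#' Generates a synthetic evoked-response dataset under the configured
#' design and SNR, and writes the sensor data, ground truth, network
#' and configuration into the output directory.
#'
#' @param config a `run_config`.
#' @return list with `data`, `truth`, `net` (invisibly).
#' @export
run_simulate <- function(config = run_config()) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out, 2) != 0) {
    stop("output directory is not writable: ", config$out, call. = FALSE)
  }
  scen <- default_scenario(config_design(config))
  ds <- generate_dataset(scen$net, scen$params,
    snr_db = config$snr_db, seed = config$seed
  )
  write_sensor_data(ds$data, config$out, config$name)
  write_ground_truth(ds$truth, file.path(config$out, "ground_truth.json"))
  write_network(scen$net, file.path(config$out, "network.yaml"))
  write_config(config, config$out)
  message(
    "simulated ", length(ds$data$data), " conditions (seed ",
    config$seed, ", SNR ", config$snr_db, " dB) into ", config$out
  )
  invisible(list(data = ds$data, truth = ds$truth, net = scen$net))
}

#' Fit and compare models on a simulated dataset
#'
#' Reads a dataset written by [run_simulate()], inverts the full
#' model, scores all reduced models by Bayesian model reduction and
#' writes the inversion posterior, free-energy trace, comparison
#' table and Bayesian model average into the run directory.
#'
#' @param config a `run_config` whose `out` contains a dataset.
#' @return list with `fit` and `comparison` (invisibly).
#' @export
run_fit <- function(config = run_config()) {
  data <- read_sensor_data(config$out, config$name)
  net <- read_network(file.path(config$out, "network.yaml"))
  if (data$grid$n != time_grid()$n && nrow(net$design) != length(data$data)) {
    stop("dataset and network design are inconsistent", call. = FALSE)
  }
  prior <- prior_belief(net)
  fit <- invert_erp(data, net,
    prior = prior,
    options = list(max_iter = config$max_iter, tol = config$tol)
  )
  cmp <- compare_reduced_models(fit, prior)
  write_belief(fit$posterior, file.path(config$out, "posterior.json"))
  utils::write.csv(
    tibble::tibble(iteration = seq_along(fit$trace), free_energy = fit$trace),
    file.path(config$out, "free_energy_trace.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    dplyr::select(cmp$models, "model", "kept", "delta_f", "prob"),
    file.path(config$out, "model_comparison.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      free_energy = fit$free_energy,
      converged = fit$converged,
      iterations = fit$iterations,
      noise_log_precision = fit$lambda$mean,
      residual_variance = as.list(fit$residual_variance),
      bma_mean = as.list(stats::setNames(
        unname(cmp$bma$mean[cmp$effects]), cmp$effects
      ))
    ),
    file.path(config$out, "fit_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_config(config, config$out)
  message(
    "fit F = ", format(fit$free_energy, digits = 6), "; winning model ",
    cmp$models$model[which.max(cmp$models$prob)]
  )
  invisible(list(fit = fit, comparison = cmp))
}

#' Run a recovery experiment and write its report
#'
#' @param config a `run_config`; `n_replicates`, `snr_db`, `seed` and
#'   the inversion options are taken from it.
#' @return the `recovery_report` (invisibly).
#' @export
run_recover <- function(config = run_config()) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  rep <- recovery_experiment(
    n_replicates = config$n_replicates, snr_db = config$snr_db,
    seed = config$seed,
    scenario = default_scenario(config_design(config)),
    options = list(max_iter = config$max_iter, tol = config$tol)
  )
  jsonlite::write_json(
    list(
      n_replicates = rep$n_replicates, snr_db = rep$snr_db,
      seed = rep$seed, model_hit_rate = rep$model_hit_rate,
      per_effect = rep$per_effect,
      failures = rep$failures
    ),
    file.path(config$out, "recovery_report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  utils::write.csv(rep$per_effect,
    file.path(config$out, "recovery_summary.csv"),
    row.names = FALSE
  )
  write_config(config, config$out)
  message(
    "recovery: hit rate ", format(rep$model_hit_rate, digits = 3),
    " over ", rep$n_replicates, " replicates"
  )
  invisible(rep)
}
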