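full_precision <- function(x) format(x, digits = 17, trim = TRUE)

#' Write and read sensor-level evoked responses
#'
#' `write_sensor_data()` serializes a `sensor_erp` as one delimited
#' numeric matrix (channels by samples) per condition plus a JSON
#' metadata sidecar (sampling rate, window, channel and condition
#' labels, condition covariates). `read_sensor_data()` reconstructs
#' the object; the round trip is lossless to full double precision.
#'
#' @param data a `sensor_erp`.
#' @param dir directory to write into (created if needed).
#' @param name file-name stem; conditions become
#'   `<name>_<condition>.csv` and metadata `<name>_meta.json`.
#' @return `write_sensor_data()` the sidecar path invisibly;
#'   `read_sensor_data()` a `sensor_erp`.
#' @export
write_sensor_data <- function(data, dir, name = "erp") {
  stopifnot(inherits(data, "sensor_erp"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(data$data)) {
    m <- data$data[[cond]]
    utils::write.table(
      matrix(full_precision(m), nrow(m), ncol(m)),
      file.path(dir, paste0(name, "_", cond, ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  meta <- list(
    rate = data$grid$rate, start = data$grid$start, stop = data$grid$stop,
    n_samples = data$grid$n, channels = data$channels,
    conditions = data$design$condition, covariates = data$design$covariate
  )
  path <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_data
#' @export
read_sensor_data <- function(dir, name = "erp") {
  meta <- jsonlite::read_json(
    file.path(dir, paste0(name, "_meta.json")),
    simplifyVector = TRUE
  )
  grid <- time_grid(meta$start, meta$stop, meta$rate)
  mats <- lapply(meta$conditions, function(cond) {
    m <- as.matrix(utils::read.table(
      file.path(dir, paste0(name, "_", cond, ".csv")),
      sep = ",", header = FALSE
    ))
    dimnames(m) <- list(meta$channels, NULL)
    m
  })
  names(mats) <- meta$conditions
  new_sensor_erp(
    mats, grid, meta$channels,
    tibble::tibble(condition = meta$conditions, covariate = meta$covariates)
  )
}

#' Write and read a network specification
#'
#' Serializes a `cmc_network` (sources, typed edge list with
#' modulation numbering, input targets, condition design) as YAML.
#' The load/save/load round trip is lossless.
#'
#' @param net a `cmc_network`.
#' @param path YAML file path.
#' @return `write_network()` the path invisibly; `read_network()` a
#'   validated `cmc_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cmc_network"))
  obj <- list(
    sources = net$sources,
    edges = lapply(seq_len(nrow(net$edges)), function(i) {
      e <- net$edges[i, ]
      list(
        from = e$from, to = e$to, type = e$type,
        effect = if (is.na(e$effect)) NULL else e$effect
      )
    }),
    input_targets = net$input_targets,
    design = list(
      condition = net$design$condition,
      covariate = net$design$covariate
    )
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- yaml::read_yaml(path)
  edges <- dplyr::bind_rows(lapply(obj$edges, function(e) {
    tibble::tibble(
      from = e$from, to = e$to, type = e$type,
      effect = if (is.null(e$effect)) NA_integer_ else as.integer(e$effect)
    )
  }))
  edges$label <- paste0(edges$from, "->", edges$to)
  edges$masked <- !is.na(edges$effect)
  net <- structure(
    list(
      sources = unlist(obj$sources),
      edges = edges,
      input_targets = unlist(obj$input_targets),
      design = tibble::tibble(
        condition = unlist(obj$design$condition),
        covariate = as.numeric(unlist(obj$design$covariate))
      )
    ),
    class = "cmc_network"
  )
  validate_network(net)
  net
}

#' Write and read a Gaussian belief
#'
#' Serializes a `gaussian_belief` as JSON (names and means) plus a
#' delimited covariance matrix next to it.
#'
#' @param belief a `gaussian_belief`.
#' @param path JSON path; the covariance goes to `<path>_cov.csv`.
#' @return `write_belief()` the path invisibly; `read_belief()` a
#'   `gaussian_belief`.
#' @export
write_belief <- function(belief, path) {
  stopifnot(inherits(belief, "gaussian_belief"))
  jsonlite::write_json(
    list(names = belief$names, mean = unname(belief$mean)),
    path,
    auto_unbox = FALSE, digits = NA
  )
  cov_path <- paste0(path, "_cov.csv")
  utils::write.table(
    matrix(full_precision(belief$cov), nrow(belief$cov)),
    cov_path,
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_belief
#' @export
read_belief <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- as.matrix(utils::read.table(paste0(path, "_cov.csv"), sep = ","))
  dimnames(cov) <- NULL
  gaussian_belief(obj$names, obj$mean, cov)
}

#' Write and read a ground-truth record
#'
#' @param truth a `ground_truth` from [generate_dataset()].
#' @param path JSON file path.
#' @param net the network the parameters belong to (needed to rebuild
#'   the `cmc_params` on read).
#' @return `write_ground_truth()` the path invisibly;
#'   `read_ground_truth()` a `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$params
  obj <- list(
    theta = as.list(flatten_params(p)),
    input_amplitude = p$input_amplitude,
    input_onset = p$input_onset,
    input_dispersion = p$input_dispersion,
    firing_gain = p$firing_gain,
    snr_db = truth$snr_db, seed = truth$seed,
    noise_sd = truth$noise_sd, channel_cor = truth$channel_cor,
    design = list(
      condition = truth$design$condition,
      covariate = truth$design$covariate
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path, net) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- cmc_parameters(net,
    input_amplitude = obj$input_amplitude,
    input_onset = obj$input_onset,
    input_dispersion = obj$input_dispersion,
    firing_gain = obj$firing_gain
  )
  params <- unflatten_params(unlist(obj$theta), template)
  structure(
    list(
      params = params,
      design = tibble::tibble(
        condition = obj$design$condition,
        covariate = as.numeric(obj$design$covariate)
      ),
      snr_db = if (is.character(obj$snr_db)) Inf else obj$snr_db,
      seed = obj$seed, noise_sd = obj$noise_sd,
      channel_cor = obj$channel_cor
    ),
    class = "ground_truth"
  )
}
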