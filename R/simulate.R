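#' Peristimulus time grid
#'
#' @param start,stop window bounds in seconds.
#' @param rate sampling rate in Hz.
#' @return An object of class `time_grid` with the sample times. The
#'   default covers 0 to 0.25 s at 600 Hz (150 samples).
#' @export
time_grid <- function(start = 0, stop = 0.25, rate = 600) {
  n <- round((stop - start) * rate)
  if (n < 2) stop("time grid must contain at least 2 samples", call. = FALSE)
  structure(
    list(
      start = start, stop = stop, rate = rate,
      times = start + (seq_len(n) - 1L) / rate,
      n = as.integer(n)
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(
    "<time_grid>", x$n, "samples,", x$start, "to", x$stop, "s at",
    x$rate, "Hz\n"
  )
  invisible(x)
}

#' Exogenous (geniculate) input
#'
#' A Gaussian bump of activity modelling the volley of input caused by
#' a cancellation event: peak `amplitude` at `onset`, spread
#' `dispersion`.
#'
#' @param t time (s); vectorized.
#' @param onset peak time (s).
#' @param dispersion Gaussian standard deviation (s); must be positive.
#' @param amplitude peak value (a.u.).
#' @return drive values, same length as `t`.
#' @export
exogenous_input <- function(t, onset = 0.06, dispersion = 0.016,
                            amplitude = 1) {
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be positive", call. = FALSE)
  }
  amplitude * exp(-(t - onset)^2 / (2 * dispersion^2))
}

#' Integrate the network dynamics over a time grid
#'
#' Solves the canonical-microcircuit flow from the zero initial state
#' with a fixed-step classical Runge-Kutta (4th order) scheme,
#' sub-stepping between output samples. A fixed-step integrator keeps
#' the pipeline bit-reproducible across platforms; the default two
#' sub-steps per sample (1/1200 s) are well inside the scheme's
#' stability region for the default rate constants.
#'
#' @param net a `cmc_network`.
#' @param params a `cmc_params`.
#' @param grid a `time_grid`.
#' @param condition_index design row whose effective gains drive the
#'   simulation.
#' @param substeps internal integration steps per output sample.
#' @param state_bound guard: integration aborts with an informative
#'   error if any state magnitude exceeds this bound.
#' @param engine `"cpp"` (compiled core, default) or `"r"` (pure-R
#'   reference implementation of the same scheme, used for
#'   cross-checking).
#'
#' @return An object of class `source_response`: matrix `voltage`
#'   (time by source-population, columns named `source.pop`), plus the
#'   grid and network.
#' @export
integrate_cmc <- function(net, params, grid = time_grid(),
                          condition_index = 1L, substeps = 2L,
                          state_bound = 1e6, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  coup <- build_coupling(params, net, condition_index)
  np <- length(coup$kappa)
  h <- 1 / (grid$rate * substeps)
  amp <- params$input_amplitude * exp(params$log_amp)
  fg <- params$firing_gain
  # drive sampled at half-step resolution for the RK4 stages
  n_sub <- substeps * (grid$n - 1L)
  u_times <- grid$start + (0:(2L * n_sub)) * (h / 2)
  u <- exogenous_input(u_times, params$input_onset,
    params$input_dispersion, amp)
  if (engine == "cpp") {
    out <- tryCatch(
      .cmc_integrate_cpp(
        coup$W, coup$cvec, coup$kappa, fg, u, h, grid$n, substeps,
        state_bound
      ),
      error = function(e) {
        stop(
          conditionMessage(e), "; largest log-scalings: ",
          paste(utils::head(names(sort(abs(flatten_params(params)),
            decreasing = TRUE
          )), 3), collapse = ", "),
          call. = FALSE
        )
      }
    )
  } else {
    out <- integrate_cmc_r(coup, fg, u, h, grid$n, substeps, state_bound,
      params)
  }
  colnames(out) <- paste(
    rep(net$sources, each = 4L), rep(cmc_populations(), length(net$sources)),
    sep = "."
  )
  structure(
    list(voltage = out, grid = grid, net = net,
         condition_index = condition_index),
    class = "source_response"
  )
}

# Pure-R reference RK4 integrator (same scheme as the compiled core).
integrate_cmc_r <- function(coup, fg, u, h, n_out, substeps, state_bound,
                            params) {
  np <- length(coup$kappa)
  x <- numeric(2L * np)
  vi <- seq(1L, 2L * np, by = 2L)
  out <- matrix(0, n_out, np)
  ustep <- 0L
  for (i in seq_len(n_out - 1L)) {
    for (s in seq_len(substeps)) {
      u0 <- u[2L * ustep + 1L]
      um <- u[2L * ustep + 2L]
      u1 <- u[2L * ustep + 3L]
      ustep <- ustep + 1L
      k1 <- cmc_flow_raw(x, u0, coup, fg)
      k2 <- cmc_flow_raw(x + h / 2 * k1, um, coup, fg)
      k3 <- cmc_flow_raw(x + h / 2 * k2, um, coup, fg)
      k4 <- cmc_flow_raw(x + h * k3, u1, coup, fg)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (anyNA(x) || max(abs(x)) > state_bound) {
      stop(
        "numerical blow-up during integration (|state| > ",
        format(state_bound), "); largest log-scalings: ",
        paste(utils::head(names(sort(abs(flatten_params(params)),
          decreasing = TRUE
        )), 3), collapse = ", "),
        call. = FALSE
      )
    }
    out[i + 1L, ] <- x[vi]
  }
  out
}

#' @export
as_tibble.source_response <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(x$voltage))
  df$time <- x$grid$times
  out <- tidyr::pivot_longer(df, -"time",
    names_to = c("source", "population"),
    names_sep = "\\.", values_to = "voltage"
  )
  out
}

# per-source contribution series seen by the sensors (default: the
# superficial pyramidal voltage, the origin of ascending connections)
source_contributions <- function(resp, population = "sp") {
  cols <- paste(resp$net$sources, population, sep = ".")
  resp$voltage[, cols, drop = FALSE]
}

#' Project source activity to the sensors
#'
#' Applies the linear lead field: each channel is a weighted sum of the
#' per-source contribution series (by default the superficial-pyramidal
#' voltage of each source).
#'
#' @param resp a `source_response`.
#' @param params a `cmc_params` carrying the channel-by-source `lead`
#'   matrix.
#' @param population which population's voltage the sensors see.
#' @return A channels-by-samples numeric matrix.
#' @export
apply_lead_field <- function(resp, params, population = "sp") {
  contrib <- source_contributions(resp, population) # time x sources
  y <- params$lead %*% t(contrib) # channels x time
  rownames(y) <- rownames(params$lead)
  y
}

#' Predict per-condition evoked responses at the sensors
#'
#' Runs the forward model once per experimental condition; conditions
#' differ only through the modulated edges' effective gains (covariate
#' values in the network design).
#'
#' @param net a `cmc_network`.
#' @param params a `cmc_params`.
#' @param grid a `time_grid`.
#' @param conditions integer indices into the design (default: all).
#' @param substeps integrator sub-steps per sample.
#' @return A `sensor_erp` object: list of channels-by-samples matrices
#'   (one per condition), with the grid, channel labels and design.
#' @export
predict_erp <- function(net, params, grid = time_grid(),
                        conditions = NULL, substeps = 2L) {
  if (is.null(conditions)) conditions <- seq_len(nrow(net$design))
  if (!all(conditions %in% seq_len(nrow(net$design)))) {
    stop("conditions must index rows of the network design", call. = FALSE)
  }
  mats <- lapply(conditions, function(j) {
    resp <- integrate_cmc(net, params, grid,
      condition_index = j,
      substeps = substeps
    )
    apply_lead_field(resp, params)
  })
  names(mats) <- net$design$condition[conditions]
  new_sensor_erp(mats, grid, rownames(params$lead),
    net$design[conditions, , drop = FALSE])
}

new_sensor_erp <- function(mats, grid, channels, design) {
  structure(
    list(data = mats, grid = grid, channels = channels,
         design = tibble::as_tibble(design)),
    class = "sensor_erp"
  )
}

#' @export
print.sensor_erp <- function(x, ...) {
  cat(
    "<sensor_erp>", length(x$data), "conditions x", length(x$channels),
    "channels x", x$grid$n, "samples (", x$grid$rate, "Hz )\n"
  )
  invisible(x)
}

#' @export
as_tibble.sensor_erp <- function(x, ...) {
  purrr::map_dfr(names(x$data), function(cond) {
    m <- x$data[[cond]]
    tibble::tibble(
      condition = cond,
      channel = rep(x$channels, times = ncol(m)),
      time = rep(x$grid$times, each = nrow(m)),
      value = as.vector(m)
    )
  })
}

# Stack a sensor_erp into one numeric vector (channel fastest, then
# time, then condition) — the data vector seen by the inversion.
stack_sensor_erp <- function(x) {
  as.numeric(unlist(lapply(x$data, as.vector), use.names = FALSE))
}
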