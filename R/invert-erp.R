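# Forward map and Jacobian for the ERP model, over the flattened
# parameter vector. The Jacobian uses central finite differences for
# the parameters that enter the dynamics and exact analytic columns
# for the lead-field gains (the observation stage is linear in them).
erp_forward_factory <- function(net, template, grid, substeps = 2L) {
  nm <- param_names(template)
  lead_idx <- which(startsWith(nm, "lead["))
  dyn_idx <- setdiff(seq_along(nm), lead_idx)
  n_cond <- nrow(net$design)
  n_ch <- nrow(template$lead)
  n_src <- length(net$sources)

  contribs <- function(theta) {
    p <- unflatten_params(theta, template)
    lapply(seq_len(n_cond), function(j) {
      source_contributions(
        integrate_cmc(net, p, grid, condition_index = j, substeps = substeps)
      )
    })
  }
  predict_from <- function(theta, ctr = NULL) {
    p <- unflatten_params(theta, template)
    if (is.null(ctr)) ctr <- contribs(theta)
    unlist(lapply(ctr, function(cm) as.vector(p$lead %*% t(cm))),
      use.names = FALSE
    )
  }
  forward <- function(theta) predict_from(theta)
  jacobian <- function(theta, eps = 1e-3) {
    base_ctr <- contribs(theta)
    n_t <- nrow(base_ctr[[1]])
    n_obs <- n_cond * n_ch * n_t
    J <- matrix(0, n_obs, length(nm), dimnames = list(NULL, nm))
    for (i in dyn_idx) {
      tp <- theta
      tm <- theta
      tp[i] <- tp[i] + eps
      tm[i] <- tm[i] - eps
      J[, i] <- (predict_from(tp) - predict_from(tm)) / (2 * eps)
    }
    # analytic columns: d y[ch, t, cond] / d lead[ch, src] is the
    # source's contribution trace, zero on other channels
    for (ci in lead_idx) {
      lab <- sub("^lead\\[(.*)\\]$", "\\1", nm[ci])
      parts <- strsplit(lab, ",", fixed = TRUE)[[1]]
      ch <- match(parts[1], rownames(template$lead))
      src <- match(parts[2], colnames(template$lead))
      col <- numeric(n_obs)
      for (j in seq_len(n_cond)) {
        off <- (j - 1L) * n_ch * n_t
        pos <- off + ch + (seq_len(n_t) - 1L) * n_ch
        col[pos] <- base_ctr[[j]][, src]
      }
      J[, ci] <- col
    }
    J
  }
  list(forward = forward, jacobian = jacobian, names = nm)
}

#' Fit the network model to sensor data by variational Laplace
#'
#' Inverts the canonical-microcircuit forward model: estimates all
#' log-scaling parameters (extrinsic, modulatory, intrinsic, input,
#' rate constants, input amplitude) and the lead-field gains from
#' per-condition evoked responses, together with the sensor-noise
#' log-precision.
#'
#' @param data a `sensor_erp` whose grid matches the model's.
#' @param net the `cmc_network` generating the predictions; its design
#'   must match the data's conditions.
#' @param prior `gaussian_belief` over the flattened parameters
#'   (default [prior_belief()]).
#' @param template a `cmc_params` supplying the fixed structural
#'   constants (input timing, firing gain, baseline amplitude).
#' @param options see [vl_invert()].
#'
#' @return A `vl_fit` (see [vl_invert()]) whose posterior is over the
#'   named network parameters, with per-channel residual variances in
#'   `$residual_variance`.
#' @export
invert_erp <- function(data, net, prior = NULL,
                       template = cmc_parameters(net),
                       options = list()) {
  stopifnot(inherits(data, "sensor_erp"))
  if (data$grid$n != time_grid(data$grid$start, data$grid$stop,
    data$grid$rate)$n) {
    stop("corrupt data time grid", call. = FALSE)
  }
  if (length(data$data) != nrow(net$design)) {
    stop(
      "data has ", length(data$data), " conditions but the design has ",
      nrow(net$design),
      call. = FALSE
    )
  }
  if (is.null(prior)) prior <- prior_belief(net, template)
  opt <- utils::modifyList(default_vl_options(), options)
  maps <- erp_forward_factory(net, template, data$grid,
    substeps = opt$substeps
  )
  if (!identical(maps$names, prior$names)) {
    stop("prior parameter names do not match the model's", call. = FALSE)
  }
  y <- stack_sensor_erp(data)
  fit <- vl_invert(y, maps$forward, prior,
    options = options,
    jacobian = function(theta) maps$jacobian(theta, eps = opt$fd_step)
  )
  # per-channel residual variance
  n_ch <- length(data$channels)
  res <- matrix(fit$residuals, nrow = n_ch)
  fit$residual_variance <- stats::setNames(
    apply(res, 1, function(r) mean(r^2)), data$channels
  )
  fit$net <- net
  fit$template <- template
  fit
}

#' Free energy of a parameter belief given sensor data
#'
#' Evaluates the variational free energy (accuracy minus complexity)
#' of a Gaussian belief about the network parameters: the expected
#' Gaussian log-likelihood of the residuals under the belief (via
#' local linearization of the forward model at the belief mean) minus
#' the KL divergence from the belief to the prior.
#'
#' @param data a `sensor_erp`.
#' @param belief,prior `gaussian_belief`s over the flattened
#'   parameters.
#' @param net the `cmc_network`.
#' @param template structural constants, as in [invert_erp()].
#' @param log_precision sensor-noise log-precision at which to
#'   evaluate the likelihood (treated as known here).
#' @param substeps integrator sub-steps.
#'
#' @return The free energy in nats, with attributes `accuracy` and
#'   `complexity`.
#' @export
free_energy <- function(data, belief, prior, net,
                        template = cmc_parameters(net),
                        log_precision = 0, substeps = 2L) {
  stopifnot(inherits(data, "sensor_erp"))
  if (!identical(belief$names, prior$names)) {
    stop("belief and prior must share parameter names", call. = FALSE)
  }
  tryCatch(chol(prior$cov), error = function(e) {
    stop("singular prior covariance", call. = FALSE)
  })
  maps <- erp_forward_factory(net, template, data$grid, substeps = substeps)
  y <- stack_sensor_erp(data)
  m <- unname(belief$mean)
  names(m) <- belief$names
  e <- y - maps$forward(m)
  J <- maps$jacobian(m)
  vl_free_energy_core(e, J, m, belief$cov, prior, log_precision,
    lambda_prior = NULL
  )
}
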