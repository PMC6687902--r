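# Default synthetic lead field: 4 channels x 5 sources. Mixed weights
# with opposite polarity on the temporoparietal source in the posterior
# channels, so every source leaves a distinguishable sensor footprint.
default_lead_field <- function(net) {
  ns <- length(net$sources)
  if (ns == 5) {
    L <- rbind(
      c(1.0, 0.3, 0.5, 0.1, 0.4),
      c(0.3, 1.0, 0.1, 0.5, 0.4),
      c(0.5, 0.1, 0.8, 0.2, -0.6),
      c(0.1, 0.5, 0.2, 0.8, -0.6)
    )
  } else {
    # deterministic mixed-sign pattern for non-default networks
    L <- outer(1:4, seq_len(ns), function(i, j) round(sin(i * j + 1), 2))
  }
  dimnames(L) <- list(paste0("c", 1:4), net$sources)
  L
}

#' Model parameters for the canonical-microcircuit network
#'
#' Creates the full parameter set of the generative model. All coupling
#' parameters are log-scalings around fixed positive templates: with
#' every log-scaling at zero the effective connectivity equals the
#' prior-mean template exactly, and because scalings enter through
#' `exp()` no connection can change sign during estimation.
#'
#' @param net a `cmc_network`.
#' @param a_fwd,a_bwd named log-scalings per forward/backward edge
#'   (default 0). Partial named vectors are merged over zeros.
#' @param b named log-slopes `b1..bk` per modulated effect (default 0);
#'   a modulated edge's gain in condition with covariate `X` is scaled
#'   by `exp(a + b * X)`.
#' @param g log-scalings per intrinsic connection class
#'   (`self`, `exc`, `inh`).
#' @param c log input gain per input target.
#' @param kappa log-scalings of the per-population rate constants.
#' @param log_amp log-scaling of the exogenous input amplitude.
#' @param input_amplitude baseline input amplitude (a.u.); the
#'   effective peak drive is `input_amplitude * exp(log_amp)`. The
#'   default puts peak source voltages at a few tenths of a mV, where
#'   the presynaptic sigmoid is mildly compressive.
#' @param input_onset,input_dispersion Gaussian input bump timing (s).
#' @param lead channel-by-source lead-field matrix (defaults to the
#'   package's fixed 4-channel synthetic lead field).
#' @param firing_gain slope of the presynaptic sigmoid at 0.
#'
#' @return An object of class `cmc_params`.
#' @export
cmc_parameters <- function(net,
                           a_fwd = NULL, a_bwd = NULL, b = NULL,
                           g = NULL, c = NULL, kappa = NULL,
                           log_amp = 0,
                           input_amplitude = 5,
                           input_onset = 0.06,
                           input_dispersion = 0.016,
                           lead = NULL,
                           firing_gain = 50) {
  e <- net$edges
  fwd_labels <- e$label[e$type == "forward"]
  bwd_labels <- e$label[e$type == "backward"]
  eff <- sort(e$effect[e$masked])
  merge_named <- function(defaults, user, what) {
    if (is.null(user)) {
      return(defaults)
    }
    if (is.null(names(user)) && length(user) == length(defaults)) {
      return(stats::setNames(as.numeric(user), names(defaults)))
    }
    bad <- setdiff(names(user), names(defaults))
    if (length(bad) > 0) {
      stop("unknown ", what, " entries: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    defaults[names(user)] <- user
    defaults
  }
  p <- structure(
    list(
      a_fwd = merge_named(
        stats::setNames(rep(0, length(fwd_labels)), fwd_labels),
        a_fwd, "a_fwd"
      ),
      a_bwd = merge_named(
        stats::setNames(rep(0, length(bwd_labels)), bwd_labels),
        a_bwd, "a_bwd"
      ),
      b = merge_named(
        stats::setNames(rep(0, length(eff)), paste0("b", eff)[seq_along(eff)]),
        b, "b"
      ),
      g = merge_named(c(self = 0, exc = 0, inh = 0), g, "g"),
      c = merge_named(
        stats::setNames(rep(0, length(net$input_targets)), net$input_targets),
        c, "c"
      ),
      kappa = merge_named(c(ss = 0, sp = 0, ii = 0, dp = 0), kappa, "kappa"),
      log_amp = log_amp,
      input_amplitude = input_amplitude,
      input_onset = input_onset,
      input_dispersion = input_dispersion,
      lead = if (is.null(lead)) default_lead_field(net) else lead,
      firing_gain = firing_gain
    ),
    class = "cmc_params"
  )
  if (!identical(colnames(p$lead), net$sources)) {
    stop("lead-field columns must match the network's sources", call. = FALSE)
  }
  p
}

#' @export
print.cmc_params <- function(x, ...) {
  cat(
    "<cmc_params>",
    length(x$a_fwd) + length(x$a_bwd), "extrinsic,",
    length(x$b), "modulatory,", length(x$g), "intrinsic,",
    length(x$c), "input log-scalings;",
    nrow(x$lead), "x", ncol(x$lead), "lead field\n"
  )
  invisible(x)
}

# Names of the estimable parameters, in flattening order.
param_names <- function(params) {
  c(
    paste0("a_f[", names(params$a_fwd), "]"),
    paste0("a_b[", names(params$a_bwd), "]"),
    names(params$b),
    paste0("g_", names(params$g)),
    paste0("c[", names(params$c), "]"),
    paste0("kappa_", names(params$kappa)),
    "log_amp",
    paste0(
      "lead[", rep(rownames(params$lead), times = ncol(params$lead)), ",",
      rep(colnames(params$lead), each = nrow(params$lead)), "]"
    )
  )
}

# Flatten the estimable parameters into a named numeric vector
# (column-major for the lead field). input_onset/dispersion and the
# firing gain are structural constants, not estimated.
flatten_params <- function(params) {
  stats::setNames(
    c(
      unname(params$a_fwd), unname(params$a_bwd), unname(params$b),
      unname(params$g), unname(params$c), unname(params$kappa),
      params$log_amp, as.vector(params$lead)
    ),
    param_names(params)
  )
}

# Rebuild a cmc_params from a flat vector using `template` for
# structure and the fixed (non-estimated) fields.
unflatten_params <- function(theta, template) {
  nm <- param_names(template)
  if (length(theta) != length(nm)) {
    stop("parameter vector length mismatch", call. = FALSE)
  }
  out <- template
  i <- 0L
  take <- function(k) {
    res <- theta[i + seq_len(k)]
    i <<- i + k
    unname(res)
  }
  out$a_fwd[] <- take(length(template$a_fwd))
  out$a_bwd[] <- take(length(template$a_bwd))
  out$b[] <- take(length(template$b))
  out$g[] <- take(length(template$g))
  out$c[] <- take(length(template$c))
  out$kappa[] <- take(length(template$kappa))
  out$log_amp <- take(1L)
  out$lead[] <- take(length(template$lead))
  out
}

#' Default prior belief over the model parameters
#'
#' Mildly shrinking Gaussian priors centered on the template (all
#' log-scalings zero, lead field at its fixed default): variance 1/16
#' for extrinsic, modulatory, intrinsic and input-gain log-scalings,
#' 1/128 for the rate-constant scalings, and unit variance for the
#' input amplitude and lead-field gains. A zero prior mean encodes "no
#' change" as the default belief about condition effects.
#'
#' @param net a `cmc_network`.
#' @param params optional `cmc_params` giving the prior mean structure
#'   (defaults to `cmc_parameters(net)`).
#'
#' @return A `gaussian_belief` over the estimable parameters.
#' @export
prior_belief <- function(net, params = cmc_parameters(net)) {
  mean <- flatten_params(params)
  # prior mean for log-scalings is 0 regardless of params used for shape
  nm <- names(mean)
  v <- numeric(length(mean))
  is_lead <- startsWith(nm, "lead[")
  is_kappa <- startsWith(nm, "kappa_")
  is_amp <- nm == "log_amp"
  v[is_lead] <- 1
  v[is_amp] <- 1
  v[is_kappa] <- 1 / 128
  v[!(is_lead | is_amp | is_kappa)] <- 1 / 16
  mean[!(is_lead)] <- 0
  mean["log_amp"] <- 0
  gaussian_belief(nm, mean, v)
}
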