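#' Enumerate reduced models over switchable condition effects
#'
#' Builds the full model space over `k` switchable effects: every
#' keep/remove combination, ordered by binary counting with effect 1
#' as the least significant bit. Pattern index 0 (first row) removes
#' every effect; the last row keeps all of them (the full model).
#'
#' @param effects character vector of effect (parameter) labels,
#'   1 to 20 of them.
#' @return A `model_space` tibble: column `model` (1-based index) and
#'   one logical keep-column per effect.
#' @export
#'
#' @examples
#' enumerate_reduced_models(paste0("b", 1:4)) # 16 models
enumerate_reduced_models <- function(effects) {
  k <- length(effects)
  if (k < 1 || k > 20) {
    stop("between 1 and 20 switchable effects are supported, got ", k,
      call. = FALSE
    )
  }
  n <- 2L^k
  keep <- matrix(FALSE, n, k, dimnames = list(NULL, effects))
  for (j in seq_len(k)) {
    keep[, j] <- bitwAnd(0:(n - 1L), bitwShiftL(1L, j - 1L)) > 0L
  }
  out <- tibble::as_tibble(as.data.frame(keep))
  out <- dplyr::bind_cols(tibble::tibble(model = seq_len(n)), out)
  class(out) <- c("model_space", class(out))
  out
}

#' Bayesian model reduction
#'
#' Computes, analytically, the change in log evidence and the reduced
#' posterior obtained by replacing the full model's prior with a
#' reduced prior, given the full model's posterior. All three beliefs
#' must live on the same parameters; the models may differ only in
#' their priors. In precision form, the reduced posterior combines
#' the full posterior with the prior swap:
#' reduced posterior precision = posterior + reduced prior - full
#' prior precision, with the matching precision-weighted mean, and the
#' evidence change is the Gaussian integral implied by the swap.
#'
#' @param full_posterior,full_prior,reduced_prior `gaussian_belief`s
#'   on identical parameter names.
#' @param label optional model label used in error messages.
#'
#' @return list with `delta_f` (nats, relative to the full model) and
#'   `posterior` (the reduced `gaussian_belief`).
#' @export
reduce_model <- function(full_posterior, full_prior, reduced_prior,
                         label = NULL) {
  if (!identical(full_posterior$names, full_prior$names) ||
    !identical(full_posterior$names, reduced_prior$names)) {
    stop("beliefs must share parameter names", call. = FALSE)
  }
  safe_prec <- function(b, what) {
    tryCatch(chol2inv(chol(b$cov)), error = function(e) {
      stop("singular ", what, " covariance", call. = FALSE)
    })
  }
  P0 <- safe_prec(full_prior, "full prior")
  Pr <- safe_prec(reduced_prior, "reduced prior")
  mu0 <- unname(full_prior$mean)
  mur <- unname(reduced_prior$mean)
  muq <- unname(full_posterior$mean)
  Sq <- full_posterior$cov
  # the prior swap as an exponential tilt: pr/p0 =
  #   |Pr/P0|^{1/2} exp(-1/2 th' dP th + th' dw - c0)
  dP <- Pr - P0
  dw <- as.numeric(Pr %*% mur - P0 %*% mu0)
  scale <- max(abs(dP), abs(dw), .Machine$double.eps)
  s <- which(rowSums(abs(dP)) > 1e-12 * scale | abs(dw) > 1e-12 * scale)
  if (length(s) == 0) {
    # identity reduction: evidence unchanged
    return(list(delta_f = 0, posterior = full_posterior))
  }
  logdet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  const <- 0.5 * (logdet(Pr) - logdet(P0)) -
    0.5 * (sum(mur * (Pr %*% mur)) - sum(mu0 * (P0 %*% mu0)))
  # the tilt only involves the changed coordinates: integrate it
  # against the posterior marginal there. Everything is computed from
  # covariances (never the posterior precision), so near-delta
  # posteriors stay numerically benign.
  D <- dP[s, s, drop = FALSE]
  w <- dw[s]
  M <- Sq[s, s, drop = FALSE]
  m <- muq[s]
  r <- length(s)
  IDM <- diag(r) + M %*% D
  # the reduced precision Pq + dP is positive definite iff every
  # eigenvalue of D M (real, as D M ~ M^1/2 D M^1/2) exceeds -1
  ev <- Re(eigen(D %*% M, only.values = TRUE)$values)
  K <- tryCatch(solve(IDM), error = function(e) NULL)
  if (is.null(K) || any(!is.finite(K)) || any(ev <= -1 + 1e-12)) {
    stop(
      "reduced-posterior precision is not positive definite",
      if (!is.null(label)) paste0(" for model ", label) else "",
      call. = FALSE
    )
  }
  dt <- determinant(IDM, logarithm = TRUE)
  v <- w - as.numeric(D %*% m)
  # E_q[exp(-1/2 e'De + v'e)] over e ~ N(0, M):
  #   det(I+MD)^{-1/2} exp( 1/2 v' (I+MD)^{-1} M v )
  delta_f <- const - 0.5 * sum(m * (D %*% m)) + sum(w * m) -
    0.5 * as.numeric(dt$modulus) +
    0.5 * sum(v * as.numeric(K %*% (M %*% v)))
  # reduced posterior via the matched low-rank downdate:
  #   Sqr = Sq - Sq[,s] (I + D M)^{-1} D Sq[s,]
  #   mqr = muq + Sqr[,s] v
  KD <- solve(diag(r) + D %*% M, D)
  Sqs <- Sq[, s, drop = FALSE]
  Sqr <- Sq - Sqs %*% KD %*% t(Sqs)
  Sqr <- repair_psd(Sqr)
  mqr <- muq + as.numeric(Sqr[, s, drop = FALSE] %*% v)
  list(
    delta_f = delta_f,
    posterior = gaussian_belief(full_posterior$names, mqr, Sqr)
  )
}

#' Posterior model probabilities from free energies
#'
#' Softmax of per-model (log-evidence) free energies, optionally with
#' non-uniform prior model probabilities, computed with max
#' subtraction so large evidence differences cannot overflow.
#'
#' @param free_energies numeric vector of free energies (nats).
#' @param prior_model_probs optional prior over models.
#' @return probabilities summing to one.
#' @export
model_posterior <- function(free_energies, prior_model_probs = NULL) {
  if (length(free_energies) == 0) {
    stop("at least one model is required", call. = FALSE)
  }
  if (any(!is.finite(free_energies))) {
    stop("free energies must be finite", call. = FALSE)
  }
  lp <- free_energies
  if (!is.null(prior_model_probs)) {
    if (length(prior_model_probs) != length(lp)) {
      stop("prior model probabilities must match the model count",
        call. = FALSE
      )
    }
    lp <- lp + log(prior_model_probs)
  }
  lp <- lp - max(lp)
  w <- exp(lp)
  w / sum(w)
}

#' Bayesian model averaging of Gaussian posteriors
#'
#' Moment-matched Gaussian of the probability-weighted mixture of
#' per-model posteriors: mean is the weighted mean, covariance adds
#' the between-model spread of the means to the weighted within-model
#' covariance.
#'
#' @param posteriors list of `gaussian_belief`s on identical names.
#' @param probs model probabilities (non-negative, summing to 1).
#' @return the averaged `gaussian_belief`.
#' @export
bma <- function(posteriors, probs) {
  stopifnot(length(posteriors) == length(probs), length(posteriors) >= 1)
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-6) {
    stop("`probs` must be a probability vector", call. = FALSE)
  }
  nm <- posteriors[[1]]$names
  for (p in posteriors) {
    if (!identical(p$names, nm)) {
      stop("posteriors must share parameter names", call. = FALSE)
    }
  }
  mu <- Reduce(`+`, Map(function(p, w) w * unname(p$mean), posteriors, probs))
  S2 <- Reduce(`+`, Map(
    function(p, w) w * (p$cov + tcrossprod(unname(p$mean))),
    posteriors, probs
  ))
  S <- S2 - tcrossprod(mu)
  gaussian_belief(nm, mu, repair_psd(S))
}

#' Linear parametric design over sequential events
#'
#' Covariate sequence for a linear parametric effect of event number:
#' `0, 1, ..., n_events - 1`. Because coupling changes are log-scaling
#' parameters, a linear covariate corresponds to a monoexponential
#' change in coupling across events. The two-event case recovers the
#' early/late contrast.
#'
#' @param n_events number of sequential events (>= 2).
#' @return integer covariate vector of length `n_events` starting at 0.
#' @export
parametric_design <- function(n_events) {
  if (!is.numeric(n_events) || n_events < 2) {
    stop("`n_events` must be at least 2", call. = FALSE)
  }
  seq.int(0L, n_events - 1L)
}

#' Coupling strength across events under a log-slope
#'
#' Percentage of the initial connection strength after `k` events
#' under log-slope `b_effect`: `100 * exp(k * b_effect)`. At `k = 0`
#' the coupling is `exp(0)`, i.e. 100% of baseline.
#'
#' @param b_effect log-slope per event (dimensionless).
#' @param k event index (0-based); vectorized.
#' @return percent of initial strength.
#' @export
coupling_trajectory <- function(b_effect, k) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  100 * exp(k * b_effect)
}

# Build the reduced prior for one keep/remove pattern: removed effects
# get mean 0 and variance `off_var` (a numerically stable stand-in for
# the zero-variance limit).
reduced_prior_for <- function(full_prior, effects, keep, off_var = 1e-8) {
  idx <- match(effects[!keep], full_prior$names)
  if (anyNA(idx)) stop("unknown effect names", call. = FALSE)
  mean <- unname(full_prior$mean)
  cov <- full_prior$cov
  for (i in idx) {
    mean[i] <- 0
    cov[i, ] <- 0
    cov[, i] <- 0
    cov[i, i] <- off_var
  }
  gaussian_belief(full_prior$names, mean, cov)
}

#' Compare all reduced models of the condition-specific effects
#'
#' Scores every keep/remove combination of the switchable effects by
#' Bayesian model reduction of one full inversion, converts the
#' evidence differences to posterior model probabilities, and forms
#' the Bayesian model average over all reduced posteriors.
#'
#' @param fit a `vl_fit` from [invert_erp()] (or [vl_invert()]).
#' @param prior the full-model prior used for the fit.
#' @param effects labels of the switchable effect parameters (default
#'   every `b` parameter in the prior).
#' @param prior_model_probs optional non-uniform prior over models.
#' @param off_var prior variance representing a switched-off effect.
#'
#' @return A `cmc_comparison`: `models` tibble (model id, kept
#'   effects, `delta_f` relative to the full model, `prob`), the list
#'   of reduced posteriors, and `bma` (the averaged belief).
#' @export
compare_reduced_models <- function(fit, prior, effects = NULL,
                                   prior_model_probs = NULL,
                                   off_var = 1e-8) {
  stopifnot(inherits(fit, "vl_fit"))
  if (is.null(effects)) {
    effects <- grep("^b[0-9]+$", prior$names, value = TRUE)
  }
  space <- enumerate_reduced_models(effects)
  keep_mat <- as.matrix(space[, effects, drop = FALSE])
  results <- lapply(seq_len(nrow(space)), function(i) {
    rp <- reduced_prior_for(prior, effects, keep_mat[i, ], off_var)
    reduce_model(fit$posterior, prior, rp, label = space$model[i])
  })
  delta_f <- vapply(results, function(r) r$delta_f, numeric(1))
  probs <- model_posterior(delta_f, prior_model_probs)
  posteriors <- lapply(results, function(r) r$posterior)
  avg <- bma(posteriors, probs)
  models <- dplyr::mutate(space,
    kept = apply(keep_mat, 1, function(k) {
      paste(effects[k], collapse = "+")
    }),
    delta_f = delta_f,
    prob = probs
  )
  structure(
    list(
      models = models, effects = effects, posteriors = posteriors,
      bma = avg, free_energy_full = fit$free_energy
    ),
    class = "cmc_comparison"
  )
}

#' @export
print.cmc_comparison <- function(x, ...) {
  best <- which.max(x$models$prob)
  cat(
    "<cmc_comparison>", nrow(x$models), "reduced models over effects {",
    paste(x$effects, collapse = ", "), "}\n"
  )
  cat(
    "  winning model:", x$models$model[best], "( keeps",
    ifelse(nzchar(x$models$kept[best]), x$models$kept[best], "none"),
    ") prob", format(x$models$prob[best], digits = 3), "\n"
  )
  invisible(x)
}
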