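default_vl_options <- function() {
  list(
    tol = 0.01,             # free-energy gain (nats) counting toward convergence
    tol_consecutive = 4L,   # accepted steps below tol needed to stop
    max_iter = 128L,
    lambda0 = 0,            # hyperprior mean for the noise log-precision
    lambda_var = 16,        # hyperprior variance
    fix_lambda = FALSE,     # if TRUE, lambda0 is used as a known precision
    fd_step = 1e-3,
    substeps = 2L,
    init = NULL,            # optional starting mean (default: prior mean)
    lm_init = 1e-6,         # initial Levenberg-Marquardt regularizer
    lm_shrink = 8,
    lm_max = 1e10,
    tie_tol = 1e-9,         # |dF| below this counts as a tie: accept
    verbose = FALSE
  )
}

# Free energy of a Gaussian belief q = N(m, S) about the parameters of
# a (locally linearized) nonlinear-Gaussian observation model:
#   accuracy  = E_q[log N(y; h(theta), exp(-lambda) I)]
#             ~ log N(y; h(m), exp(-lambda) I) - exp(lambda)/2 tr(S J'J)
#   complexity = KL(q || prior)
# plus, when the noise log-precision lambda is a free hyperparameter,
# the corresponding accuracy/complexity terms of its Gaussian belief
# (variance s_lambda from the local curvature).
vl_free_energy_core <- function(e, J, m, S, prior, lambda,
                                lambda_prior = NULL) {
  n <- length(e)
  k <- length(m)
  P0 <- chol2inv(chol(prior$cov))
  dm <- unname(m - prior$mean)
  A <- crossprod(J)
  trSA <- sum(S * A)
  ess <- sum(e * e)
  accuracy <- -n / 2 * log(2 * pi) + n / 2 * lambda -
    exp(lambda) / 2 * (ess + trSA)
  ld_S <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  ld_P0 <- as.numeric(determinant(P0, logarithm = TRUE)$modulus)
  complexity <- 0.5 * (sum(P0 * S) + sum(dm * (P0 %*% dm)) - k - ld_S - ld_P0)
  f <- accuracy - complexity
  if (!is.null(lambda_prior)) {
    E <- ess + trSA
    s_lam <- 1 / (exp(lambda) * E / 2 + 1 / lambda_prior[2])
    kl_lam <- 0.5 * (s_lam / lambda_prior[2] +
      (lambda - lambda_prior[1])^2 / lambda_prior[2] - 1 +
      log(lambda_prior[2] / s_lam))
    f <- f - kl_lam
  }
  structure(f, accuracy = accuracy, complexity = complexity)
}

# Newton ascent of the free energy in the noise log-precision, holding
# the parameter belief's curvature structure fixed. Concave in lambda;
# guarded by step-halving so the objective never decreases. The
# log-precision is capped 35 nats either side of its hyperprior mean:
# beyond that (noise ~1e-8 of signal scale) the likelihood is
# numerically saturated and larger precisions only destabilize the
# curvature algebra.
update_lambda <- function(ess, A, P0, lambda, lambda_prior, n,
                          max_steps = 8, cap = 35) {
  clamp <- function(l) {
    max(min(l, lambda_prior[1] + cap), lambda_prior[1] - cap)
  }
  obj <- function(l) {
    S <- tryCatch(chol2inv(chol(exp(l) * A + P0)), error = function(e) NULL)
    if (is.null(S)) {
      return(-Inf)
    }
    E <- ess + sum(S * A)
    n / 2 * l - exp(l) / 2 * E -
      (l - lambda_prior[1])^2 / (2 * lambda_prior[2])
  }
  lambda <- clamp(lambda)
  f_cur <- obj(lambda)
  for (i in seq_len(max_steps)) {
    S <- tryCatch(chol2inv(chol(exp(lambda) * A + P0)),
      error = function(e) NULL
    )
    if (is.null(S)) break
    E <- ess + sum(S * A)
    g <- n / 2 - exp(lambda) * E / 2 - (lambda - lambda_prior[1]) / lambda_prior[2]
    h <- -exp(lambda) * E / 2 - 1 / lambda_prior[2]
    step <- -g / h
    step <- max(min(step, 8), -8)
    while (abs(step) > 1e-12) {
      cand <- clamp(lambda + step)
      if (cand == lambda) break
      f_cand <- obj(cand)
      if (f_cand >= f_cur) {
        lambda <- cand
        f_cur <- f_cand
        break
      }
      step <- step / 2
    }
    if (abs(g) < 1e-8 * max(1, n)) break
  }
  lambda
}

#' Invert a nonlinear-Gaussian observation model by variational Laplace
#'
#' Maximizes a free-energy bound on the log model evidence for
#' `y = forward(theta) + noise`, with Gaussian prior over `theta`,
#' i.i.d. Gaussian observation noise with unknown log-precision, and a
#' Gaussian posterior (Laplace) assumption. Optimization is regularized
#' Gauss-Newton ascent: candidate steps that decrease the free energy
#' are rejected and the trust-region (Levenberg-Marquardt) regularizer
#' increased, so the trace of accepted free energies is non-decreasing
#' by construction. The noise log-precision is updated by guarded
#' Newton ascent interleaved with the parameter updates.
#'
#' @param y numeric data vector.
#' @param forward function mapping a named parameter vector to a
#'   predicted data vector.
#' @param prior a `gaussian_belief` over the parameters.
#' @param options list overriding the defaults: `tol` (free-energy
#'   convergence tolerance, nats), `tol_consecutive`, `max_iter`,
#'   `lambda0`/`lambda_var` (hyperprior on the noise log-precision),
#'   `fix_lambda`, `fd_step`, `lm_init`.
#' @param jacobian optional function `theta -> J` (n by k). Defaults to
#'   central finite differences via [sensitivity()].
#'
#' @return An object of class `vl_fit`: `posterior` (gaussian_belief),
#'   `free_energy`, `trace` (free energy per accepted iteration),
#'   `converged`, `iterations`, `lambda` (mean and variance of the
#'   noise log-precision belief), `residuals`, `n_obs`.
#' @export
vl_invert <- function(y, forward, prior, options = list(),
                      jacobian = NULL) {
  opt <- utils::modifyList(default_vl_options(), options)
  if (is.null(jacobian)) {
    jacobian <- function(theta) sensitivity(forward, theta, opt$fd_step)
  }
  P0 <- tryCatch(chol2inv(chol(prior$cov)), error = function(e) {
    stop("singular prior covariance: ", conditionMessage(e), call. = FALSE)
  })
  lam_prior <- if (opt$fix_lambda) NULL else c(opt$lambda0, opt$lambda_var)
  m <- unname(prior$mean)
  if (!is.null(opt$init)) {
    if (length(opt$init) != length(m)) {
      stop("`init` must match the prior dimension", call. = FALSE)
    }
    m <- unname(opt$init)
  }
  names(m) <- prior$names
  lambda <- opt$lambda0
  pred <- forward(m)
  if (length(pred) != length(y)) {
    stop("forward model prediction length does not match the data",
      call. = FALSE
    )
  }
  e <- y - pred
  n <- length(y)
  k <- length(m)

  belief_at <- function(m, S) {
    list(m = m, S = S)
  }
  f_of <- function(e, J, m, S, lambda) {
    as.numeric(vl_free_energy_core(
      e, J, m, S, prior, lambda, lam_prior
    ))
  }

  if (opt$max_iter == 0L) {
    # free energy of the prior belief itself (no-op contract)
    J <- jacobian(m)
    f_prior <- f_of(e, J, m, prior$cov, lambda)
    return(new_vl_fit(
      posterior = prior, free_energy = f_prior, trace = f_prior,
      converged = FALSE, iterations = 0L,
      lambda = list(mean = lambda, var = if (opt$fix_lambda) 0 else opt$lambda_var),
      residuals = e, n_obs = n, options = opt, floored = 0L
    ))
  }

  # Evaluate the objective at a parameter point: fresh linearization,
  # coordinate-ascent update of the noise log-precision, curvature
  # covariance, free energy. F is thereby a well-defined function of
  # (m, lambda-init), so accept/reject comparisons are consistent and
  # the accepted trace is monotone by construction.
  eval_point <- function(m, lambda) {
    pred <- tryCatch(forward(m), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) {
      return(NULL)
    }
    e <- y - pred
    J <- jacobian(m)
    A <- crossprod(J)
    if (!opt$fix_lambda) {
      lambda <- update_lambda(sum(e * e), A, P0, lambda, lam_prior, n)
    }
    S <- tryCatch(chol2inv(chol(exp(lambda) * A + P0)),
      error = function(e) NULL
    )
    if (is.null(S)) {
      return(NULL)
    }
    list(
      m = m, e = e, J = J, A = A, S = S, lambda = lambda,
      f = f_of(e, J, m, S, lambda)
    )
  }

  gamma <- opt$lm_init
  cur <- eval_point(m, lambda)
  if (is.null(cur) || !is.finite(cur$f)) {
    stop(
      "non-finite free energy at the prior mean; inspect prior scales ",
      "and data units",
      call. = FALSE
    )
  }
  trace <- cur$f
  n_small <- 0L
  converged <- FALSE
  iterations <- 0L

  for (iter in seq_len(opt$max_iter)) {
    iterations <- iter
    # gradient and curvature of the (expected) log joint at cur$m
    g <- exp(cur$lambda) * crossprod(cur$J, cur$e) -
      P0 %*% (cur$m - unname(prior$mean))
    H <- exp(cur$lambda) * cur$A + P0
    accepted <- FALSE
    best_short <- -Inf # best (negative) dF among rejected candidates
    for (try in 1:12) {
      R <- H + gamma * diag(diag(H), k)
      dm <- tryCatch(solve(R, g), error = function(e) NULL)
      if (!is.null(dm)) {
        m_new <- cur$m + as.numeric(dm)
        names(m_new) <- prior$names
        cand <- eval_point(m_new, cur$lambda)
        if (!is.null(cand) && is.finite(cand$f) &&
          cand$f >= cur$f - opt$tie_tol) {
          d_f <- cand$f - cur$f
          cand$f <- max(cand$f, cur$f)
          cur <- cand
          trace <- c(trace, cur$f)
          gamma <- max(gamma / opt$lm_shrink, 1e-10)
          n_small <- if (abs(d_f) < opt$tol) n_small + 1L else 0L
          accepted <- TRUE
          break
        }
        if (!is.null(cand) && is.finite(cand$f)) {
          best_short <- max(best_short, cand$f - cur$f)
        }
      }
      gamma <- gamma * opt$lm_shrink
      if (gamma > opt$lm_max) break
    }
    if (!accepted) {
      # no admissible uphill step remains: converged if every probe
      # sits within the free-energy tolerance of the current maximum
      converged <- n_small > 0L || best_short > -opt$tol
      break
    }
    if (opt$verbose) {
      message(sprintf("iter %3d  F = %.4f", iter, cur$f))
    }
    if (n_small >= opt$tol_consecutive) {
      converged <- TRUE
      break
    }
  }

  m <- cur$m
  e <- cur$e
  lambda <- cur$lambda
  f_best <- cur$f
  S <- repair_psd(cur$S)
  floored <- attr(S, "floored")
  E <- sum(e * e) + sum(S * cur$A)
  s_lam <- if (opt$fix_lambda) 0 else 1 / (exp(lambda) * E / 2 + 1 / opt$lambda_var)
  new_vl_fit(
    posterior = gaussian_belief(prior$names, m, S),
    free_energy = f_best, trace = trace, converged = converged,
    iterations = iterations,
    lambda = list(mean = lambda, var = s_lam),
    residuals = e, n_obs = n, options = opt, floored = floored
  )
}

new_vl_fit <- function(posterior, free_energy, trace, converged,
                       iterations, lambda, residuals, n_obs, options,
                       floored) {
  structure(
    list(
      posterior = posterior, free_energy = free_energy, trace = trace,
      converged = converged, iterations = iterations, lambda = lambda,
      residuals = residuals, n_obs = n_obs, options = options,
      floored = floored
    ),
    class = "vl_fit"
  )
}

#' @export
print.vl_fit <- function(x, ...) {
  cat(
    "<vl_fit> F =", format(x$free_energy, digits = 6), "nats after",
    x$iterations, "iterations (",
    if (x$converged) "converged" else "not converged", ")\n"
  )
  cat(
    "  noise log-precision:", format(x$lambda$mean, digits = 4),
    " residual sd:", format(exp(-x$lambda$mean / 2), digits = 4), "\n"
  )
  invisible(x)
}

#' Finite-difference sensitivity of a forward model
#'
#' Central-difference Jacobian of a forward model's predictions with
#' respect to its parameters.
#'
#' @param forward function from named parameter vector to prediction
#'   vector.
#' @param theta named parameter vector at which to differentiate.
#' @param eps step size (must be positive).
#' @return An n-by-k Jacobian with columns named after `theta`.
#' @export
sensitivity <- function(forward, theta, eps = 1e-3) {
  if (!is.numeric(eps) || eps <= 0) {
    stop("`eps` must be positive", call. = FALSE)
  }
  base <- forward(theta)
  k <- length(theta)
  J <- matrix(0, length(base), k, dimnames = list(NULL, names(theta)))
  for (i in seq_len(k)) {
    tp <- theta
    tm <- theta
    tp[i] <- tp[i] + eps
    tm[i] <- tm[i] - eps
    J[, i] <- (forward(tp) - forward(tm)) / (2 * eps)
  }
  J
}
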