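# Shared fixtures, all built in code.

# A single cortical source with exogenous drive and no extrinsic
# edges; used for tests of the within-source dynamics.
make_single_source_network <- function() {
  net <- structure(
    list(
      sources = "src",
      edges = tibble::tibble(
        from = character(), to = character(), type = character(),
        effect = integer(), label = character(), masked = logical()
      ),
      input_targets = "src",
      design = tibble::tibble(condition = "on", covariate = 0)
    ),
    class = "cmc_network"
  )
  validate_network(net)
  net
}

# Conjugate linear-Gaussian regression fixture with closed-form
# evidence: y = X theta + noise of known precision exp(lambda).
make_linear_fixture <- function(seed = 42, n = 40, k = 3,
                                theta = c(0.5, -1, 0.25),
                                noise_sd = 0.2, prior_var = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * k), n, k)
    y <- as.vector(X %*% theta) + stats::rnorm(n, sd = noise_sd)
  })
  prior <- gaussian_belief(paste0("t", seq_len(k)), rep(0, k),
    diag(prior_var, k))
  lambda <- log(1 / noise_sd^2)
  # closed-form log marginal likelihood for an arbitrary prior
  evidence <- function(pr) {
    C <- noise_sd^2 * diag(n) + X %*% pr$cov %*% t(X)
    r <- y - as.vector(X %*% unname(pr$mean))
    -n / 2 * log(2 * pi) -
      0.5 * as.numeric(determinant(C, logarithm = TRUE)$modulus) -
      0.5 * sum(r * solve(C, r))
  }
  # closed-form posterior
  P0 <- solve(prior$cov)
  Pn <- exp(lambda) * crossprod(X) + P0
  Sn <- solve(Pn)
  mn <- as.vector(Sn %*% (exp(lambda) * crossprod(X, y) +
    P0 %*% unname(prior$mean)))
  list(
    X = X, y = y, prior = prior, lambda = lambda,
    forward = function(th) as.vector(X %*% th),
    evidence = evidence,
    post_mean = mn, post_cov = Sn
  )
}

# Matrix-exponential solution of the linearized network driven by the
# Gaussian input bump: the independent oracle for the integrator.
# Uses exact exponential stepping with the input held constant over
# fine sub-intervals.
linear_response_oracle <- function(net, params, grid, condition_index = 1L,
                                   refine = 10L) {
  A <- erpdcm:::cmc_jacobian0(params, net, condition_index)
  coup <- erpdcm:::build_coupling(params, net, condition_index)
  nx <- nrow(A)
  B <- numeric(nx)
  vi <- seq(1L, nx, by = 2L)
  B[vi + 1L] <- coup$kappa * coup$cvec
  h <- 1 / (grid$rate * refine)
  eAh <- as.matrix(Matrix::expm(A * h))
  # integral of expm(A (h - s)) B ds for constant input over the step
  AinvE <- solve(A, eAh - diag(nx))
  amp <- params$input_amplitude * exp(params$log_amp)
  x <- numeric(nx)
  out <- matrix(0, grid$n, nx / 2)
  for (i in seq_len(grid$n - 1L)) {
    for (s in seq_len(refine)) {
      t_mid <- grid$times[i] + (s - 0.5) * h
      u <- exogenous_input(t_mid, params$input_onset,
        params$input_dispersion, amp)
      x <- as.vector(eAh %*% x + AinvE %*% (B * u))
    }
    out[i + 1L, ] <- x[vi]
  }
  colnames(out) <- paste(
    rep(net$sources, each = 4L),
    rep(erpdcm:::cmc_populations(), length(net$sources)),
    sep = "."
  )
  out
}

# Small-amplitude parameter set on the attention network, deep in the
# linear regime of the presynaptic sigmoid.
small_amplitude_params <- function(net, amp = 1e-3) {
  cmc_parameters(net, input_amplitude = amp)
}
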