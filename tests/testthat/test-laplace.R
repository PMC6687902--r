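test_that("linear-Gaussian inversion reproduces the conjugate posterior", {
  fx <- make_linear_fixture()
  fit <- vl_invert(fx$y, fx$forward, fx$prior,
    options = list(
      fix_lambda = TRUE, lambda0 = fx$lambda,
      tol = 1e-9, max_iter = 200
    )
  )
  logz <- fx$evidence(fx$prior)
  expect_lt(abs(fit$free_energy - logz) / abs(logz), 1e-6)
  expect_equal(unname(fit$posterior$mean), fx$post_mean, tolerance = 1e-6)
  expect_equal(fit$posterior$cov, fx$post_cov,
    tolerance = 1e-6,
    ignore_attr = TRUE
  )
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= -1e-9))
})

test_that("free energy decomposes into accuracy minus complexity", {
  # belief equal to the prior carries zero complexity
  fx <- make_linear_fixture()
  e <- fx$y - fx$forward(unname(fx$prior$mean))
  J <- fx$X
  f <- erpdcm:::vl_free_energy_core(
    e, J, unname(fx$prior$mean), fx$prior$cov, fx$prior, fx$lambda
  )
  expect_equal(attr(f, "complexity"), 0, tolerance = 1e-12)

  # with fixed large residuals, inflating the noise precision beyond
  # its optimum strictly decreases the accuracy term
  e2 <- c(2, -2)
  J2 <- matrix(0, 2, 1)
  pr <- gaussian_belief("a", 0, 1)
  acc <- vapply(c(0, 1, 2, 3), function(l) {
    attr(erpdcm:::vl_free_energy_core(e2, J2, 0, pr$cov, pr, l), "accuracy")
  }, numeric(1))
  expect_true(all(diff(acc) < 0))
})

test_that("zero-iteration inversion returns the prior belief", {
  fx <- make_linear_fixture()
  fit <- vl_invert(fx$y, fx$forward, fx$prior,
    options = list(max_iter = 0, fix_lambda = TRUE, lambda0 = fx$lambda)
  )
  expect_equal(fit$posterior$mean, fx$prior$mean)
  expect_equal(fit$posterior$cov, fx$prior$cov)
  expect_equal(fit$iterations, 0L)
  expect_length(fit$trace, 1)
})

test_that("singular priors and impossible starts fail loudly", {
  fx <- make_linear_fixture()
  sing <- fx$prior
  sing$cov[2, 2] <- 0
  expect_error(
    vl_invert(fx$y, fx$forward, sing),
    "singular prior"
  )
  expect_error(
    vl_invert(fx$y, function(th) rep(NaN, length(fx$y)), fx$prior),
    "non-finite free energy"
  )
})

test_that("sensitivity gives accurate, self-consistent derivatives", {
  f <- function(th) c(th[1]^2 + th[2], sin(th[2]), exp(th[1] / 2))
  th <- c(a = 0.7, b = -0.3)
  J <- sensitivity(f, th, eps = 1e-4)
  expect_equal(colnames(J), c("a", "b"))
  J_true <- rbind(
    c(2 * 0.7, 1),
    c(0, cos(-0.3)),
    c(exp(0.35) / 2, 0)
  )
  expect_equal(unname(J), J_true, tolerance = 1e-6)
  # Richardson check: halving the step barely moves central differences
  J2 <- sensitivity(f, th, eps = 5e-5)
  expect_lt(max(abs(J - J2)), 1e-8)
  # and agrees with a one-sided secondary estimate
  J1 <- (f(th + c(1e-6, 0)) - f(th)) / 1e-6
  expect_equal(J[, "a"], J1, tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(sensitivity(f, th, eps = 0), "positive")
})

test_that("modulation parameters have zero sensitivity when no condition differs", {
  # with all covariates zero the b parameters mask no pathway
  net <- build_attention_network(
    design = tibble::tibble(condition = c("one", "two"), covariate = c(0, 0))
  )
  template <- cmc_parameters(net)
  maps <- erpdcm:::erp_forward_factory(net, template, time_grid(0, 0.05, 600))
  theta <- erpdcm:::flatten_params(template)
  J <- maps$jacobian(theta)
  expect_true(all(abs(J[, paste0("b", 1:4)]) < 1e-9))
})

test_that("analytic lead-field sensitivity equals the contribution trace", {
  net <- build_attention_network()
  template <- cmc_parameters(net)
  grid <- time_grid(0, 0.1, 600)
  maps <- erpdcm:::erp_forward_factory(net, template, grid)
  theta <- erpdcm:::flatten_params(template)
  J <- maps$jacobian(theta)
  fd <- sensitivity(maps$forward, theta, eps = 1e-4)
  lead_cols <- grep("^lead\\[", colnames(J))
  expect_equal(J[, lead_cols], fd[, lead_cols], tolerance = 1e-6)
})

test_that("noiseless self-consistency: truth at the prior mean is retained", {
  net <- build_attention_network()
  p <- cmc_parameters(net) # prior-mean parameters
  ds <- generate_dataset(net, p, snr_db = Inf, seed = 1)
  prior <- prior_belief(net)
  fit <- invert_erp(ds$data, net, prior = prior, options = list(max_iter = 24))
  prior_sd <- sqrt(diag(prior$cov))
  expect_true(all(
    abs(unname(fit$posterior$mean) - unname(prior$mean)) <= prior_sd
  ))
  # residual variance far below any plausible injected-noise floor
  expect_lt(max(fit$residual_variance), 1e-12)
  expect_true(all(diff(fit$trace) >= -1e-9))
})
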