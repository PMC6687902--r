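test_that("model enumeration covers every keep/remove pattern", {
  sp <- enumerate_reduced_models(paste0("b", 1:4))
  expect_equal(nrow(sp), 16)
  keep <- as.matrix(sp[, paste0("b", 1:4)])
  expect_false(any(keep[1, ])) # pattern 0: everything removed
  expect_true(all(keep[16, ])) # last: the full model
  expect_equal(sum(rowSums(keep) == 4), 1)
  # binary counting, effect 1 least significant
  expect_equal(unname(keep[2, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(keep[3, ]), c(FALSE, TRUE, FALSE, FALSE))
  expect_false(anyDuplicated(apply(keep, 1, paste, collapse = "")) > 0)

  expect_equal(nrow(enumerate_reduced_models("b1")), 2)
  expect_error(enumerate_reduced_models(character(0)), "between 1 and 20")
  expect_error(enumerate_reduced_models(paste0("e", 1:21)), "between 1 and 20")
})

test_that("identity reduction leaves evidence and posterior untouched", {
  fx <- make_linear_fixture()
  fit <- vl_invert(fx$y, fx$forward, fx$prior,
    options = list(fix_lambda = TRUE, lambda0 = fx$lambda, tol = 1e-9)
  )
  red <- reduce_model(fit$posterior, fx$prior, fx$prior)
  expect_identical(red$delta_f, 0)
  expect_equal(red$posterior$mean, fit$posterior$mean)
})

test_that("analytic reduction matches the closed-form evidence change", {
  fx <- make_linear_fixture()
  fit <- vl_invert(fx$y, fx$forward, fx$prior,
    options = list(fix_lambda = TRUE, lambda0 = fx$lambda, tol = 1e-9)
  )
  for (drop in list(3L, c(2L, 3L))) {
    rcov <- fx$prior$cov
    rmean <- unname(fx$prior$mean)
    for (i in drop) {
      rcov[i, ] <- 0
      rcov[, i] <- 0
      rcov[i, i] <- 1e-8
      rmean[i] <- 0
    }
    rprior <- gaussian_belief(fx$prior$names, rmean, rcov)
    red <- reduce_model(fit$posterior, fx$prior, rprior)
    direct <- fx$evidence(rprior) - fx$evidence(fx$prior)
    expect_lt(abs(red$delta_f - direct) / abs(direct), 1e-6)
  }
})

test_that("shrinking the prior on a truly-zero effect is rewarded on average", {
  # Occam's effect: removing a parameter the data do not need should
  # not hurt the evidence, across seeded replicates
  dfs <- vapply(1:20, function(s) {
    fx <- make_linear_fixture(seed = 100 + s, theta = c(0.5, -1, 0))
    fit <- vl_invert(fx$y, fx$forward, fx$prior,
      options = list(fix_lambda = TRUE, lambda0 = fx$lambda, tol = 1e-9)
    )
    rcov <- fx$prior$cov
    rcov[3, ] <- 0
    rcov[, 3] <- 0
    rcov[3, 3] <- 1e-8
    rprior <- gaussian_belief(fx$prior$names, c(0.5, -1, 0) * 0, rcov)
    reduce_model(fit$posterior, fx$prior, rprior)$delta_f
  }, numeric(1))
  expect_gt(mean(dfs), 0)
})

test_that("incompatible reductions fail naming the model", {
  post <- gaussian_belief(c("a", "b"), c(0, 0), diag(2, 2))
  full_prior <- gaussian_belief(c("a", "b"), c(0, 0), diag(1, 2))
  wide <- gaussian_belief(c("a", "b"), c(0, 0), diag(100, 2))
  expect_error(
    reduce_model(post, full_prior, wide, label = "m7"),
    "not positive definite.*m7"
  )
})

test_that("model posteriors are a safe softmax", {
  expect_equal(model_posterior(c(0, 0)), c(0.5, 0.5))
  expect_equal(model_posterior(c(log(3), 0)), c(0.75, 0.25))
  p <- model_posterior(stats::rnorm(32, sd = 500))
  expect_true(all(p >= 0))
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_equal(
    model_posterior(c(0, 0), prior_model_probs = c(0.9, 0.1)),
    c(0.9, 0.1)
  )
  expect_error(model_posterior(numeric(0)), "at least one")
  expect_error(model_posterior(c(0, NA)), "finite")
})

test_that("model averaging moment-matches the mixture", {
  b1 <- gaussian_belief("x", 1, matrix(1))
  b2 <- gaussian_belief("x", -1, matrix(1))
  expect_equal(bma(list(b1), 1), b1)
  avg_same <- bma(list(b1, b1), c(0.5, 0.5))
  expect_equal(avg_same$mean, b1$mean)
  expect_equal(avg_same$cov, b1$cov, ignore_attr = TRUE)

  mix <- bma(list(b1, b2), c(0.5, 0.5))
  expect_equal(unname(mix$mean), 0)
  expect_equal(mix$cov[1, 1], 2) # 1 + between-model spread of means
  # Monte-Carlo cross-check of the matched moments
  draws <- withr::with_seed(1, {
    z <- stats::rbinom(2e5, 1, 0.5)
    stats::rnorm(2e5, mean = ifelse(z == 1, 1, -1), sd = 1)
  })
  expect_equal(mean(draws), unname(mix$mean), tolerance = 0.02)
  expect_equal(stats::var(draws), mix$cov[1, 1], tolerance = 0.03)

  expect_error(bma(list(b1, gaussian_belief("y", 0, matrix(1))), c(.5, .5)),
    "share parameter names")
  expect_error(bma(list(b1, b2), c(0.7, 0.7)), "probability vector")
})

test_that("parametric designs count events from zero", {
  expect_equal(parametric_design(16), 0:15)
  expect_equal(parametric_design(2), c(0, 1))
  expect_equal(parametric_design(5)[1], 0)
  expect_error(parametric_design(1), "at least 2")
})

test_that("coupling trajectories are monoexponential from 100%", {
  expect_equal(coupling_trajectory(-0.73, 0), 100)
  expect_equal(coupling_trajectory(0, 0:15), rep(100, 16))
  expect_equal(coupling_trajectory(-0.05, 15), 100 * exp(-0.75))
  expect_error(coupling_trajectory(0.1, -1), "non-negative")
})

test_that("16-event gains follow the coupling trajectory exactly", {
  design <- tibble::tibble(
    condition = sprintf("ev%02d", 1:16),
    covariate = parametric_design(16)
  )
  net <- build_attention_network(design)
  b <- c(b1 = 0.02, b2 = 0.1, b3 = -0.05, b4 = -0.4)
  p <- cmc_parameters(net, b = b)
  base <- effective_gains(p, net, 1)
  for (k in c(0, 3, 15)) {
    g <- effective_gains(p, net, k + 1)
    eff <- net$edges$effect[match(g$label, net$edges$label)]
    expected <- rep(1, nrow(g))
    idx <- which(!is.na(eff))
    expected[idx] <-
      coupling_trajectory(unname(b[paste0("b", eff[idx])]), k) / 100
    expect_equal(g$gain / base$gain, expected, tolerance = 1e-12)
  }
})

test_that("reduction agrees with direct re-inversion on a network fixture", {
  # remove the truly-null effect (edge 1) and compare the analytic
  # evidence change against a full re-inversion under the reduced prior
  # the direct route starts from the full fit's optimum (pinned effect
  # zeroed) so both routes score the same posterior basin rather than
  # whichever local optimum each search happens to reach
  scen <- default_scenario()
  ds <- generate_dataset(scen$net, scen$params, snr_db = 30, seed = 5)
  prior <- prior_belief(scen$net)
  fit_full <- invert_erp(ds$data, scen$net,
    prior = prior,
    options = list(max_iter = 48)
  )
  rprior <- erpdcm:::reduced_prior_for(prior, "b1", FALSE)
  red <- reduce_model(fit_full$posterior, prior, rprior)
  init <- unname(fit_full$posterior$mean)
  init[match("b1", prior$names)] <- 0
  fit_red <- invert_erp(ds$data, scen$net,
    prior = rprior,
    options = list(max_iter = 48, init = init)
  )
  direct <- fit_red$free_energy - fit_full$free_energy
  expect_lt(abs(red$delta_f - direct), 0.5)
})
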