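test_that("attention network has the published structure", {
  net <- build_attention_network()
  expect_setequal(net$sources, c("lFEF", "rFEF", "lIPS", "rIPS", "rTPJ"))
  expect_equal(nrow(net$edges), 8)
  expect_equal(sum(net$edges$masked), 4)
  # modulation numbering: 1 rTPJ->lFEF, 2 rTPJ->rFEF, 3 lFEF->rTPJ,
  # 4 rFEF->rTPJ
  masked <- net$edges[net$edges$masked, ]
  expect_equal(
    masked$label[order(masked$effect)],
    c("rTPJ->lFEF", "rTPJ->rFEF", "lFEF->rTPJ", "rFEF->rTPJ")
  )
  expect_equal(masked$type[order(masked$effect)],
    c("forward", "forward", "backward", "backward"))
  # every ascending edge has a matching descending counterpart
  fwd <- net$edges[net$edges$type == "forward", ]
  bwd <- net$edges[net$edges$type == "backward", ]
  expect_setequal(paste(fwd$from, fwd$to), paste(bwd$to, bwd$from))
  expect_true("rTPJ" %in% net$input_targets)
  expect_equal(erpdcm:::n_states(net), 40)
})

test_that("network invariants are enforced", {
  net <- build_attention_network()
  overlap <- net
  overlap$edges <- dplyr::bind_rows(
    overlap$edges,
    tibble::tibble(
      from = "rTPJ", to = "lFEF", type = "backward",
      effect = NA_integer_, label = "rTPJ->lFEF", masked = FALSE
    )
  )
  expect_error(validate_network(overlap), "disjoint|duplicate")
  stray <- net
  stray$input_targets <- c(stray$input_targets, "V1")
  expect_error(validate_network(stray), "declared sources")
})

test_that("effective gains scale log-linearly and never change sign", {
  net <- build_attention_network()
  p0 <- cmc_parameters(net)
  g1 <- effective_gains(p0, net, 1)
  expect_equal(g1$gain, g1$template)
  expect_true(all(g1$gain > 0))

  p <- cmc_parameters(net, b = c(b3 = -0.5))
  early <- effective_gains(p, net, 1)
  late <- effective_gains(p, net, 2)
  on3 <- early$label == "lFEF->rTPJ"
  expect_equal(late$gain[on3] / early$gain[on3],
    rep(exp(-0.5), sum(on3)),
    tolerance = 1e-12
  )
  # unmodulated edges identical across conditions
  un <- early$label == "lIPS->lFEF"
  expect_equal(late$gain[un], early$gain[un])

  # positive slope on an inhibitory (backward) edge strengthens the
  # inhibition without a sign flip
  pp <- cmc_parameters(net, b = c(b4 = 0.8))
  e <- effective_gains(pp, net, 1)
  l <- effective_gains(pp, net, 2)
  on4 <- e$label == "rFEF->rTPJ"
  expect_true(all(l$gain[on4] > e$gain[on4]))
  expect_true(all(l$sign[on4] == -1))
  expect_true(all(l$gain[on4] > 0))

  expect_error(effective_gains(p0, net, 99), "unknown condition")
})

test_that("effective gains are continuous in the parameters", {
  net <- build_attention_network()
  eps <- 1e-7
  g0 <- effective_gains(cmc_parameters(net), net, 2)
  g1 <- effective_gains(cmc_parameters(net, b = c(b2 = eps)), net, 2)
  expect_lt(max(abs(g1$gain - g0$gain)), 1e-5)
})

test_that("presynaptic transform is odd, bounded, zero-centered", {
  expect_identical(firing_rate(0), 0)
  v <- seq(-5, 5, by = 0.25)
  expect_equal(firing_rate(v), -firing_rate(-v))
  expect_true(all(abs(firing_rate(v * 100)) <= 1))
  expect_true(all(diff(firing_rate(v)) >= 0))
  # slope at the origin equals the configured gain
  for (gain in c(0.5, 1, 50)) {
    slope <- (firing_rate(1e-7, gain) - firing_rate(-1e-7, gain)) / 2e-7
    expect_equal(slope, gain, tolerance = 1e-6)
  }
})

test_that("zero state with zero input is an exact equilibrium", {
  net <- build_attention_network()
  p <- cmc_parameters(net)
  dx <- cmc_flow(numeric(40), 0, p, net)
  expect_identical(dx, numeric(40))
  expect_error(cmc_flow(numeric(12), 0, p, net), "length")
})

test_that("an impulse drives only the stellate cells of input targets", {
  net <- build_attention_network()
  p <- cmc_parameters(net)
  p$c[c("lIPS", "rIPS")] <- -Inf # silence all inputs but rTPJ
  dx <- cmc_flow(numeric(40), 1, p, net)
  nz <- which(dx != 0)
  # rTPJ is source 5; its spiny stellate conductance is entry 8*(5-1)+2
  expect_equal(nz, 8 * 4 + 2)
})

test_that("the prior-mean network is damped at equilibrium", {
  net <- build_attention_network()
  J <- erpdcm:::cmc_jacobian0(cmc_parameters(net), net)
  ev <- eigen(J, only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
})

test_that("doubling all rate constants halves the impulse-response peak time", {
  net <- make_single_source_network()
  peak_time <- function(kappa_scale) {
    p <- cmc_parameters(net, kappa = rep(kappa_scale, 4))
    A <- erpdcm:::cmc_jacobian0(p, net)
    x <- numeric(8)
    x[2] <- 1 # impulse on spiny stellate conductance
    times <- seq(0, 0.2, by = 1e-4)
    v_sp <- vapply(times, function(t) {
      as.numeric((Matrix::expm(A * t) %*% x)[3]) # superficial pyramidal v
    }, numeric(1))
    times[which.max(abs(v_sp))]
  }
  t1 <- peak_time(0)
  t2 <- peak_time(log(2))
  expect_equal(t2, t1 / 2, tolerance = 0.02)
})

test_that("parameter flattening round-trips", {
  net <- build_attention_network()
  p <- cmc_parameters(net,
    b = c(b1 = 0.2, b3 = -0.3), g = c(inh = 0.1),
    kappa = c(ss = 0.05), log_amp = -0.2
  )
  theta <- erpdcm:::flatten_params(p)
  p2 <- erpdcm:::unflatten_params(theta, cmc_parameters(net))
  expect_equal(erpdcm:::flatten_params(p2), theta)
  expect_equal(p2$b, p$b)
  expect_equal(p2$lead, p$lead)
})
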