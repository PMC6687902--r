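test_that("default time grid covers 0-250 ms at 600 Hz", {
  g <- time_grid()
  expect_equal(g$n, 150L)
  expect_equal(g$times[1], 0)
  expect_equal(diff(g$times)[1], 1 / 600)
  expect_error(time_grid(0, 0.001, 600), "at least 2")
})

test_that("exogenous input is a symmetric Gaussian bump", {
  expect_equal(exogenous_input(0.06, onset = 0.06, amplitude = 3), 3)
  expect_equal(exogenous_input(seq(0, 1, 0.1), amplitude = 0),
    rep(0, 11))
  d <- 0.01
  expect_equal(
    exogenous_input(0.06 + d),
    exogenous_input(0.06 - d)
  )
  expect_error(exogenous_input(0, dispersion = 0), "positive")
  expect_error(exogenous_input(0, dispersion = -1), "positive")
})

test_that("integration from zero input stays exactly at zero", {
  net <- build_attention_network()
  p <- cmc_parameters(net, input_amplitude = 0)
  r <- integrate_cmc(net, p)
  expect_true(all(r$voltage == 0))
})

test_that("compiled and reference integrators agree bit-for-bit", {
  net <- build_attention_network()
  p <- cmc_parameters(net, b = c(b2 = 0.1, b3 = -0.4))
  for (j in 1:2) {
    a <- integrate_cmc(net, p, condition_index = j, engine = "cpp")
    b <- integrate_cmc(net, p, condition_index = j, engine = "r")
    expect_identical(a$voltage, b$voltage)
  }
})

test_that("integration is self-convergent under step refinement", {
  net <- build_attention_network()
  p <- cmc_parameters(net)
  r1 <- integrate_cmc(net, p, substeps = 2L)
  r2 <- integrate_cmc(net, p, substeps = 4L)
  rel <- sqrt(sum((r1$voltage - r2$voltage)^2) / sum(r2$voltage^2))
  expect_lt(rel, 0.005)
})

test_that("small-amplitude responses match the matrix-exponential oracle", {
  net <- build_attention_network()
  p <- small_amplitude_params(net)
  num <- integrate_cmc(net, p)$voltage
  lin <- linear_response_oracle(net, p, time_grid())
  rel <- sqrt(sum((num - lin)^2) / sum(lin^2))
  expect_lt(rel, 0.01)
})

test_that("state-bound violations fail with an informative error", {
  net <- build_attention_network()
  p <- cmc_parameters(net)
  expect_error(
    integrate_cmc(net, p, state_bound = 1e-9),
    "blow-up"
  )
  expect_error(
    integrate_cmc(net, p, state_bound = 1e-9, engine = "r"),
    "blow-up"
  )
})

test_that("lead-field projection is linear in the source response", {
  net <- build_attention_network()
  p <- cmc_parameters(net)
  r <- integrate_cmc(net, p)
  y <- apply_lead_field(r, p)
  expect_equal(dim(y), c(4, 150))
  r0 <- r
  r0$voltage[] <- 0
  expect_true(all(apply_lead_field(r0, p) == 0))
  r2 <- r
  r2$voltage <- 2 * r$voltage
  expect_equal(apply_lead_field(r2, p), 2 * y)
  # identity lead field reads out each source's contribution directly
  p_id <- cmc_parameters(net,
    lead = diag(5)[, ] |>
      (\(L) {
        dimnames(L) <- list(paste0("s", 1:5), net$sources)
        L
      })()
  )
  y_id <- apply_lead_field(r, p_id)
  expect_equal(unname(y_id), unname(t(erpdcm:::source_contributions(r))))
})

test_that("condition predictions differ only through modulated edges", {
  net <- build_attention_network()
  p0 <- cmc_parameters(net) # all b = 0
  pred0 <- predict_erp(net, p0)
  expect_identical(pred0$data[[1]], pred0$data[[2]])
  expect_equal(length(pred0$data), 2)
  expect_equal(dim(pred0$data[[1]]), c(4, 150))

  # repeated runs are bit-identical (deterministic pipeline)
  pred0b <- predict_erp(net, p0)
  expect_identical(pred0$data, pred0b$data)
})

test_that("reduced descending inhibition raises late TPJ output", {
  net <- build_attention_network()
  p <- cmc_parameters(net, b = c(b3 = -0.4, b4 = -0.4))
  early <- integrate_cmc(net, p, condition_index = 1)
  late <- integrate_cmc(net, p, condition_index = 2)
  amp <- function(r) max(abs(erpdcm:::source_contributions(r)[, "rTPJ.sp"]))
  expect_gt(amp(late), amp(early))
})

test_that("sensor data tidies into a long tibble", {
  net <- build_attention_network()
  pred <- predict_erp(net, cmc_parameters(net))
  df <- as_tibble(pred)
  expect_s3_class(df, "tbl_df")
  expect_equal(nrow(df), 2 * 4 * 150)
  expect_named(df, c("condition", "channel", "time", "value"))
  m <- pred$data[["early"]]
  sub <- df[df$condition == "early" & df$channel == "c2", ]
  expect_equal(sub$value, unname(m[2, ]))
})
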