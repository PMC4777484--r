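test_that("classic-limit clamp reproduces the sigmoid steady state and a
           degenerate dual-exponential fit", {
  cp <- voltageClampProtocol(target_V = 30, target_duration = 95)
  tr <- runGateClamp("n", cp, eta = 1, dt = 0.01)
  expect_lt(abs(as.numeric(estimateXinfEta(tr)) - hhSteadyState(30)[["n"]]),
            1e-3)
  f <- fitExponentials(tr)
  expect_lt(abs(f$tau_fast / f$tau_slow - 1), 0.02)
  expect_lt(abs(f$tau_fast / hhTau(30)[["n"]] - 1), 0.02)
  # x_inf^eta at eta = 1 matches alpha/(alpha+beta) across gates/voltages
  for (gate in c("n", "m", "h")) {
    for (V in c(-40, 10)) {
      cp2 <- voltageClampProtocol(target_V = V, target_duration = 115)
      tr2 <- runGateClamp(gate, cp2, eta = 1, dt = 0.01)
      expect_lt(abs(as.numeric(suppressWarnings(estimateXinfEta(tr2))) -
                      hhSteadyState(V)[[gate]]), 1e-3)
    }
  }
})

test_that("fractional clamp responses cross the classic ones: faster early,
           slower late", {
  cp <- voltageClampProtocol(target_V = 30, target_duration = 91)
  t1 <- runGateClamp("n", cp, 1, dt = 0.01)
  t5 <- runGateClamp("n", cp, 0.5, dt = 0.01)
  d <- t5$x - t1$x
  tt <- t1$t_ms
  expect_gt(d[which.min(abs(tt - 0.1))], 0)   # early: fractional ahead
  expect_lt(d[which.min(abs(tt - 90))], 0)    # late: fractional behind
})

test_that("power-law order reshapes the long-term response of n but not m", {
  slope <- function(df) max(abs(diff(df$x_inf_eta) / diff(df$V)), na.rm = TRUE)
  sn1 <- slope(clampXinfSweep("n", 1, dt = 0.01))
  sn4 <- slope(clampXinfSweep("n", 0.4, dt = 0.01))
  sm1 <- slope(clampXinfSweep("m", 1, dt = 0.01))
  sm4 <- slope(clampXinfSweep("m", 0.4, dt = 0.01))
  expect_lt(sn4, sn1)                      # n-gate sigmoid gets shallower
  expect_lt(abs(sm4 - sm1) / sm1, 0.1)     # m-gate inflection nearly unchanged
})

test_that("dual-exponential time constants split as the order decreases", {
  # large-amplitude deactivation command; depolarized commands leave the
  # n gate nearly saturated and the fast component poorly determined
  cp <- voltageClampProtocol(target_V = -100, target_duration = 95)
  fits <- lapply(c(1, 0.8, 0.6, 0.4), function(eta)
    fitExponentials(runGateClamp("n", cp, eta, dt = 0.01)))
  tf <- vapply(fits, `[[`, numeric(1), "tau_fast")
  ts <- vapply(fits, `[[`, numeric(1), "tau_slow")
  expect_true(all(diff(tf) < 0))   # fast constant accelerates
  expect_true(all(diff(ts) > 0))   # slow constant slows down
})

test_that("exponential fit recovers known parameters from synthetic data", {
  t <- seq(0, 100, by = 0.01)
  x <- 0.8 - 0.25 * exp(-t / 2) - 0.25 * exp(-t / 20)
  tr <- structure(data.frame(t_ms = t, V_mV = 30, x = x),
                  gate = "n", eta = 0.5, target_onset = 0, dt = 0.01,
                  protocol = voltageClampProtocol(target_V = 30),
                  class = c("gate_clamp", "data.frame"))
  f <- fitExponentials(tr)
  expect_lt(abs(f$tau_fast / 2 - 1), 0.05)
  expect_lt(abs(f$tau_slow / 20 - 1), 0.05)
  expect_lt(abs(f$x_inf_fit - 0.8), 0.01)
  f1 <- fitExponentials(tr, n_components = 1)
  expect_identical(f1$tau_fast, f1$tau_slow)
})

test_that("numeric-vs-analytic error is tiny in the classic limit and
           decreases with dt", {
  r1 <- numericVsAnalyticMse("n", etas = 1, Vs = 30, dt = 0.001)
  expect_lt(r1$mse, 1e-8)
  ra <- numericVsAnalyticMse("n", etas = 0.5, Vs = 30, dt = 0.01)
  rb <- numericVsAnalyticMse("n", etas = 0.5, Vs = 30, dt = 0.001)
  expect_lt(rb$mse, ra$mse)
  # unstable m-gate traces are excluded and counted
  rm <- numericVsAnalyticMse("m", etas = 0.1, Vs = -55, dt = 0.01)
  expect_identical(rm$n_unstable, 1L)
  expect_identical(rm$n_traces, 0L)
})

test_that("clamp traces too short for the read time are rejected", {
  cp <- voltageClampProtocol(target_V = 30, target_duration = 50)
  tr <- runGateClamp("n", cp, eta = 1, dt = 0.01)
  expect_error(estimateXinfEta(tr), "too short")
})
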