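test_that("hybrid scheme equals an independent R implementation step by step", {
  # short runs, compared to a from-scratch R stepper with the same coupling
  for (cfg in list(list(gate = "n", eta = 0.5, I = 5, total = 5, dt = 0.05),
                   list(gate = "h", eta = 0.7, I = 12, total = 5, dt = 0.05))) {
    # current stays on past the trace end: the oracle applies a constant
    # current, so the final RK4 substeps must not straddle the falling edge
    tr <- simulateHybrid(
      fconfig = fractionalConfig(cfg$gate, eta = cfg$eta, dt = cfg$dt),
      protocol = stepCurrentProtocol(cfg$I, duration = cfg$total + 1,
                                     total_time = cfg$total))
    ora <- oracle_hybrid(cfg$gate, cfg$eta, cfg$I, cfg$total, cfg$dt)
    expect_equal(tr$V_mV, ora$V_mV, tolerance = 1e-10)
    expect_equal(tr[[cfg$gate]], ora[[cfg$gate]], tolerance = 1e-10)
    expect_equal(tr$memtrace, ora$memtrace, tolerance = 1e-10)
  }
})

test_that("eta = 1 and gate = none reproduce the classic model exactly", {
  p <- stepCurrentProtocol(18, duration = 100)
  trc <- simulateClassic(protocol = p, dt = 0.01)
  tr1 <- simulateHybrid(fconfig = fractionalConfig("n", eta = 1, dt = 0.01),
                        protocol = p)
  tr0 <- simulateHybrid(fconfig = fractionalConfig("none", dt = 0.01),
                        protocol = p)
  expect_identical(trc$V_mV, tr1$V_mV)
  expect_identical(trc$V_mV, tr0$V_mV)
  expect_true(all(tr1$memtrace == 0))
})

test_that("windowed memory with a full-length window reproduces full memory
           exactly, and truncation reports an error bound", {
  p <- stepCurrentProtocol(10, duration = 50)
  full <- simulateHybrid(fconfig = fractionalConfig("n", eta = 0.6, dt = 0.05),
                         protocol = p)
  win <- simulateHybrid(
    fconfig = fractionalConfig("n", eta = 0.6, dt = 0.05, truncation = 10000),
    protocol = p)
  expect_identical(full$V_mV, win$V_mV)
  expect_identical(attr(win, "truncation_error_bound"), 0)
  short <- simulateHybrid(
    fconfig = fractionalConfig("n", eta = 0.6, dt = 0.05, truncation = 100),
    protocol = p)
  expect_gt(attr(short, "truncation_error_bound"), 0)
  # truncated run deviates, but by no more than ~the reported per-step bound
  # accumulated over the run
  expect_gt(max(abs(short$n - full$n)), 0)
})

test_that("power-law m gate at low order raises a divergence error", {
  expect_error(
    runGateClamp("m", voltageClampProtocol(target_V = -55,
                                           target_duration = 40),
                 eta = 0.1, dt = 0.001),
    class = "frachh_divergence")
  err <- tryCatch(
    simulateHybrid(fconfig = fractionalConfig("m", eta = 0.1, dt = 0.01),
                   protocol = stepCurrentProtocol(10, duration = 200)),
    frachh_divergence = function(e) e)
  expect_s3_class(err, "frachh_divergence")
  # the diagnostic names the configuration
  expect_match(conditionMessage(err), "gate=m")
  expect_match(conditionMessage(err), "eta=0.1")
})

test_that("clamped fractional gates stay bounded for eta >= 0.3", {
  for (gate in c("n", "h")) {
    for (eta in c(0.3, 0.6)) {
      tr <- runGateClamp(gate, voltageClampProtocol(target_V = 30,
                                                    target_duration = 50),
                         eta = eta, dt = 0.01)
      expect_true(all(tr$x >= -0.01 & tr$x <= 1.01))
    }
  }
})

test_that("numerical clamp solution converges to the Mittag-Leffler solution
           as dt decreases", {
  x0 <- hhSteadyState(0)[["n"]]
  errs <- vapply(c(0.1, 0.01, 0.001), function(dt) {
    n <- round(90 / dt)
    t <- seq_len(n) * dt
    num <- frachh:::.gateClampL1Cpp(0L, 0.5, x0, 30, -65, n, dt, 10)
    keep <- abs(t / 0.1 - round(t / 0.1)) < 1e-9   # common 0.1-ms grid
    ana <- analyticGateResponse(30, 0.5, x0, t[keep], "n")
    max(abs(num[keep] - ana))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
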