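test_that("sub-threshold oscillation detector finds damped sinusoid maxima
           and nothing on flat traces", {
  t <- seq(0, 1000, by = 0.1)
  V <- -60 + 5 * exp(-t / 800) * sin(2 * pi * 30 * t / 1000)
  tr <- structure(data.frame(t_ms = t, V_mV = V),
                  class = c("sim_trace", "data.frame"))
  osc <- detectSubthresholdOscillations(tr)
  # 30 Hz over 1 s: all ~30 maxima found (amplitude stays above prominence)
  expect_equal(nrow(osc), 30, tolerance = 0.05)
  expect_true(all(osc$V_mV < -20))
  flat <- structure(data.frame(t_ms = t, V_mV = -65),
                    class = c("sim_trace", "data.frame"))
  expect_identical(nrow(detectSubthresholdOscillations(flat)), 0L)
  # maxima above the ceiling are excluded
  hi <- structure(data.frame(t_ms = t, V_mV = V + 50),
                  class = c("sim_trace", "data.frame"))
  expect_identical(nrow(detectSubthresholdOscillations(hi)), 0L)
})

test_that("classifier labels synthetic archetypes of each pattern", {
  mk <- function(spike_times, osc_times = numeric(0), plateau = NULL,
                 total = 1500) {
    tr <- synthetic_spike_train(spike_times, total = total)
    for (to in osc_times) {
      b <- -60 + 8 * exp(-(tr$t_ms - to)^2 / 8)   # sub-threshold bump
      tr$V_mV <- pmax(tr$V_mV, b)
    }
    if (!is.null(plateau))
      tr$V_mV[tr$t_ms >= plateau[1] & tr$t_ms <= plateau[2]] <- -10
    attr(tr, "protocol") <- stepCurrentProtocol(10, duration = total)
    tr
  }
  expect_identical(classifyPattern(mk(5))$label, "RS")
  expect_identical(classifyPattern(mk(c(20, 60, 110, 180)))$label, "PS")
  expect_identical(classifyPattern(mk(seq(10, 1490, by = 15)))$label, "TS")
  # single spikes with oscillations interleaved
  sp <- seq(50, 1450, by = 100)
  expect_identical(classifyPattern(mk(sp, osc_times = sp[-1] - 50))$label,
                   "MMO")
  # bursts of 4 spikes separated by oscillation-filled silent phases
  bursts <- as.vector(outer(c(0, 15, 30, 45), seq(100, 1400, by = 300), "+"))
  silent_osc <- as.vector(outer(c(100, 150, 200), seq(145, 1145, by = 300), "+"))
  expect_identical(classifyPattern(mk(bursts, osc_times = silent_osc))$label,
                   "SWB")
  expect_identical(classifyPattern(mk(c(20), plateau = c(25, 80)))$label,
                   "PPB")
  # labels are deterministic
  tr <- mk(sp, osc_times = sp[-1] - 50)
  expect_identical(classifyPattern(tr)$label, classifyPattern(tr)$label)
  expect_error(classifyPattern(mk(5, total = 800)), "1500")
})

test_that("phase-diagram sweep labels cells, marks divergent cells as
           unstable, and shows the classic column structure", {
  pd <- sweepPhaseDiagram("n", I_values = c(2, 18), eta_values = 1,
                          duration = 1500, dt = 0.01)
  expect_identical(unname(pd$labels[, 1]), c("RS", "TS"))
  pdm <- sweepPhaseDiagram("m", I_values = 10, eta_values = c(0.1, 0.6),
                           duration = 1500, dt = 0.02)
  expect_identical(unname(pdm$labels[1, ]), c("UNST", "TS"))
  expect_true(all(!is.na(pd$labels)))
})

test_that("strong input recovers tonic firing for moderate orders", {
  for (cfg in list(c("n", 0.4), c("h", 0.5))) {
    tr <- simulateHybrid(
      fconfig = fractionalConfig(cfg[1], eta = as.numeric(cfg[2]), dt = 0.02),
      protocol = stepCurrentProtocol(20, duration = 1500))
    expect_identical(classifyPattern(tr)$label, "TS")
  }
})
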