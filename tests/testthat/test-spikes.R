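test_that("spike detector recovers known event times and ignores quiet traces", {
  times <- c(20, 55, 90.5, 140)
  tr <- synthetic_spike_train(times)
  sp <- detectSpikes(tr)
  expect_identical(sp$n_spikes, length(times))
  expect_equal(sp$spike_times, times, tolerance = 0.05)
  expect_true(all(abs(sp$peak_V - 30) < 0.1))
  # flat trace: nothing
  flat <- structure(data.frame(t_ms = seq(0, 100, 0.1), V_mV = -65),
                    class = c("sim_trace", "data.frame"))
  expect_identical(detectSpikes(flat)$n_spikes, 0L)
  # sub-threshold oscillations (staying below 0 mV) are not spikes
  t <- seq(0, 200, 0.05)
  osc <- structure(
    data.frame(t_ms = t, V_mV = -60 + 10 * sin(2 * pi * t / 30)),
    class = c("sim_trace", "data.frame"))
  expect_identical(detectSpikes(osc)$n_spikes, 0L)
})

test_that("firing rate is consistent with the inter-spike intervals on a
           tonic trace", {
  tr <- simulateClassic(protocol = stepCurrentProtocol(18, duration = 1500),
                        dt = 0.01)
  sp <- detectSpikes(tr)
  expect_equal(sp$firing_rate, 84, tolerance = 0.01)
  rate_isi <- 1000 / mean(diff(sp$spike_times))
  expect_lt(abs(sp$firing_rate - rate_isi) / rate_isi, 0.05)
})

test_that("half-width is exact on triangular geometry and stable under
           decimation", {
  # symmetric triangular spike, base 2 ms, from -65 to +35: half level
  # crossings are 1 ms apart regardless of the baseline convention
  t <- seq(0, 40, by = 0.001)
  V <- -65 + pmax(0, 100 * (1 - abs(t - 20)))
  tr <- structure(data.frame(t_ms = t, V_mV = V),
                  class = c("sim_trace", "data.frame"))
  sp <- detectSpikes(tr)
  expect_equal(halfWidth(tr, sp, 1, baseline = "trough"), 1, tolerance = 1e-3)
  # model spike: decimating the stored trace by 2 changes the interpolated
  # width only marginally
  full <- simulateClassic(protocol = stepCurrentProtocol(10, duration = 60),
                          dt = 0.001)
  half <- full[seq(1, nrow(full), by = 2), ]
  attr(half, "protocol") <- attr(full, "protocol")
  w1 <- halfWidth(full)
  w2 <- halfWidth(half)
  expect_lt(abs(w1 - w2), 0.01)
})

test_that("pseudo-plateau events make the half-width undefined", {
  t <- seq(0, 200, by = 0.01)
  V <- ifelse(t > 20, 10, -65)     # plateau persisting to the trace end
  V[t > 18 & t <= 20] <- -65 + (t[t > 18 & t <= 20] - 18) * 37.5
  tr <- structure(data.frame(t_ms = t, V_mV = V),
                  class = c("sim_trace", "data.frame"))
  sp <- detectSpikes(tr)
  expect_identical(sp$n_spikes, 1L)
  expect_error(halfWidth(tr, sp, 1, baseline = "trough"),
               class = "frachh_halfwidth")
})

test_that("grid scan for the current threshold agrees with a bisection oracle", {
  fc <- fractionalConfig("none", dt = 0.01)
  th <- currentThreshold(fconfig = fc)
  # independent bisection on "elicits at least 2 spikes" at 0.01-nA resolution
  spikes_at <- function(I) {
    tr <- simulateClassic(protocol = stepCurrentProtocol(I, duration = 500),
                          dt = 0.01)
    detectSpikes(tr)$n_spikes
  }
  lo <- 1; hi <- 24
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) >= 2) hi <- mid else lo <- mid
  }
  expect_lte(abs(th$I_two - hi), th$grid_step)
  expect_lte(th$I_one, th$I_two)
  # below-threshold grid returns the no-threshold sentinel
  none <- currentThreshold(fconfig = fc, I_grid = seq(0.5, 2, by = 0.5))
  expect_true(is.na(none$I_two))
})

test_that("voltage threshold lies in the physiological envelope and the
           criterion failure is reported", {
  th <- currentThreshold(fconfig = fractionalConfig("none", dt = 0.01),
                         keep_trace = TRUE)
  v <- voltageThreshold(th$trace)
  expect_gt(v, -60)
  expect_lt(v, -40)
  slow <- structure(
    data.frame(t_ms = seq(0, 300, 0.5),
               V_mV = -65 + 70 * pmin(1, seq(0, 300, 0.5) / 250)),
    class = c("sim_trace", "data.frame"))
  expect_error(voltageThreshold(slow, index = 1), "dv/dt")
})

test_that("phase-plane decomposition satisfies the current balance exactly", {
  tr <- simulateClassic(protocol = stepCurrentProtocol(18, duration = 200),
                        dt = 0.01)
  pp <- phasePlane(tr)
  expect_identical(pp$imbalance, pp$INa + pp$Iw)
  expect_identical(pp$Iw, tr$IK + tr$IL + tr$Iin)
  # the classic tonic orbit closes on itself: compare successive cycles
  sp <- detectSpikes(tr)
  i3 <- which(tr$t_ms >= sp$spike_times[3] & tr$t_ms < sp$spike_times[4])
  i4 <- which(tr$t_ms >= sp$spike_times[4] & tr$t_ms < sp$spike_times[5])
  n <- min(length(i3), length(i4))
  dist <- max(sqrt((pp$INa[i3[1:n]] - pp$INa[i4[1:n]])^2 +
                     (pp$Iw[i3[1:n]] - pp$Iw[i4[1:n]])^2))
  diam <- max(pp$INa) - min(pp$INa)
  expect_lt(dist / diam, 0.01)
})
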