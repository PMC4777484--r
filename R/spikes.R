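#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of 0 mV followed by a local maximum;
#' upward crossings closer than 2 ms to the previous one are treated as the
#' same event. Sub-threshold oscillations (which stay well below 0 mV in
#' this model) are never detected as spikes. The firing rate is the spike
#' count divided by the stimulation window.
#'
#' @param trace a `sim_trace` (or any data frame with `t_ms` and `V_mV`).
#' @param threshold_mV crossing level, default 0 mV.
#' @param min_separation_ms minimum separation between crossings (ms).
#' @param window stimulation window `c(start, end)` in ms used for the rate;
#'   defaults to the protocol's current step (or the full trace).
#' @return A `spike_features` list: `spike_times` (ms, time of peak),
#'   `peak_V` (mV), `crossing_times` (ms), `n_spikes`, `firing_rate` (Hz).
#' @export
detectSpikes <- function(trace, threshold_mV = 0, min_separation_ms = 2,
                         window = NULL) {
  t <- trace$t_ms
  V <- trace$V_mV
  up <- which(V[-length(V)] < threshold_mV & V[-1] >= threshold_mV)
  if (length(up) > 1) {
    keep <- c(TRUE, diff(t[up]) >= min_separation_ms)
    up <- up[keep]
  }
  spike_times <- peak_V <- numeric(length(up))
  for (i in seq_along(up)) {
    i0 <- up[i]
    i1 <- if (i < length(up)) up[i + 1] - 1L else length(V)
    # end of this suprathreshold event: first return below threshold
    below <- which(V[i0:i1] < threshold_mV)
    if (length(below) > 1) i1 <- i0 + below[below > 1][1] - 1L
    seg <- i0:i1
    j <- seg[which.max(V[seg])]
    spike_times[i] <- t[j]
    peak_V[i] <- V[j]
  }
  if (is.null(window)) {
    proto <- attr(trace, "protocol")
    window <- if (!is.null(proto))
      c(proto$onset, proto$onset + proto$duration) else range(t)
  }
  structure(list(spike_times = spike_times, peak_V = peak_V,
                 crossing_times = t[up], n_spikes = length(up),
                 firing_rate = length(up) / (diff(window) / 1000),
                 window = window),
            class = "spike_features")
}

#' @export
print.spike_features <- function(x, ...) {
  cat(sprintf("%d spikes in [%g, %g] ms: firing rate %.2f Hz\n",
              x$n_spikes, x$window[1], x$window[2], x$firing_rate))
  invisible(x)
}

#' Width of an action potential at half-height
#'
#' The spike height is the peak voltage minus a baseline, and the width is
#' the time between the two crossings of the half-height level, linearly
#' interpolated between samples. The default baseline is the spike's voltage
#' threshold (first upstroke sample with dv/dt > 20 mV/ms), the standard
#' electrophysiological convention of measuring spike amplitude from
#' threshold; `baseline = "trough"` instead uses the minimum voltage in the
#' 20 ms preceding the peak. If either flank never crosses the half-height
#' level (pseudo-plateau events) an error of class `frachh_halfwidth` is
#' raised.
#'
#' @param trace a `sim_trace`.
#' @param spikes a `spike_features` from [detectSpikes()]; computed if NULL.
#' @param index which spike (1-based). The second spike is the conventional
#'   choice for spike-shape metrics at minimum spiking current.
#' @param baseline `"threshold"` (default) or `"trough"`.
#' @return Half-width in ms.
#' @export
halfWidth <- function(trace, spikes = NULL, index = 2,
                      baseline = c("threshold", "trough")) {
  baseline <- match.arg(baseline)
  if (is.null(spikes)) spikes <- detectSpikes(trace)
  if (spikes$n_spikes < index)
    stop(sprintf("trace has %d spikes; spike %d requested", spikes$n_spikes, index))
  t <- trace$t_ms
  V <- trace$V_mV
  ipk <- which.min(abs(t - spikes$spike_times[index]))
  base_V <- if (baseline == "trough") {
    min(V[t >= t[ipk] - 20 & t <= t[ipk]])
  } else {
    voltageThreshold(trace, spikes, index)
  }
  level <- base_V + (V[ipk] - base_V) / 2
  # left flank
  il <- ipk
  while (il > 1 && V[il] > level) il <- il - 1L
  if (V[il] > level) stop(halfwidth_condition("left flank never crosses half height"))
  t_left <- interp_crossing(t[il], t[il + 1], V[il], V[il + 1], level)
  # right flank
  ir <- ipk
  while (ir < length(V) && V[ir] > level) ir <- ir + 1L
  if (V[ir] > level) stop(halfwidth_condition("right flank never crosses half height"))
  t_right <- interp_crossing(t[ir - 1], t[ir], V[ir - 1], V[ir], level)
  t_right - t_left
}

interp_crossing <- function(t0, t1, v0, v1, level) {
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

halfwidth_condition <- function(msg) {
  structure(class = c("frachh_halfwidth", "error", "condition"),
            list(message = paste0("half-width undefined: ", msg), call = NULL))
}

#' Current threshold for spiking
#'
#' Scans an ascending grid of step-current amplitudes (500-ms steps by
#' default) and reports the smallest current eliciting at least one spike
#' and the smallest eliciting at least two (repetitive spiking; the
#' reference current for spike-shape metrics). The scan is bracketed
#' coarse-to-fine over the same grid (spiking onset is monotone in the input
#' current), so the result equals a plain ascending scan at a fraction of
#' the cost. The grid step is the resolution of the answer.
#'
#' @param params `hhParams()`.
#' @param fconfig `fractionalConfig()`; classic when the gate is `"none"`.
#' @param I_grid ascending current grid, default `seq(1, 24, by = 0.5)`.
#' @param duration step duration (ms), default 500.
#' @param keep_trace if TRUE, the trace at the >= 2 spike threshold is
#'   returned (used by spike-shape analyses).
#' @return List: `I_one`, `I_two` (NA when nothing on the grid spikes),
#'   `grid_step`, `evaluated` (data frame I, n_spikes), and optionally
#'   `trace`.
#' @export
currentThreshold <- function(params = hhParams(),
                             fconfig = fractionalConfig(),
                             I_grid = seq(1, 24, by = 0.5),
                             duration = 500, keep_trace = FALSE) {
  stopifnot(!is.unsorted(I_grid))
  n_sp <- function(I) {
    tr <- run_step(params, fconfig, I, duration)
    if (is.null(tr)) NA_integer_ else detectSpikes(tr)$n_spikes
  }
  counts <- rep(NA_integer_, length(I_grid))
  eval_at <- function(i) {
    if (is.na(counts[i])) counts[i] <<- n_sp(I_grid[i])
    counts[i]
  }
  # coarse pass over every 4th grid point (always including the last),
  # stopping at the first repetitive-spiking current
  coarse_idx <- unique(c(seq(1L, length(I_grid), by = 4L), length(I_grid)))
  hit2 <- NA_integer_
  for (ci in coarse_idx) {
    n <- eval_at(ci)
    if (!is.na(n) && n >= 2) { hit2 <- ci; break }
  }
  # fill in the fine grid between the last silent coarse point and the hit
  hit_any <- which(!is.na(counts) & counts >= 1)
  upper <- if (!is.na(hit2)) hit2 else if (length(hit_any)) max(hit_any) else NA
  if (!is.na(upper)) {
    silent <- which(!is.na(counts) & counts == 0 &
                      seq_along(counts) < upper)
    lo <- if (length(silent)) max(silent) else 0L
    if (upper - lo > 1L) for (fi in seq(lo + 1L, upper - 1L)) eval_at(fi)
  }
  spiking1 <- which(!is.na(counts) & counts >= 1)
  spiking2 <- which(!is.na(counts) & counts >= 2)
  I_one <- if (length(spiking1)) I_grid[min(spiking1)] else NA_real_
  I_two <- if (length(spiking2)) I_grid[min(spiking2)] else NA_real_
  evaluated <- data.frame(I = I_grid[!is.na(counts)],
                          n_spikes = counts[!is.na(counts)])
  out <- list(I_one = I_one, I_two = I_two,
              grid_step = if (length(I_grid) > 1) min(diff(I_grid)) else NA_real_,
              evaluated = evaluated)
  if (keep_trace && !is.na(I_two))
    out$trace <- run_step(params, fconfig, I_two, duration)
  out
}

run_step <- function(params, fconfig, I, duration) {
  proto <- stepCurrentProtocol(I, onset = 0, duration = duration)
  tryCatch({
    if (fconfig$fractional_gate == "none" || fconfig$eta == 1)
      simulateClassic(params, proto, dt = fconfig$dt)
    else simulateHybrid(params, fconfig, proto)
  }, frachh_divergence = function(e) NULL)
}

#' Voltage threshold of an action potential
#'
#' The voltage at the first sample of the spike's upstroke where the voltage
#' slope (central differences) exceeds `dvdt_crit` (20 mV/ms by default),
#' the standard phase-plot threshold criterion.
#'
#' @param trace a `sim_trace`.
#' @param spikes optional `spike_features`.
#' @param index which spike.
#' @param dvdt_crit slope criterion (mV/ms).
#' @return Threshold voltage (mV).
#' @export
voltageThreshold <- function(trace, spikes = NULL, index = 2, dvdt_crit = 20) {
  if (is.null(spikes)) spikes <- detectSpikes(trace)
  if (spikes$n_spikes < index)
    stop(sprintf("trace has %d spikes; spike %d requested", spikes$n_spikes, index))
  t <- trace$t_ms
  V <- trace$V_mV
  dvdt <- c(NA, (V[-(1:2)] - V[-((length(V) - 1):length(V))]) /
              (t[-(1:2)] - t[-((length(t) - 1):length(t))]), NA)
  ipk <- which.min(abs(t - spikes$spike_times[index]))
  # upstroke: from the pre-spike trough (minimum over the preceding 20 ms)
  # to the peak; the threshold is the first sample whose slope exceeds the
  # criterion
  pre <- which(t >= t[ipk] - 20 & t <= t[ipk])
  itr <- pre[which.min(V[pre])]
  seg <- itr:ipk
  cand <- seg[!is.na(dvdt[seg]) & dvdt[seg] > dvdt_crit]
  if (!length(cand))
    stop(sprintf("dv/dt never exceeds %g mV/ms on the upstroke of spike %d",
                 dvdt_crit, index))
  i <- cand[1]
  # sub-sample refinement: interpolate the exact dv/dt crossing between the
  # last sub-critical sample and the first super-critical one
  if (i > seg[1] && !is.na(dvdt[i - 1]) && dvdt[i - 1] <= dvdt_crit) {
    f <- (dvdt_crit - dvdt[i - 1]) / (dvdt[i] - dvdt[i - 1])
    V[i - 1] + f * (V[i] - V[i - 1])
  } else {
    V[i]
  }
}

#' Phase-plane current decomposition
#'
#' Reconstructs, at every sample, the depolarizing sodium current
#' \eqn{I_{Na} = \bar g_{Na} m^3 h (E_{Na} - V)} and the aggregate
#' \eqn{I_w} = potassium + leak + injected currents, all expressed as
#' contributions to \eqn{C\,dV/dt} (so the balance line is
#' \eqn{I_{Na} + I_w = 0}). The imbalance current is their sum.
#'
#' @param trace a `sim_trace`.
#' @return Data frame `t_ms`, `INa`, `Iw`, `imbalance`.
#' @export
phasePlane <- function(trace) {
  stopifnot(all(c("INa", "IK", "IL", "Iin") %in% names(trace)))
  Iw <- trace$IK + trace$IL + trace$Iin
  data.frame(t_ms = trace$t_ms, INa = trace$INa, Iw = Iw,
             imbalance = trace$INa + Iw)
}

#' Voltage-threshold shift across the fractional-order sweep
#'
#' For each order `eta`, finds the minimum repetitive-spiking current of the
#' fractional model (500-ms steps, 0.5-nA grid), measures the voltage
#' threshold (dv/dt > 20 mV/ms) of the second spike, and compares it with
#' the classic model's threshold. With `anchor = "matched"` (default) the
#' classic reference is measured at the same injected current, isolating the
#' effect of the fractional gate from the current dependence of the
#' threshold itself; with `anchor = "rheobase"` the reference is the classic
#' threshold at the classic minimum spiking current. Orders whose
#' simulations diverge are reported as unstable; matched references below
#' the classic rheobase are NA.
#'
#' @param gate fractional gate, `"n"`, `"m"` or `"h"`.
#' @param etas orders to sweep (default 0.2 to 0.9; 1 is the reference).
#' @param dt integration step (ms).
#' @param anchor `"matched"` or `"rheobase"`.
#' @param params `hhParams()`.
#' @return Data frame with `eta`, `I` (min spiking current), `threshold`
#'   (mV), `reference` (mV), `shift` (mV), `stable` (logical).
#' @export
voltageThresholdShifts <- function(gate, etas = seq(0.2, 0.9, by = 0.1),
                                   dt = 0.01,
                                   anchor = c("matched", "rheobase"),
                                   params = hhParams()) {
  gate <- match.arg(gate, c("n", "m", "h"))
  anchor <- match.arg(anchor)
  classic_fc <- fractionalConfig("none", dt = dt)
  classic_cache <- new.env(parent = emptyenv())
  classic_thr_at <- function(I) {
    key <- format(I, digits = 15)
    if (is.null(classic_cache[[key]])) {
      tr <- simulateClassic(params, stepCurrentProtocol(I, duration = 500),
                            dt = dt)
      classic_cache[[key]] <- tryCatch(voltageThreshold(tr),
                                       error = function(e) NA_real_)
    }
    classic_cache[[key]]
  }
  ref_rheo <- if (anchor == "rheobase") {
    th0 <- currentThreshold(params, classic_fc, keep_trace = TRUE)
    voltageThreshold(th0$trace)
  } else NA_real_
  rows <- lapply(etas, function(eta) {
    fc <- fractionalConfig(gate, eta = eta, dt = dt)
    th <- tryCatch(currentThreshold(params, fc, keep_trace = TRUE),
                   frachh_divergence = function(e) NULL)
    if (is.null(th) || is.na(th$I_two))
      return(data.frame(eta = eta, I = NA_real_, threshold = NA_real_,
                        reference = NA_real_, shift = NA_real_,
                        stable = FALSE))
    v <- tryCatch(voltageThreshold(th$trace), error = function(e) NA_real_)
    ref <- if (anchor == "matched") classic_thr_at(th$I_two) else ref_rheo
    data.frame(eta = eta, I = th$I_two, threshold = v, reference = ref,
               shift = v - ref, stable = TRUE)
  })
  do.call(rbind, rows)
}
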