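# Independent reference implementations used as oracles. These deliberately
# re-derive everything from the model definitions in plain R, without calling
# the package's integrators.

# rate functions, written out directly
oracle_rates <- function(V, V0 = -65) {
  v <- V - V0
  an <- if (abs(10 - v) < 1e-9) 0.1 else 0.01 * (10 - v) / (exp((10 - v) / 10) - 1)
  bn <- 0.125 * exp(-v / 80)
  am <- if (abs(25 - v) < 1e-9) 1 else 0.1 * (25 - v) / (exp((25 - v) / 10) - 1)
  bm <- 4 * exp(-v / 18)
  ah <- 0.07 * exp(-v / 20)
  bh <- 1 / (1 + exp(3 - 0.1 * v))
  list(n = c(a = an, b = bn), m = c(a = am, b = bm), h = c(a = ah, b = bh))
}

# naive O(N) memory-trace evaluation with an explicit double loop
oracle_memory_trace <- function(history, eta) {
  N <- length(history)
  if (N < 2) return(0)
  s <- 0
  for (k in 0:(N - 2)) {
    w <- (N - k)^(1 - eta) - (N - 1 - k)^(1 - eta)
    s <- s + (history[k + 2] - history[k + 1]) * w
  }
  -s
}

# naive L1 clamp integration of a single gate at fixed voltage
oracle_gate_clamp <- function(gate, eta, x0, V, nstep, dt, V0 = -65) {
  r <- oracle_rates(V, V0)[[gate]]
  x <- numeric(nstep + 1)
  x[1] <- x0
  pref <- dt^eta * gamma(2 - eta)
  for (i in seq_len(nstep)) {
    kin <- r[["a"]] * (1 - x[i]) - r[["b"]] * x[i]
    x[i + 1] <- pref * kin + x[i] + oracle_memory_trace(x[1:i], eta)
  }
  x[-1]
}

# naive hybrid stepper: L1 update of the fractional gate from the previous
# voltage, then one RK4 step of (V, classic gates) with the fractional gate
# held at its fresh value
oracle_hybrid <- function(gate, eta, I, total, dt, params = hhParams()) {
  nstep <- round(total / dt)
  V <- params$V0
  g <- as.list(hhSteadyState(params$V0, params$V0))
  hist_x <- g[[gate]]
  classic <- setdiff(c("n", "m", "h"), gate)
  pref <- dt^eta * gamma(2 - eta)
  dV <- function(V, n, m, h) {
    (params$gNa_bar * m^3 * h * (params$ENa - V) +
       params$gK_bar * n^4 * (params$EK - V) +
       params$gm * (params$EL - V) + I) / params$C
  }
  dgate <- function(gt, V, x) {
    r <- oracle_rates(V, params$V0)[[gt]]
    r[["a"]] * (1 - x) - r[["b"]] * x
  }
  out <- data.frame(t_ms = 0, V_mV = V, n = g$n, m = g$m, h = g$h, memtrace = 0)
  for (i in seq_len(nstep)) {
    x_prev <- hist_x[length(hist_x)]
    mem <- oracle_memory_trace(hist_x, eta)
    x_new <- pref * dgate(gate, V, x_prev) + x_prev + mem
    hist_x <- c(hist_x, x_new)
    g[[gate]] <- x_new
    st <- c(V = V, unlist(g[classic]))
    deriv <- function(s) {
      gg <- g
      gg[[classic[1]]] <- s[[2]]
      gg[[classic[2]]] <- s[[3]]
      c(dV(s[[1]], gg$n, gg$m, gg$h),
        dgate(classic[1], s[[1]], s[[2]]),
        dgate(classic[2], s[[1]], s[[3]]))
    }
    k1 <- deriv(st)
    k2 <- deriv(st + dt / 2 * k1)
    k3 <- deriv(st + dt / 2 * k2)
    k4 <- deriv(st + dt * k3)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    V <- st[[1]]
    g[[classic[1]]] <- st[[2]]
    g[[classic[2]]] <- st[[3]]
    out[i + 1, ] <- c(i * dt, V, g$n, g$m, g$h, mem)
  }
  out
}

# synthetic voltage trace assembled from Gaussian bumps on a baseline
synthetic_spike_train <- function(spike_times, total = NULL, dt = 0.05,
                                  peak = 30, base = -65, sigma = 0.5) {
  if (is.null(total)) total <- max(spike_times) + 20
  t <- seq(0, total, by = dt)
  V <- rep(base, length(t))
  for (ts in spike_times) V <- pmax(V, base + (peak - base) * exp(-(t - ts)^2 / (2 * sigma^2)))
  structure(data.frame(t_ms = t, V_mV = V),
            class = c("sim_trace", "data.frame"))
}
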