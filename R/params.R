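#' Membrane parameters of the Hodgkin-Huxley model
#'
#' Constructs the parameter set of the membrane equation
#' \deqn{C \frac{dV}{dt} = -\left(g_m (V - E_L) + \bar g_K n^4 (V - E_K) +
#'   \bar g_{Na} m^3 h (V - E_{Na})\right) + I}
#' Defaults are the standard squid-axon values per 1 cm^2 of membrane.
#' Units are mV, ms, mS/cm^2 and uF/cm^2; injected current amplitudes are
#' current densities (dimensionally uA/cm^2, conventionally printed as "nA"
#' in this model family).
#'
#' @param C membrane capacitance (uF/cm^2), > 0.
#' @param gNa_bar,gK_bar maximal sodium / potassium conductances (mS/cm^2).
#' @param gm passive (leak) conductance (mS/cm^2).
#' @param ENa,EK,EL reversal potentials (mV).
#' @param V0 reference voltage of the rate functions and the default initial
#'   voltage (mV); the resting state of the model.
#' @return An object of class `hh_params`.
#' @examples
#' p <- hhParams()
#' p$gNa_bar
#' @export
hhParams <- function(C = 1, gNa_bar = 120, gK_bar = 36, gm = 0.3,
                     ENa = 50, EK = -77, EL = -54, V0 = -65) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0,
            gNa_bar >= 0, gK_bar >= 0, gm >= 0,
            is.finite(ENa), is.finite(EK), is.finite(EL), is.finite(V0))
  structure(list(C = C, gNa_bar = gNa_bar, gK_bar = gK_bar, gm = gm,
                 ENa = ENa, EK = EK, EL = EL, V0 = V0),
            class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Hodgkin-Huxley membrane parameters (per cm^2):\n")
  cat(sprintf("  C = %g uF, gNa_bar = %g mS, gK_bar = %g mS, gm = %g mS\n",
              x$C, x$gNa_bar, x$gK_bar, x$gm))
  cat(sprintf("  ENa = %g mV, EK = %g mV, EL = %g mV, V0 = %g mV\n",
              x$ENa, x$EK, x$EL, x$V0))
  invisible(x)
}

as_param_vector <- function(params) {
  unlist(params[c("C", "gNa_bar", "gK_bar", "gm", "ENa", "EK", "EL", "V0")])
}

#' Constant current-step stimulation protocol
#'
#' @param amplitude current density of the step ("nA" per cm^2, dimensionally
#'   uA/cm^2).
#' @param onset step onset (ms), >= 0.
#' @param duration step duration (ms), > 0.
#' @param total_time total simulated time (ms), >= onset + duration not
#'   required; the trace simply ends at `total_time`.
#' @return An object of class `step_protocol`.
#' @examples
#' stepCurrentProtocol(18, duration = 1500, total_time = 1500)
#' @export
stepCurrentProtocol <- function(amplitude, onset = 0, duration = 500,
                                total_time = onset + duration) {
  stopifnot(is.finite(amplitude), onset >= 0, duration > 0, total_time > 0)
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 total_time = total_time),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Current step: %g nA from t = %g to %g ms (trace %g ms)\n",
              x$amplitude, x$onset, x$onset + x$duration, x$total_time))
  invisible(x)
}

#' Voltage-clamp protocol for isolated-gate characterization
#'
#' A holding phase at `hold_V` followed by a step to `target_V`. Gate
#' characterization starts the gate at its steady state at `hold_V`, so the
#' holding phase carries no memory into the target phase.
#'
#' @param hold_V holding voltage (mV). Default 0 mV (absolute).
#' @param hold_duration duration of the holding phase (ms).
#' @param target_V command voltage of the measurement phase (mV).
#' @param target_duration duration of the measurement phase (ms). The
#'   default 110 ms accommodates the h gate's read time; n and m use 90 and
#'   40 ms read times respectively.
#' @return An object of class `clamp_protocol`.
#' @export
voltageClampProtocol <- function(hold_V = 0, hold_duration = 25,
                                 target_V, target_duration = 110) {
  stopifnot(hold_duration > 0, target_duration > 0, is.finite(target_V))
  structure(list(hold_V = hold_V, hold_duration = hold_duration,
                 target_V = target_V, target_duration = target_duration),
            class = "clamp_protocol")
}

#' Fractional-dynamics configuration
#'
#' Selects which gate evolves under the Caputo derivative of order `eta`,
#' the integration step, and the memory-truncation policy of the L1 scheme.
#'
#' @param fractional_gate one of `"n"`, `"m"`, `"h"`, or `"none"`.
#' @param eta fractional order, in (0, 1]. `eta = 1` (or gate `"none"`)
#'   reproduces the classic model.
#' @param dt integration step (ms).
#' @param truncation `"full"` (authoritative default) or a positive integer
#'   K: only the most recent K increments enter the memory sum. Windowed runs
#'   carry a worst-case truncation-error estimate in the result.
#' @param divergence_bound the integration aborts with a divergence error
#'   when the fractional gate exceeds this magnitude (the documented m-gate
#'   instability at low `eta` is surfaced, never clamped).
#' @return An object of class `fractional_config`.
#' @examples
#' fractionalConfig("n", eta = 0.8)
#' @export
fractionalConfig <- function(fractional_gate = c("none", "n", "m", "h"),
                             eta = 1, dt = 0.001, truncation = "full",
                             divergence_bound = 10) {
  fractional_gate <- match.arg(fractional_gate)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) ||
      eta <= 0 || eta > 1)
    stop("eta must be in (0, 1], got ", format(eta))
  stopifnot(dt > 0, divergence_bound > 0)
  if (!identical(truncation, "full")) {
    if (!is.numeric(truncation) || length(truncation) != 1L ||
        truncation < 1 || truncation != round(truncation))
      stop("truncation must be \"full\" or a positive integer window K")
    truncation <- as.integer(truncation)
  }
  structure(list(fractional_gate = fractional_gate, eta = eta, dt = dt,
                 truncation = truncation, divergence_bound = divergence_bound),
            class = "fractional_config")
}

#' @export
print.fractional_config <- function(x, ...) {
  if (x$fractional_gate == "none") {
    cat("Fractional config: no fractional gate (classic dynamics)\n")
  } else {
    cat(sprintf("Fractional config: gate %s, eta = %g, dt = %g ms, memory %s\n",
                x$fractional_gate, x$eta, x$dt,
                if (identical(x$truncation, "full")) "full"
                else paste0("window(", x$truncation, ")")))
  }
  invisible(x)
}

gate_index <- function(gate) {
  match(match.arg(gate, c("n", "m", "h")), c("n", "m", "h")) - 1L
}
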