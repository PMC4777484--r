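#' L1 discretization weights of the Caputo derivative
#'
#' Weights of the memory sum at step N on a uniform grid,
#' \eqn{w_k = (N-k)^{1-\eta} - (N-1-k)^{1-\eta}}, for k = 0 ... N-2. The
#' weight applied to the most recent stored increment (k = N-2) is the
#' largest for `eta < 1`; all weights are exactly zero for `eta = 1`.
#'
#' @param N step count (>= 2): the update computes x(t_N) from x(t_0..t_{N-1}).
#' @param eta fractional order in (0, 1].
#' @return Numeric vector of length N-1 (indices k = 0 ... N-2).
#' @examples
#' l1Weights(3, 0.5)   # sqrt(3)-sqrt(2), sqrt(2)-1
#' @export
l1Weights <- function(N, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta > 1)
    stop("eta must be in (0, 1]")
  stopifnot(N >= 2, N == round(N))
  k <- 0:(N - 2)
  (N - k)^(1 - eta) - (N - 1 - k)^(1 - eta)
}

#' Memory trace of the L1 update
#'
#' The history-dependent term of the L1 update of the Caputo derivative:
#' the negative weighted sum of all past increments of the gate,
#' \eqn{-\sum_{k=0}^{N-2} [x(t_{k+1}) - x(t_k)] w_k}. It is added as the
#' final term of the gate update, vanishes identically for `eta = 1` or for
#' a constant history, and acts as a negative feedback between the voltage
#' trajectory and the power-law gate.
#'
#' @param history numeric vector x(t_0) ... x(t_{N-1}) of past gate values on
#'   the uniform grid (length >= 1; lengths < 2 give an empty sum, i.e. 0).
#' @param eta fractional order in (0, 1].
#' @return The (signed) memory-trace value.
#' @export
memoryTrace <- function(history, eta) {
  N <- length(history)
  if (N < 2) return(0)
  dx <- diff(history)                      # increments k = 0 ... N-2
  -sum(dx * l1Weights(N, eta))
}

#' One L1 step of a fractional gating variable
#'
#' Advances the fractional gate one step: the kinetic term is evaluated
#' explicitly from the previous voltage and gate value, scaled by
#' \eqn{dt^\eta \Gamma(2-\eta)}, and the memory trace of the whole history is
#' added. For `eta = 1` this reduces exactly to one forward-Euler step of the
#' classic gate equation.
#'
#' @param history numeric vector of past gate values x(t_0) ... x(t_{N-1})
#'   (nonempty; the last entry is the current value).
#' @param V_prev membrane voltage at t_{N-1} (mV).
#' @param gate `"n"`, `"m"` or `"h"`.
#' @param eta fractional order in (0, 1].
#' @param dt step (ms).
#' @param params `hhParams()` (only `V0` is used by the rates).
#' @param divergence_bound abort threshold on the magnitude of the result.
#' @return The next gate value x(t_N).
#' @export
fractionalGateStep <- function(history, V_prev, gate, eta, dt,
                               params = hhParams(), divergence_bound = 10) {
  stopifnot(length(history) >= 1)
  x_prev <- history[length(history)]
  a <- hhRate(gate, "alpha", V_prev, params$V0)
  b <- hhRate(gate, "beta", V_prev, params$V0)
  x_new <- dt^eta * gamma(2 - eta) * (a * (1 - x_prev) - b * x_prev) +
    x_prev + memoryTrace(history, eta)
  if (!is.finite(x_new) || abs(x_new) > divergence_bound)
    stop(sprintf("fractional gate divergence (gate=%s, eta=%g, dt=%g): |x| > %g",
                 gate, eta, dt, divergence_bound))
  x_new
}
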