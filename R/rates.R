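#' Hodgkin-Huxley rate functions
#'
#' Forward (`alpha`) and backward (`beta`) transition rates of the gating
#' variables, in 1/ms, with voltages relative to the reference `V0`
#' (so at `V = V0` the rates take their classic resting-axon values). The
#' removable 0/0 singularities of `alpha` for the n gate (at `V - V0 = 10`)
#' and the m gate (at `V - V0 = 25`) return their analytic limits.
#'
#' @param gate `"n"`, `"m"` or `"h"`.
#' @param kind `"alpha"` or `"beta"`.
#' @param V membrane voltage (mV), vectorized.
#' @param V0 reference voltage (mV).
#' @return Numeric vector of rates (1/ms).
#' @examples
#' hhRate("n", "alpha", -65)      # 0.1 / (e - 1)
#' hhRate("n", "alpha", -55)      # the removable-singularity limit, 0.1
#' @export
hhRate <- function(gate = c("n", "m", "h"), kind = c("alpha", "beta"),
                   V, V0 = -65) {
  gate <- match.arg(gate)
  kind <- match.arg(kind)
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("rate(): V must be finite numeric")
  .rateCpp(rep.int(gate_index(gate), length(V)),
           rep.int(match(kind, c("alpha", "beta")) - 1L, length(V)),
           as.numeric(V), V0)
}

#' Steady states and time constants of the gating variables
#'
#' `hhSteadyState` returns the voltage-dependent equilibrium values
#' \eqn{x_\infty(V) = \alpha_x(V) / (\alpha_x(V) + \beta_x(V))} and
#' `hhTau` the classic time constants \eqn{\tau_x(V) = 1/(\alpha_x + \beta_x)}
#' (ms) for x = n, m, h.
#'
#' @param V membrane voltage (mV), scalar.
#' @param V0 reference voltage (mV).
#' @return `hhSteadyState`: named numeric vector `c(n=, m=, h=)`;
#'   `hhTau`: same shape, in ms.
#' @examples
#' round(hhSteadyState(-65), 4)   # n 0.3177, m 0.0529, h 0.5960
#' @export
hhSteadyState <- function(V, V0 = -65) {
  vapply(c(n = "n", m = "m", h = "h"), function(g) {
    a <- hhRate(g, "alpha", V, V0)
    b <- hhRate(g, "beta", V, V0)
    a / (a + b)
  }, numeric(length(V)))
}

#' @rdname hhSteadyState
#' @export
hhTau <- function(V, V0 = -65) {
  vapply(c(n = "n", m = "m", h = "h"), function(g) {
    1 / (hhRate(g, "alpha", V, V0) + hhRate(g, "beta", V, V0))
  }, numeric(length(V)))
}
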