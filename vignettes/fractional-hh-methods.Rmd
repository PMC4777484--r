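---
title: "Power-law gating in a Hodgkin-Huxley model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-law gating in a Hodgkin-Huxley model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(frachh)
```

## The model and its assumptions

`frachh` studies what happens to action-potential generation when a single
membrane conductance acquires power-law, history-dependent kinetics. The
membrane is the standard squid-axon model,

$$C \frac{dV}{dt} = -\left(g_m (V - E_L) + \bar g_K\, n^4 (V - E_K) +
\bar g_{Na}\, m^3 h (V - E_{Na})\right) + I,$$

with the usual voltage-dependent forward/backward rates $\alpha_x(V)$,
$\beta_x(V)$ for $x \in \{n, m, h\}$, referenced to the resting voltage
$V_0 = -65$ mV. One selected gate obeys the Caputo fractional-order
equation

$$\frac{d^\eta x}{dt^\eta} = \alpha_x(V)(1 - x) - \beta_x(V)\,x,
\qquad 0 < \eta \le 1 .$$

The Caputo derivative weights all past values of $\dot x$ by
$(t - u)^{-\eta}/\Gamma(1-\eta)$, so the gate's current rate of change
depends on its whole trajectory; $\eta = 1$ recovers the memoryless classic
gate. Biophysically this stands in for channels whose closed/inactive
states are numerous or interacting, which makes residence times power-law
distributed rather than exponential. Only one gate is fractional at a time;
multi-term (distributed-order) gating and fractional voltage dynamics are
out of scope.

A note on units: all printed current amplitudes ("nA") act on 1 cm$^2$ of
membrane with $C = 1\,\mu$F, so they behave dimensionally as $\mu$A/cm$^2$.
The package keeps the conventional "nA" labels.

One printed rate constant required a choice: the published form of
$\alpha_n$ mixes $(V + V_0)$ and $(V - V_0)$ in its exponential. We use
$(V - V_0)$ throughout, which is the classic form and is the only choice
that reproduces the published resting gate values
$(n, m, h)_\infty(-65) = (0.3177, 0.0529, 0.5960)$.

## Numerical scheme

**L1 discretization.** On a uniform grid $t_k = k\,dt$ the Caputo
derivative is discretized with the L1 scheme, giving the explicit update

$$x(t_N) \approx dt^\eta\,\Gamma(2-\eta)\,
\left[\alpha_x(1 - x) - \beta_x x\right]_{t_{N-1}} + x(t_{N-1})
- \sum_{k=0}^{N-2}\left[x(t_{k+1}) - x(t_k)\right]
\left[(N-k)^{1-\eta} - (N-1-k)^{1-\eta}\right].$$

The trailing sum (sign included) is the **memory trace**. The weights
depend only on the lag $N-1-k$, so they are precomputed once and each step
is a single dot product; a full run of $N$ steps costs $O(N^2)$
multiply-adds (the compiled core sustains roughly $10^9$ per second).

**Coupling.** Per time step the fractional gate is updated first, with
rates evaluated at the previous voltage (the scheme is explicit); then $V$
and the two classic gates take one RK4 step during which the fractional
gate is held constant at its freshly updated value. Holding the fresh value
keeps the whole step explicit and consistent as $dt \to 0$; the split
itself follows the standard practice of mixing an L1 gate update with an
RK4 membrane update.

**The $\eta = 1$ limit.** At $\eta = 1$ every L1 weight vanishes and the
update degenerates to forward Euler. Because the Caputo derivative *is* the
ordinary derivative there, `simulateHybrid()` delegates $\eta = 1$ (and
`fractional_gate = "none"`) to the all-RK4 classic integrator. This makes
the classic limit exact rather than Euler-perturbed: a forward-Euler gate
shifts spike times by $O(dt)$ per spike, and on a 500-ms tonic train even
$dt = 0.001$ ms accumulates several mV of sup-norm difference purely from
spike-edge phase, which would misrepresent an exactly classical model.

**Memory truncation.** Full memory is the default and authoritative mode.
`truncation = K` keeps only the most recent $K$ increments for long runs;
such runs carry a `truncation_error_bound` attribute — the sum of the
neglected tail weights times the largest observed increment, a worst-case
estimate. A window spanning the whole run reproduces full mode bit-exactly.

**Divergence handling.** The explicit L1 update of the fast m gate is
numerically unstable at low orders (with $dt = 0.01$ ms inside the full
model, $\eta \le 0.3$ diverges; the isolated clamp at $dt = 0.001$ ms
diverges at $\eta = 0.1$). The integrator raises an error carrying the
(gate, $\eta$, dt) triple as soon as the gate magnitude exceeds
`divergence_bound` (default 10), rather than clamping: instability is
surfaced, never masked. Phase-diagram sweeps record such cells with the
first-class label `"UNST"`.

**Default step.** `dt = 0.001` ms for classic and clamp work. Full-model
fractional runs in the tests and the acceptance script use `dt = 0.01` ms:
the firing rates, spike shapes and thresholds reported there were checked
to be converged against `dt = 0.005`-`0.002`, and full-memory cost grows
quadratically in $1/dt$.

## Mittag-Leffler evaluation

The clamped fractional gate has the closed form
$x(t) = x_\infty + (x_0 - x_\infty)E_\eta(-t^\eta/\tau_x)$ with
$E_\eta(z) = \sum_k z^k/\Gamma(\eta k + 1)$. Two routes are combined:

* the defining series, used whenever a peak-term bound certifies that
  alternating cancellation costs at most ~4 digits (for small $\eta$ this
  restricts the series to small $|z|$; at $\eta = 0.2$, $|z| = 2$ the naive
  series already loses ~13 digits);
* otherwise the spectral (complete-monotonicity) representation
  $$E_\eta(-x) = \frac{\sin \eta\pi}{\eta\pi}\int_0^\infty
  \frac{e^{-(px)^{1/\eta}}}{p^2 + 2p\cos \eta\pi + 1}\,dp,$$
  integrated adaptively with a split at the spectral peak.

The routes agree to ~$10^{-12}$ where both apply, match $E_1 = \exp$ and
$E_{1/2}(-x) = e^{x^2}\operatorname{erfc} x$ to ~$10^{-10}$, and reproduce
the algebraic tail $1/(x\Gamma(1-\eta))$. As $\eta \to 1$ the spectral
density sharpens toward a pole pair at the splitting point of the adaptive
quadrature, which keeps the evaluation accurate to ~$10^{-12}$ up to at
least $\eta = 0.999$ (verified against arbitrary-precision series sums);
$\eta = 1$ itself is `exp`. Dense time grids are served by a cached
cubic spline on a log-spaced knot grid (spacing 0.01 in $\log x$, absolute
error ~$10^{-10}$); pointwise calls always use the exact routes.

## Voltage-clamp characterization

Clamp protocols hold the gate at its steady state at 0 mV (taken literally,
not "rest") for 25 ms, then step to a target voltage. Because a constant
history contributes no memory, the target-phase response is the pure
fractional relaxation from $x_\infty(0)$. Long-term responses
$x_\infty^\eta$ are read at 90/40/110 ms for n/m/h (the times at which the
traces change by less than 0.01% per millisecond; the h-gate read time
forces the default 110-ms target window). Sweeps default to target voltages
$-100$ to $120$ mV in 10-mV steps and $\eta$ from 0.2 to 1 in 0.1 steps.

Dual-exponential fits
$x(t) = x_{\inf} - A_1 e^{-t/\tau_{fast}} - A_2 e^{-t/\tau_{slow}}$ use
bounded Levenberg-Marquardt with initial time constants $\{0.3, 3\}\times$
the classic $\tau_x$ at the target voltage and amplitudes from the trace
endpoints; the m gate is fitted with a single component. At $\eta = 1$ the
two constants degenerate to the classic $\tau_x$ (within 2% in the tests);
as $\eta$ decreases the fast constant shortens and the slow one lengthens —
the fingerprint of a process with no single time scale.

The numeric-vs-analytic mean squared error averages per-trace MSE between
the L1 solution and the Mittag-Leffler solution on the identical grid over
the gate's analysis window, excluding (and counting) diverged traces. Our
pipeline yields ~$10^{-10}$ at $dt = 0.001$ ms — the published average of
~$10^{-6}$ for the same comparison evidently includes protocol details
(storage decimation, window placement) that are not recoverable from the
text; we report our computed value as-is. The acceptance script uses a
reduced grid ($V \in \{-100, -60, ..., 100\}$, $\eta \in \{0.2, 0.4, ...,
1.0\}$, 30 traces) chosen up front to keep the $O(N^2)$ clamp runs at
$dt = 0.001$ within minutes; MSE is insensitive to this thinning.

## Spike metrics

* **Detection:** upward 0-mV crossing followed by a local maximum, 2-ms
  minimum separation. Sub-threshold oscillations in this model stay below
  $-20$ mV and are never counted. Firing rate = count / stimulation window.
* **Rate windows:** the published sustained-activity rates for the
  fractional n gate at I = 18 correspond to stimulation "between 1,500 and
  3,000 ms"; with lengthening inter-spike intervals the window matters. Our
  3000-ms rates (43.0/14.0/28.7 Hz at $\eta$ = 0.8/0.6/0.4) match the
  printed 43/13/28 Hz; the 1500-ms rates are systematically higher
  (45/19/37 Hz). The package reports rates over the full stimulus window
  and the acceptance protocol uses 3000 ms.
* **Half-width:** measured at the level halfway between the spike peak and
  a baseline, linearly interpolated. The default baseline is the spike's
  voltage threshold (below), the standard amplitude-from-threshold
  convention; it reproduces the published classic value 1.18 ms at minimum
  spiking current (we get 1.135 ms). A pre-spike-trough baseline is
  available but gives 1.51 ms for the same spike, so it cannot be the
  published convention. For the $\eta = 0.2$ n gate no baseline choice we
  tried reaches the published 1.86 ms (the converged value is ~2.24 ms
  under the default); we report what the model produces.
* **Voltage threshold:** the voltage where $dV/dt$ (central differences)
  first exceeds 20 mV/ms on the upstroke from the pre-spike trough, with
  the crossing interpolated between samples (sub-sample refinement removes
  a ~0.4-mV quantization at $dt = 0.01$ ms).
* **Threshold shifts across $\eta$** (`voltageThresholdShifts()`): each
  order is simulated at its minimum repetitive-spiking current (1-24 nA,
  0.5-nA grid — the grid step is the quoted uncertainty) and the second
  spike is measured, per the published convention for spike
  characterization. The classic reference is taken at the *matched*
  current: the classic threshold itself drifts ~0.7 mV between its rheobase
  and higher currents, and anchoring at matched current isolates the
  fractional effect (and reproduces the published n-gate maximum of
  +2.14 mV almost exactly). A rheobase anchor remains available.
* **Phase plane:** currents are expressed as contributions to $C\,dV/dt$
  (depolarizing $I_{Na} > 0$), $I_w = I_K + I_L + I_{in}$, so the balance
  line is $I_{Na} + I_w = 0$ and the imbalance current is their sum.

## Pattern classification

The six labels follow the standard taxonomy: resting state (RS), phasic
spiking (PS), tonic spiking (TS), mixed-mode oscillations (MMO),
square-wave bursting (SWB), pseudo-plateau bursting (PPB). The published
phase diagrams were classified manually; this package substitutes an
automated, documented operationalization whose constants were fixed against
the five published example configurations ((n, 0.7, 23) MMO; (n, 0.4, 8)
PS; (h, 0.4, 10) SWB; (h, 0.2, 20) and (h, 0.2, 9) PPB) and are exposed as
arguments. In priority order:

1. **PPB** — any contiguous excursion above $-20$ mV lasting $\ge 20$ ms
   (a plateau; ordinary spikes spend ~2 ms there). A subtype field reports
   "pituitary" when the plateau carries supra-threshold oscillations,
   "cardiac" otherwise.
2. **RS** — at most one spike.
3. **PS** — all spikes in the first 500 ms and none after 1000 ms.
4. **SWB** — at least two spike groups of $\ge 2$ spikes (intra-group ISI
   < 25 ms) separated by at least one oscillation-filled *silent phase*, a
   gap exceeding both 3x the median ISI and 50 ms.
5. **MMO** — at least 3 sub-threshold oscillations falling between
   consecutive spikes, without such a silent phase.
6. **TS** — everything else.

Sub-threshold oscillations are local maxima below $-20$ mV with topographic
prominence $\ge 1$ mV, $\ge 2$ ms apart, outside $\pm 3$ ms spike masks.
The silent-phase definition (rather than a fixed 75-ms gap) is what
separates the MMO archetype (spike pairs with single oscillations in 30-ms
gaps) from SWB (20-ms intra-burst ISIs against 50-250-ms
oscillation-filled silences); a fixed gap threshold misclassifies one or
the other. Exact reproduction of the manually drawn phase-diagram
boundaries is a non-goal; the five fixtures above are the regression
anchors, and sweeps label divergent cells `"UNST"`.

## Analysis scales

Everything is deterministic — there is no randomness anywhere in the model
or the tools, so runs are bit-reproducible from their configuration. The
test suite and acceptance script choose problem sizes that keep the
quadratic-cost full-memory runs to minutes: classic baselines at
$dt = 0.001$ ms; full-model fractional runs at $dt = 0.01$ ms (checked
converged for every reported quantity); clamp/MSE work at $dt = 0.001$ ms
on the reduced grid stated above; phase-diagram spot checks at
$dt = 0.02$ ms on small grids.

## Known limitations

* Only one gate can be fractional; distributed-order and multi-gate
  variants are not implemented.
* The explicit L1 update limits how small $\eta$ can be for the fast m
  gate; instability is surfaced as an error, not worked around.
* The classifier is an operationalization of a manual taxonomy; near phase
  boundaries its labels are sharp (deterministic) but not claimed to match
  the published hand-drawn boundaries.
* The voltage-clamp protocol holds at an absolute 0 mV; configurations that
  read "hold" as resting potential can set `hold_V = -65`.
* Quantities defined on figure-read values (exact phase-boundary positions,
  the memory-trace "95% decay" remark, whose decay functional is undefined)
  are not asserted anywhere.
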