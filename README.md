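# frachh — fractional-order Hodgkin–Huxley simulation

`frachh` simulates a Hodgkin–Huxley neuron in which one gating variable
(n, m, or h) obeys **Caputo fractional-order kinetics**: instead of the
memoryless first-order relaxation of the classic model, the gate's rate of
change is weighted over its entire past by a power-law kernel. This gives a
single ion conductance slow, history-dependent ("non-Markovian") adaptation
of the kind seen in single-channel recordings and in the recovery from
inactivation of real sodium and calcium channels, and it is enough to turn
the classic tonic-spiking model into a generator of phasic spiking,
mixed-mode oscillations, square-wave bursting and pseudo-plateau
(pituitary- and cardiac-like) action potentials — with all biophysical
parameters fixed, moving only the input current `I` and the fractional
order `eta`.

The package is aimed at computational neuroscientists studying power-law
(fractional) dynamics in conductance-based models, and at experimentalists
who want reference curves for deciding whether a measured conductance obeys
power-law kinetics.

## The model

Membrane equation (units: mV, ms, mS/cm², µF/cm²; current densities are
written in the model family's conventional "nA", dimensionally µA/cm²):

    C dV/dt = −( g_m (V − E_L) + ḡ_K n⁴ (V − E_K) + ḡ_Na m³h (V − E_Na) ) + I

Each gate x ∈ {n, m, h} classically follows
`dx/dt = α_x(V)(1 − x) − β_x(V) x`. The fractional model replaces the first
derivative of **one** selected gate by the Caputo derivative of order
`0 < η ≤ 1`:

    d^η x / dt^η = α_x(V)(1 − x) − β_x(V) x

Numerically the Caputo derivative is discretized with the **L1 scheme** on a
uniform grid, which turns the update into the classic explicit step plus a
**memory trace** — a weighted sum of all past increments of the gate with
weights `(N−k)^(1−η) − (N−1−k)^(1−η)`. The memory trace is identically zero
for η = 1 and acts as a negative feedback between the voltage trajectory
and the power-law gate. The voltage and the two classic gates are advanced
by 4th-order Runge–Kutta around the L1 gate update.

At a clamped voltage the fractional gate equation is linear and has the
closed-form solution

    x(t) = x∞(V) + [x(0) − x∞(V)] · E_η( −t^η / τ_x(V) )

with the Mittag-Leffler function `E_η`, which the package evaluates to high
accuracy (series plus spectral-integral quadrature) and uses as the exact
reference for the numerical scheme.

## Worked example

```r
library(frachh)

# classic baseline: constant 18 nA for 1500 ms
tr <- simulateClassic(protocol = stepCurrentProtocol(18, duration = 1500),
                      dt = 0.001)
detectSpikes(tr)
#> 126 spikes in [0, 1500] ms: firing rate 84.00 Hz

# the same stimulus with a power-law n gate, eta = 0.6
fc  <- fractionalConfig("n", eta = 0.6, dt = 0.01)
trf <- simulateHybrid(fconfig = fc,
                      protocol = stepCurrentProtocol(18, duration = 3000))
detectSpikes(trf)
#> 42 spikes in [0, 3000] ms: firing rate 14.00 Hz

classifyPattern(trf, stim_window = c(0, 3000))
#> Spiking pattern: MMO (42 spikes, 154 sub-threshold oscillations)
```

The classic model fires tonically at 84 Hz. Giving the potassium-activation
gate power-law memory (η = 0.6) cuts the average rate to 14 Hz and inserts
sub-threshold oscillations between spikes — mixed-mode oscillations. Lower
orders and other gates produce the other patterns; `sweepPhaseDiagram()`
maps them over an (I, η) grid, and `phasePlane()` exports the sodium vs
potassium+leak+input current decomposition whose "imbalance current"
`I_Na + I_w` locates the sub-threshold attractor.

A command-line interface with subcommands `simulate`, `clamp`, `spikes`,
`sweep` and `mlf` is installed as `exec/frachh` (see `?frachhCli`).

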