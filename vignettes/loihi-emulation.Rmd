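---
title: "Fixed-point emulation of the Loihi computational unit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-point emulation of the Loihi computational unit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loihisim)
```

## The model

Loihi's computational unit is a current-based leaky integrate-and-fire
neuron whose continuous dynamics

$$\frac{dv}{dt} = -\frac{v}{\tau_v} + I(t), \qquad
  \frac{dI}{dt} = -\frac{I}{\tau_I}$$

are discretized with forward Euler at unit step size and evaluated in
integer arithmetic.  Time constants are expressed through integer decay
constants $\delta = 2^{12}/\tau \in [0, 4096]$: $\delta = 4096$ wipes the
state in one step, $\delta = 0$ is a perfect integrator.  The per-step
updates implemented by `update_synaptic_input()` and `update_voltage()`
are

$$I[t] = \mathrm{raz}\!\left(I[t-1]\,\tfrac{4096-\delta^I}{4096}\right)
  + \sum_j J_{ij}\, s_j[t], \qquad
  v[t] = \mathrm{raz}\!\left(v[t-1]\,\tfrac{4096-\delta^v}{4096}\right)
  + I[t] + I^{\mathrm{bias}}$$

with $\mathrm{raz}(x) = \mathrm{sign}(x)\lceil|x|\rceil$ (*round away from
zero*).  A unit spikes when $v$ **strictly** exceeds the threshold; the
voltage then resets to zero and is clamped there for the refractory
period, while the synaptic input keeps decaying and accumulating.  The
bias enters the voltage update, not the synaptic input.

Because $4096 = 2^{12}$ and all states are integers, the decay products
are exact binary rationals, so the emulator's double-precision arithmetic
computes them without rounding error before `raz` is applied; all state
stays exactly integral for as long as it fits in a double (up to
$2^{53}$, far beyond any value these dynamics produce at sane parameters
— no saturation bounds are emulated because the hardware register widths
are not part of the model here).

### A consequence of round-away-from-zero worth knowing

`raz` never shrinks a magnitude below the point where
$\lceil m(4096-\delta)/4096\rceil = m$.  A decaying state therefore does
**not** relax to zero but settles at a small residual fixed point of
magnitude at most $4096/\delta$ (e.g. 15 for $\delta = 256$); only
$\delta = 4096$ reaches zero from every start.  This is the behaviour the
update equations prescribe — it falls out of implementing the leak as
"subtract the truncated decay amount" — and the property tests assert the
fixed point rather than absorption at zero.

## The weight codec

A synaptic weight is a mantissa $\tilde w$ plus exponent
$\Theta \in [-8, 7]$.  Sign modes fix the mantissa range: excitatory
$[0, 255]$, inhibitory $[-255, 0]$, mixed $[-256, 254]$ (one bit goes to
the sign).  With $n_{wb}$ weight bits the precision exponent is
$n_s = 8 - (n_{wb} - \sigma_{\mathrm{mixed}})$ and representable mantissas
are multiples of $2^{n_s}$.  `encode_weight()` performs initialization:

1. truncate the mantissa to the $2^{n_s}$ grid **toward zero** —
   the hardware description says initialization rounds "to the next
   possible value toward zero", whereas a literal two's-complement
   arithmetic shift would round negative values toward $-\infty$; we
   follow the prose and isolate the choice in
   `truncate_to_precision()` so the alternative is a one-line change;
2. scale by $2^{6+\Theta}$; for $\Theta < -6$ this is implemented as
   toward-zero integer division, consistent with the codec's convention;
3. clip to the 21-bit limit.  The clamp value is not printed anywhere, so
   we clamp the scaled value to $\pm(2^{21}-1)$ *before* the final 6-bit
   zeroing, giving $\pm(2^{21}-2^6)$ after it; under this choice the
   property "clipping fires in exactly one representable case
   ($\tilde w = -256$, $\Theta = 7$, mixed)" holds, which is the only
   stated constraint;
4. zero the six low bits.

Every effective weight $J$ is a multiple of 64.
`enumerate_weight_table()` materializes the full table (4096 rows at
$n_{wb} = 8$ excitatory) for inspection or CSV export.

## Traces, stochastic rounding and learning

Synaptic traces are bounded integer low-pass filters in $[0, 127]$:

$$x[t] = \mathrm{SR}\big(\alpha\, x[t-1]\big) + \hat x\, s[t], \qquad
  \alpha = 1 - 1/\tau,$$

where $\mathrm{SR}$ is unbiased stochastic rounding to the integers.  The
order inside `update_trace()` is decay → stochastic round → add impulse →
clamp: only the decay product can be fractional (impulses are integers),
and the impulse of the current step's spike is never subjected to
rounding.  The first-order $\alpha = 1 - 1/\tau$ approximation of the
exponential is used as-is; refinements with an extra shape parameter are
out of scope.  Whether hardware saturates an over-ceiling trace by
clamping or wrapping is not documented; we clamp, which is the only choice
that keeps the trace a monotone function of its drive.

Learning rules are restricted expressions over the traces
($x_1, x_2, y_1, y_2, y_3$), the dependency factors $x_0, y_0$, integer
constants and power-of-two literals, composed only by `+`, `-`, `*`
(`parse_learning_rule()` rejects anything else, naming the token).  A rule
is evaluated every $2^k$ steps (`epoch_exponent`, default $k = 0$, i.e.
every step — the epoch mechanism is documented without a default, and
$k = 0$ makes the dependency factors reduce to plain per-step spike
flags).  $x_0$ ($y_0$) is 1 iff the pre- (post-)synaptic neuron spiked at
least once since the previous evaluation, and both reset after each
evaluation; accumulation semantics across an epoch are not specified
anywhere, and this choice is the one that degenerates correctly at
$k = 0$.

`apply_learning()` follows the order evaluate $dw$ → add to mantissa →
stochastic round at the weight precision $2^{n_s}$ → clip to the
sign-mode range → re-encode $J$ through the codec.  A clipped boundary
value that is off the precision grid (possible only at a range edge that
is not a multiple of $2^{n_s}$, e.g. 255 at $n_s = 2$) is truncated back
onto the grid toward zero.

## The scheduler

`step_network()` executes, per step $t$:

1. spike generators emit (Poisson draws in configuration order);
2. synaptic inputs update with the weighted spikes delivered this step;
3. voltages update (refractory units clamped);
4. threshold, reset, refractory bookkeeping;
5. traces update with this step's spikes;
6. on learning epochs, plastic groups apply their rule.

**Delivery timing.**  Generator spikes are delivered in the *same* step
they are emitted (so a spike into a quiescent synapse yields $I = J$ at
that step, matching the $s[0] = 1$ initial-condition convention), while
neuron-to-neuron spikes arrive in the *next* step — recurrence requires a
causal delay, otherwise the update order within a step would be
ill-defined.  The hardware's exact intra-step schedule is not public in
full; this choice reproduces every update equation above and is isolated
in `step_network()`.

**Reproducibility.**  One `rng_stream` (a private Mersenne-Twister state)
drives everything, with a fixed draw order: per step, generators in
configuration order (one variate per generator unit), then traces per
plastic group ($x_1, x_2$ over source units, $y_1, y_2, y_3$ over target
units; all five are drawn whether or not their impulse is zero, keeping
draw counts independent of parameters), then plastic-mantissa rounding in
synapse-pair order.  Identical `(config, steps, seed)` give bit-identical
recordings, including the CSV outputs.

## Fixtures: what they emulate and what they do not

`make_fixture()` regenerates three reference experiments.

**single-neuron** — one unit receiving 20 excitatory and 10 inhibitory
explicit generator spikes over the first 100 steps (timed from the
fixture seed; the reference experiment states "randomly timed" without
printing times).  Unit parameters $\delta^I = 512$ ($\tau_I = 8$),
$\delta^v = 256$ ($\tau_v = 16$), $v_{th} = 12000$, refractory 2, weights
$\pm 64$ at $\Theta = 0$ ($J = \pm 4096$): a few excitatory spikes within
a membrane time constant drive the unit over threshold, so both
sub-threshold integration and the spike/reset path are exercised.

**chaotic-net** — 100 inhibitory plus 400 excitatory units, driven by 40
Poisson generators connected with probability 0.05, the documented scale
of the recurrent reference network.  Values the reference does not print
were chosen once for a sparse, inhibition-dominated balanced regime and
then left alone: recurrent connection probability 0.1; log-normal
excitatory mantissas (meanlog 3.0, sdlog 0.5 → mean $J \approx 1.4$k) and
stronger inhibitory ones (meanlog 4.8 → mean $J \approx -9$k); generator
rate 0.1 per step with mantissa 64; $v_{th} = 30000$, refractory 2.  This
yields sustained irregular firing at roughly 0.08 spikes/unit/step, far
from the refractory-limited ceiling.

**stdp** — the single-plastic-synapse learning experiment: an `input`
generator with a deliberately negligible plastic weight
($\tilde w = 128$, $\Theta = -6$, so $J = 128$), a `noise` generator with
a strong static weight ($\tilde w = 254$, $\Theta = 0$, $J = 16256$) that
reliably triggers post-synaptic spikes, and the asymmetric rule
$dw = 2^{-2} x_1 y_0 - 2^{-2} x_0 y_1$ with impulses 120 and $\tau = 8$
on $x_1, y_1$.  Both generators fire Poisson at 0.05 per step (rates are
not printed in the reference; 0.05 gives a comfortable margin between
spike events relative to $\tau$).  The plastic synapse is excitatory:
its mantissa range $[0, 255]$ matches the reference's normalization of
weight errors by $\tilde w_{max} = 255$.

What passing tests on these fixtures show — and do not.  The engine is
checked for *exact* equality against an independently written scalar
(unit-by-unit, loop-based) oracle on randomized static networks; that is
the desk-scale stand-in for the hardware-vs-software spike-train match
and validates the deterministic integer pipeline completely.  For the
stochastic parts no trial-by-trial reference exists even in principle
(the chip's rounding RNG is not public), so — like the original
emulator's validation — the tests are distributional: unbiasedness of the
rounding, mean-trace agreement with $(1-1/\tau)^t$ over 400 trials, and
the sign/monotonicity structure of the STDP window.  None of this says
anything about hardware core/routing constraints, register widths, or the
chip's refractory bookkeeping inside the voltage register, all of which
are intentionally not modelled.

## Numerical and design notes

- All "integers" are R doubles; exactness is guaranteed because every
  intermediate is an exact binary rational below $2^{53}$.
- `stochastic_round()` always consumes exactly one variate per element,
  including for on-grid values (which it returns with probability 1), so
  stream positions are a pure function of the schedule.
- Degenerate inputs: an empty connection list is a valid network of
  isolated units; a zero-mantissa synapse encodes to $J = 0$; `tau = 1`
  makes a trace memoryless (decay factor 0).
- Configuration validation rejects unknown keys (a misspelled parameter
  should fail loudly, not be ignored) and all cross-references are
  resolved before any state is allocated.
- Monitors sample post-update values within the step, so a monitored
  variable at step $t$ is the value that influences step $t+1$.

## Problem sizes

The shipped test-suite sizes are the package's reference scales: the
engine-vs-oracle equivalence uses 50-unit networks for 1000 steps over 20
seeds; trace statistics use 400 trials; rounding unbiasedness uses
$10^5$ draws; the chaotic fixture is exercised for 10\,000 steps in the
suite and runs the full documented 100\,000 steps in about a minute via
`run_network(make_fixture("chaotic-net"), 1e5, seed)`.

## Known limitations

- Homeostasis, reward traces and learning-rule tags are not implemented.
- The chip's proprietary rounding RNG cannot be matched draw-for-draw;
  only distributional agreement is achievable.
- The intra-step schedule is this package's documented choice; chip
  exactness of the schedule cannot be claimed without hardware access.
- No hardware resource limits (cores, synapse memory, fan-in) are
  modelled; configurations that could never be placed on a chip will run
  happily here.
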