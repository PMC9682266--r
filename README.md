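# loihisim

A fixed-point spiking-neural-network simulator that emulates the
computational unit of Intel's Loihi neuromorphic chip in software.  It is
aimed at computational neuroscientists and neuromorphic-algorithm designers
who want to prototype networks with Loihi's exact integer semantics —
decay constants, weight precision, rounding modes, trace-based plasticity —
without access to the hardware.

## The model

Each unit is a current-based leaky integrate-and-fire neuron evolved with
forward Euler in integer arithmetic.  With decay constants
δ<sup>I</sup>, δ<sup>v</sup> ∈ [0, 4096] (δ = 2¹²/τ), the per-step updates
are

    I[t] = raz( I[t-1] · (4096 - δᴵ) / 4096 ) + Σⱼ Jᵢⱼ · sⱼ[t]
    v[t] = raz( v[t-1] · (4096 - δᵛ) / 4096 ) + I[t] + I_bias

where `raz(x) = sign(x)·⌈|x|⌉` is *round away from zero*.  A spike fires
when `v > v_th` (strictly), the voltage resets to zero and is clamped there
for the refractory period.

Synaptic weights are stored as a mantissa w̃ and exponent Θ ∈ [−8, 7].
The precision exponent is `n_s = 8 − (n_wb − σ_mixed)`; the mantissa is
truncated toward zero to a multiple of 2^n_s, scaled by 2^(6+Θ), clipped at
21 bits (a single representable case: w̃ = −256, Θ = 7 in mixed mode), and
the six low bits are zeroed, giving the effective weight J.

Plasticity uses bounded integer traces x₁, x₂ (pre) and y₁, y₂, y₃ (post)
in [0, 127] with first-order decay `α = 1 − 1/τ` and *stochastic rounding*
(unbiased, probability proportional to proximity).  Learning rules are
sums of products of traces, the dependency factors x₀/y₀ and power-of-two
constants, e.g. the asymmetric STDP rule

    dw = 2⁻² · x₁ · y₀ − 2⁻² · x₀ · y₁

evaluated every 2^k steps; the mantissa update itself is stochastically
rounded to the weight-precision grid.

## Worked example

```r
library(loihisim)

# the weight codec: full-scale excitatory mantissa at exponent 0
spec <- synapse_spec(mantissa = 255, exponent = 0)
encode_weight(spec)
#> [1] 16320          # 255 * 2^6, six low bits already zero

# single plastic synapse under asymmetric STDP (the built-in fixture:
# plastic weight mantissa 128 at exponent -6, strong static noise synapse,
# trace impulses 120 with tau = 8)
cfg <- make_fixture("stdp")
rec <- run_network(cfg, steps = 2000, seed = 7)
rec
#> <loihi_recording> 2000 steps, seed 7, 492 spikes, 8000 samples, 16000 RNG draws
#>   post: 492 spikes

w <- subset(rec$samples, variable == "mantissa")
c(start = w$value[1], end = tail(w$value, 1))
#> start   end
#>   128   255
```

The post-synaptic unit fires about 492 times in 2000 steps (driven by the
noise synapse at rate 0.05 plus the input synapse), and correlated
pre/post spiking drives the plastic mantissa from its initial 128 up to
the excitatory ceiling 255.

The full weight table (one row per representable mantissa/exponent pair)
is available programmatically or from the shell:

```r
head(enumerate_weight_table(6, "excitatory"), 3)
#>   mantissa exponent weight
#> 1        0       -8      0
#> 2        4       -8      0
#> 3        8       -8      0
```

```sh
inst/cli/loihisim weights-table --n-wb 8 --sign-mode mixed --out table.csv
inst/cli/loihisim fixtures chaotic-net --out net.yaml
inst/cli/loihisim run net.yaml --steps 10000 --seed 1 --out out/
```

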