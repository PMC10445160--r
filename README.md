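# rbncrit

Random Boolean network (RBN) reservoirs sit between order and chaos
depending on how their random weights are drawn. This package is for
computational-neuroscience and reservoir-computing researchers who want a
reproducible, tested pipeline for the whole phenomenology: it generates
fixed in-degree binary reservoirs controlled by a single parameter, maps
that parameter to the excitatory/inhibitory balance, locates the two
critical points of the free dynamics, classifies steady-state attractors,
and benchmarks memory and prediction with a trained linear readout.

## The model in brief

`N` binary neurons update synchronously through a strict Heaviside
threshold,

    x_i(t) = θ( w_in_i · u(t) + Σ_j w_ij · x_j(t−1) ),    θ(0) = 0,

with exactly `K = 16` incoming recurrent weights per neuron, i.i.d.
Gaussian `N(μ, σ)`. Because the threshold ignores positive rescaling, the
free dynamics depend on the weights only through

    σ* = σ/μ   (μ ≠ 0),

and σ* fixes the expected excitatory/inhibitory balance
`b = (S₊ − S₋)/S = 2Φ(1/σ*) − 1` (Φ the standard normal CDF). Sweeping σ*
reveals two critical points where the across-reservoir variance of the
**BiEntropy** of the binarized steady activity peaks: an inhibition-
dominated one at σ* ≈ −0.66 (b ≈ −0.87, 94% inhibitory synapses) and a
much broader excitation-dominated one at σ* ≈ 4 (b ≈ +0.20, 60%
excitatory). Steady activities fall into four attractor classes
(extinguished, fixed, cyclic, irregular); task performance — recalling
white noise shifted by δ < 0, or forecasting Mackey-Glass series δ = +10
ahead — is read out by a sigmoid unit trained on half the neurons.

## Worked example

```r
library(rbncrit)

## balance at the two critical points
balance_from_sigma_star(-0.66)
#> balance b = -0.8703 (6.5% excitatory, 93.5% inhibitory)
balance_from_sigma_star(4.0)
#> balance b = +0.1974 (59.9% excitatory, 40.1% inhibitory)

## a perfectly balanced reservoir settles at half activity
r <- generate_reservoir(1000, 16, "balanced", seed = 1)
run_free(r, init_state(1000, 0.2, seed = 2))
#> activity trace: 2000 steps (1000 transient), steady mean A = 0.4999, var = 9.71e-05

## locate the inhibitory critical point at desk scale (about 90 s)
neg <- scan_phase(seq(-0.9, -0.5, by = 0.01), n_reservoirs = 20,
                  n_neurons = 2000, seed = 1)
neg$criticality
#> critical point sigma* = -0.66 (peak BiEntropy variance 0.211)
#> critical region: [-0.71, -0.63], width 0.08 (threshold 0.01 of peak)
```

The steady mean of 0.4999 is the half-activity fixed point of the
zero-mean (perfectly balanced) ensemble; the scan's variance peak at
−0.66 is the critical point, and the narrow region around it is where
reservoirs disagree about order versus chaos — the edge of chaos.

## Analysis workflow

The numbered drivers under `analysis/` run the full study at desk scale
and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_balance_curve.R` | analytic vs empirical balance over a σ* grid |
| `02_phase_scan.R` | both phase scans + critical points/regions |
| `03_attractors.R` | attractor landscape below/at/above each critical point |
| `04_tasks.R` | memory and prediction sweeps with attractor tags |
| `05_cross_task.R` | paired memory/prediction scores per reservoir |

Each is a thin narrative over exported functions (`scan_phase()`,
`scan_attractors()`, `run_task_sweep()`, `cross_task()`), so everything
they do is unit-tested and callable directly.

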