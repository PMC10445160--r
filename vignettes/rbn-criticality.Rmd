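---
title: "Random Boolean network reservoirs: balance, criticality and task performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random Boolean network reservoirs: balance, criticality and task performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbncrit)
```

## The model

A random Boolean network (RBN) reservoir is a recurrent network of `N`
binary threshold neurons updated synchronously:

$$x_i(t) \;=\; \theta\!\Big(w^{in}_i u(t) + \sum_j w_{ij}\, x_j(t-1)\Big),
\qquad \theta(z) = \mathbb{1}[z > 0],$$

with the strict Heaviside convention $\theta(0) = 0$, applied everywhere —
in particular a neuron whose inputs are all silent stays silent, which makes
the all-off state absorbing under zero drive. Every neuron receives exactly
`K = 16` nonzero recurrent weights from distinct presynaptic partners
(self-connections excluded; the in-degree is fixed, not merely expected),
drawn i.i.d. from a Gaussian $\mathcal N(\mu, \sigma)$.

Because $\theta(\lambda z) = \theta(z)$ for any $\lambda > 0$, the free
dynamics are invariant under positive rescaling of the weight matrix: the
pair $(\mu, \sigma)$ only enters through the single control parameter

$$\sigma^\star = \sigma/\mu \quad (\mu \neq 0),$$

and every reservoir is simulated at the canonical parameters
$(\pm 1, |\sigma^\star|)$ ([`canonical_params()`]). The zero-mean case is a
distinguished limit, requested with the token `"balanced"` and simulated at
$\mathcal N(0, 1)$. The scale invariance is asserted bit-exactly in the test
suite, for free and driven runs alike.

$\sigma^\star$ also fixes the expected excitatory/inhibitory balance
$b = (S_+ - S_-)/S$, the signed fraction of positive minus negative
synapses: for the canonical Gaussian,

$$b = P(w > 0) - P(w < 0) = 2\,\Phi(1/\sigma^\star) - 1 .$$

```{r balance}
balance_from_sigma_star(-0.66)  # inhibition-dominated critical point
balance_from_sigma_star(4.0)    # excitation-dominated critical point
```

`balance_from_sigma_star()` is the analytic route; `empirical_balance()`
counts signs in a generated weight table, and `balance_curve()` tabulates
both side by side so the closed form stays auditable against the sampled
matrices.

## Free-running dynamics and the two critical points

The observable is the population activity $A(t) = \sum_i x_i(t)/N$, stored
internally as the exact integer active count so that periodicity tests use
exact equality rather than floating-point comparison. Runs start from a
random state with 20% active neurons, discard a 1,000-step transient, and
measure on the steady window. The steady window defaults to 1,000 steps —
equal to the transient — which keeps period detection (periods up to 500)
and the BiEntropy estimate well-sampled.

Per reservoir we compute the time mean $\bar A$, the time variance
$\overline{\delta A^2}$ (population convention), and the **BiEntropy**
$H_b$ of the binarized steady activity. BiEntropy is a weighted average of
the Shannon entropies of a bit string and of all its successive binary
derivatives (pairwise XOR of neighbours); unlike plain Shannon entropy it
scores *ordered* streams (constants, alternations) near 0 and disordered
streams near 1. The power-weighted form is exact but its weights overflow
beyond a few dozen bits, so strings longer than 32 bits use the
logarithmic-weight variant — the prescription for long streams — and the
1,000-bit steady windows always take that branch. Two numerical anchors
pin the implementation: constant strings give exactly 0, and the
alternating 8-bit string gives exactly $1/127$ (only the $k = 0$ term
contributes, with entropy 1 and weight $2^0$ over $2^7 - 1$).

**Binarization rule.** The activity is thresholded at its own steady-window
time mean, $s(t) = \mathbb 1[A(t) > \bar A]$. This rule is parameter-free,
maps every constant trace (fixed points, saturation, extinction) to the
all-zero — fully ordered — string, and maps period-2 oscillations to the
alternating string. It is our choice of a reasoned, reproducible rule; any
monotone threshold in the interior of the activity range gives the same
string up to complementation, and BiEntropy is invariant under
complementation.

Ensemble statistics ([`ensemble_stats()`]) aggregate over independently
generated reservoirs at the same $\sigma^\star$: the across-reservoir
variance of $H_b$, $\langle\delta H_b^2\rangle$, is zero deep in both the
ordered and disordered phases and spikes where reservoirs disagree — the
edge of chaos. [`locate_critical()`] defines the **critical point** as the
grid argmax of $\langle\delta H_b^2\rangle$ (leftmost on ties, flagged) and
the **critical region** as the contiguous interval around the peak where
the variance exceeds 1% of its peak value. The 1% floor replaces a literal
"nonzero variance" criterion, which is not robust under finite sampling:
with 20 reservoirs per point a single stray trace can make the variance
technically nonzero anywhere.

At desk scale (N = 2,000, 20 reservoirs per point, grid step 0.01 on the
negative branch and 0.1 on the positive branch) the scans place the
inhibitory critical point at $\sigma^\star_c \approx -0.66$
(balance $b_c \approx -0.87$, i.e. 94% inhibitory synapses) and the
excitatory one near $\sigma^\star_c \approx 4$ ($b_c \approx +0.20$, 60%
excitatory), with the positive-side transition more than an order of
magnitude wider — run `analysis/02_phase_scan.R` to regenerate the tables.
The peak position is stable between N = 2,000 and N = 4,000 within grid
resolution; the asymmetry between branches is intrinsic to the threshold
nonlinearity ($\theta(-z) \neq \pm\theta(z)$).

## Attractor classification

Steady activities fall into four categories ([`classify_trace()`]):
**extinguished** ($A \equiv 0$ on the steady window), **fixed** (constant
nonzero $A$, including saturation $A \equiv 1$), **cyclic** (exact minimal
period between 2 and half the window), and **irregular** (no period found
within the window). Classification deliberately operates on the scalar
activity $A(t)$, not the full state vector; a cyclic *state* trajectory
always yields a cyclic activity whose period divides the state period, but
activity aliasing could in principle mask structure. The test suite
quantifies this by exhaustively enumerating state-space cycles of tiny
networks ($N \le 12$) and checking the activity-level labels against them.
Periods longer than half the window are reported irregular by
construction; the network being finite and deterministic, every trajectory
is eventually periodic, so "irregular" means "not resolved within the
window", which is the operationally relevant notion for a 1,000-step
observation.

Each reservoir run from many initial conditions is assigned its
**dominant attractor** — the modal category, with ties broken toward the
less complex category (extinguished < fixed < cyclic < irregular) and
flagged; ties are rare in practice. Away from the critical points dominance
is near 1: the attractor is a property of the reservoir, not of the
initial state.

## Task benchmarks

Two tasks probe computation with the target $T(t) = u(t + \delta)$:

* **memory** ($\delta < 0$): the input is i.i.d. white noise, uniform on
  $[0.1, 0.9]$ — with zero autocorrelation the readout must genuinely
  remember. The amplitude interval is our choice (unspecified in the
  protocol we follow): it keeps targets strictly inside the sigmoid range
  with margin.
* **prediction** ($\delta = +10$): the input is the Mackey-Glass series,
  $\dot x = 0.2\,x_\tau/(1 + x_\tau^{10}) - 0.1\,x$ with delay
  $\tau \in \{5, 20, 28\}$, integrated by fixed-step fourth-order
  Runge-Kutta (internal step 0.1, linear interpolation of the stored
  history at off-grid delayed times), sampled every 1.0 time unit from the
  constant history 1.2 with a 1,000-sample warm-up, then rescaled affinely
  into $[0.1, 0.9]$ (the affine map is stored in the series provenance).
  $\tau$ tunes regularity from periodic ($\tau = 5$) to chaotic
  ($\tau = 28$). The integrator preserves the equilibrium $x^* = 1$
  exactly from a constant-1 history, halving the internal step changes the
  pre-chaotic segment by under $10^{-3}$ RMS, and an independent adaptive
  DDE solver reproduces the trajectory — all asserted in the tests. One
  caveat: the $\tau = 5$ limit cycle's period is incommensurate with the
  unit sampling, so the sampled series is only *approximately* periodic at
  integer lags; tests therefore discriminate periodic from chaotic via a
  near-recurrence distance rather than exact integer-period detection.

Half of the neurons (chosen once per reservoir, uniformly) receive the
input through weights drawn uniformly from $[-0.5, 0.5]$ with half zeroed;
the disjoint other half is visible to the readout, so input information
must traverse the reservoir. A benchmark run redraws the input weights
("tossing") several times on the same input half — five per reservoir in
the reference protocol — and averages the score.

The readout is a single sigmoid unit $y(t) = f(W x + c)$ trained by
full-batch ADAM on the MSE loss (learning rate $10^{-3}$, 4,000 epochs, no
early stopping), from zero-initialized weights so training is
deterministic. A closed-form alternative — ridge regression of the
readout states against $\mathrm{logit}(T)$ — is provided as
`ridge_readout()`. On well-conditioned instances the two agree to within
0.02 in correlation (a cross-oracle test), and on the instances used here
they agree to three decimals while ridge is orders of magnitude faster, so
ensemble-level analyses default to the ridge trainer; the ADAM trainer
remains the reference implementation and is exercised directly by the
tests. Scoring is the Pearson correlation $\mathrm{Corr}(y, T)$ on a
held-out test segment (training-segment scoring is available via
`score_on = "train"`); a washout of aligned samples precedes the training
segment, and degenerate (zero-variance) outputs score 0 by convention.

## Problem sizes and reproducibility

The reference protocol runs N = 10,000 neurons, 100 reservoirs per grid
point and 100 initial conditions. The package's experiment defaults are a
desk-scale profile chosen once for this implementation: N = 2,000 with 20
reservoirs per point for phase scans (the peak location is already stable
there), N = 1,000–1,200 with 5–10 reservoirs for attractor landscapes and
task sweeps, and training segments of 2,000 samples. All protocol numbers
are arguments, so the full-scale settings are one call away. At task-sweep
scale (around a thousand neurons) memory correlations are necessarily far
below the full-scale ones — the sparse near-critical activity carries less
information — but the qualitative structure this package tests (difficulty
monotonicity in $|\delta|$ and $\tau$, low reservoir-to-reservoir spread on
the inhibitory branch against the wide spread on the excitatory branch,
the collapse of frozen reservoirs) is already present.

Every source of randomness flows from explicit integer seeds.
[`seed_stream()`] derives one seed per (grid point, reservoir, run) triple
as a pure function of the master seed and a unique linear index, so any
table regenerates byte-identically from its master seed and no two runs
share a seed.

## What the generators do and do not emulate

The synthetic inputs reproduce the statistical structure the analyses
assume: Gaussian fixed-in-degree weights, uniform half-zeroed input
weights, uncorrelated bounded white noise, and the Mackey-Glass family
from periodic to chaotic. They do not emulate structured topology (degree
heterogeneity, modularity, spatial embedding), correlated or nonstationary
task signals, or measurement noise on the states — so passing tests here
demonstrate the internal consistency of the pipeline and the
reproducibility of the phase structure under the stated model, not
robustness of the conclusions to real-world deviations from it.

## Known limitations

* Activity-level attractor labels can alias distinct state cycles sharing
  one activity sequence; quantified, but not eliminated, by the tiny-network
  oracle tests.
* "Irregular" is window-relative; cycles longer than 500 steps are not
  resolved at the default window.
* The critical-region boundaries depend on the 1% peak-fraction threshold;
  the *point* estimates do not.
* The analytic balance uses the canonical Gaussian; non-Gaussian weight
  laws are out of scope.
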