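---
title: "Methods: simulating and classifying visual-flow perturbation responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying visual-flow perturbation responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vfsim` is a desk-scale simulation-and-analysis chain for one question:
how does a laminar cortical microcircuit, driven only by bottom-up
visual input, split its excitatory layer 2/3 population into neurons
that depolarize (dVf) and neurons that hyperpolarize (hVf) when visual
flow suddenly starts or stops? This vignette documents the model, its
assumptions, the tunable parameters, the synthetic-column generator, the
numerical choices, and the limits of what the package's tests show.

## 1. Neuron and synapse dynamics

Neurons are GLIF3 point neurons: leaky integrate-and-fire with two
after-spike currents (ASC) on fast and slow timescales. The membrane
update is an exponential-Euler step, which is *exact* for constant input
over a step:

v(t+δt) = α v(t) + (1−α)[(I_ext + I_int)/g + E_L],  α = e^(−δt/τ), τ = C/g.

Units are pF, nS, mV, pA and ms, so pA/nS = mV and no unit constants
appear. The spike condition is v ≥ v_th (we take H(0) = 1; the
convention matters only on a measure-zero set of trajectories). Each
after-spike current decays as I_m ← e^(−k_m δt) I_m.

**Reset and refractoriness.** A spike sets v to v_r and starts a
refractory hold of δ_r ms during which the membrane does not integrate
while synaptic channels and ASCs keep evolving. At release the ASC reset
I_m ← R_m I_m + A_m is applied. Two published descriptions of the ASC
spike increment exist side by side in this model family — an increment
z·A_m inside the per-step recursion, and the reset-rule increment after
the refractory period. Applying both would add A_m twice per spike; we
follow the canonical GLIF3 convention and apply it once, at refractory
release. The exported `ascUpdate()` still exposes the recursion form
(with an explicit spike argument) so the elementary rule can be tested
in isolation; the integrator drives it with the spike term off and uses
`applyReset()` at release.

**Synapses.** Every source category (LGN, background, recurrent-E,
recurrent-I) is an alpha-function channel per neuron, integrated by the
exact two-state recursion

I(t+δt) = e^(−δt/τ_syn)[I(t) + δt·C(t)],
C(t+δt) = e^(−δt/τ_syn) C(t) + (e/τ_syn) Σ_i W_ji z_i(t),

so a single spike of weight W produces exactly W·(t/τ)e^(1−t/τ) at grid
points (peak W at t = τ). τ_syn is 5.5, 8.5, 2.8, 5.8 ms for E→E, I→E,
E→I, I→I. Delays are integer steps in 1–4 ms, realized through
per-delay-slot accumulation buffers; a spike at step s with delay d
first affects the target's current at step s+d+2 (one step for the
arrival to enter the charging state, one for the charge to move into the
current), which the causality tests pin down.

**Within-step order.** Record state → threshold test (schedules delayed
arrivals) → membrane/ASC update using currents at t → synaptic update
consuming arrivals due at t. Recorded traces therefore hold state values
*at* each step, and inverting the membrane recursion from the voltage
trace recovers the recorded source currents exactly — that identity is
an acceptance test.

**Initial conditions and trials.** All state variables start at zero
(literally, v = 0 mV — the published convention), which produces a large
onset transient; therefore every run prepends one warm-up trial that is
simulated and discarded, and state carries over between the analyzed
trials (default 20). A config switch `initAtRest` starts at E_L instead
for controlled single-neuron experiments. Per-trial input seeds derive
deterministically from the master seed, so identical (network, protocol,
seed) gives identical rasters.

## 2. The synthetic column generator

The generator stands in for a released multi-hundred-thousand-neuron
model that this package deliberately does not ingest. It reproduces the
statistical wiring structure the mechanism depends on, not any
particular published connectome instance.

* **Geometry.** A cylinder of radius 150 µm with layer depth intervals
  L1 0–100, L2/3 100–310, L4 310–430, L5 430–650, L6 650–850 µm.
  Positions are uniform in the disk and within the layer interval;
  tuning angles are independent uniform on [0°, 360°).
* **Composition.** ~4,900 neurons: one excitatory and three inhibitory
  classes (Pvalb, Sst, Htr3a) per layer, only Htr3a in L1; counts follow
  mouse V1 proportions at roughly 1/10 of a 400 µm core column.
* **Connectivity.** Ordered pairs connect independently with
  p = p_base · exp(−(d²−75²)/(2σ²)) (clamped to [0,1]) so the base
  matrix is read at the 75 µm reference distance. The numeric p_base,
  σ and mean-weight values are *illustrative config defaults* chosen to
  preserve the canonical ordering structure — strong within-layer
  E–Pvalb reciprocity, L4→L2/3 feedforward excitation, dominant
  within-layer Pvalb inhibition — with σ = 160 µm for E→E down to 85 µm
  for I→I.
* **Like-to-like.** Weights are modulated as w̄(1 + κ cos Δθ), κ = 0.35
  by default; the modulation averages to w̄ over uniform Δθ and cannot
  flip the sign for κ < 1. Published accounts apply a probability bias
  to E→E pairs and a strength bias elsewhere; the generator applies the
  strength bias everywhere and exposes the E→E probability bias as an
  off-by-default switch (`likeToLikeProbE`), keeping the default
  generator simpler to reason about.
* **LGN afferents.** Only excitatory and Pvalb cells in L2/3–L6 and
  Htr3a cells in L1 may receive thalamic synapses. In-degrees are
  negative binomial per target type: dense onto L4 (µ = 15), sparse and
  strongly overdispersed onto L2/3 excitatory cells (µ = 3.5,
  size = 0.6, giving ~30% zero in-degree). That zero-mass is load
  bearing: cells without direct LGN input can only feel the flow onset
  through recurrent inhibition, which is what makes them hVf.
* **Background.** One shared 1 kHz Poisson source with type-specific
  weights. Because the source is shared, it injects common-mode
  fluctuations — this is the published noise model, and it keeps the
  column in a fluctuation-driven regime at low excitatory baseline rates
  (~0.1–2 Hz excitatory, ~5–10 Hz Pvalb).

**Calibration.** The wiring numbers were calibrated once, during model
construction, to put the column in that balanced regime and were then
frozen. The guiding targets were biological plausibility (baseline
rates, E/I balance of the baseline current within a few pA) — not any
specific output percentage. Across column realizations the L2/3 class
shares move considerably (dVf roughly 8–17%, hVf roughly 30–70%);
hyperpolarized cells usually outnumber depolarized ones. What is stable
across realizations is the mechanism: both classes present, an
order-of-magnitude LGN in-degree gap between them, and near-complete
sign reversal under a flow halt.

## 3. The stimulus front-end

The published thalamic model (17,400 units in 14 filter subclasses) is
replaced by an explicit parametric front-end — the package's largest
deliberate simplification. Each of 400 units samples the stimulus at a
retinotopic position (uniform in a 60° field), half ON and half OFF:

* **Gratings** contribute the luminance signal
  sin(2π·sf·(x cosθ + y sinθ) + φ − 2π·tf·t), with the temporal phase
  frozen during static epochs (default protocol: 500 ms static, 1000 ms
  drift, 1000 ms static; the halt protocol reverses the drift flags).
* **Flashes** contribute a luminance step (black = −1, white = +1;
  500/1000/1000 ms).
* The signal passes through a biphasic temporal kernel — the difference
  of two exponential low-passes (τ₁ = 20, τ₂ = 60 ms), zero DC gain,
  normalized to unit peak frequency gain — and is rectified around the
  baseline: rate = max(0, r₀ + polarity·r₁·contrast·y(t)).

The kernel is what makes the front-end *transient*: a static grating,
whatever its spatial phase, drives every unit back to r₀, while drift
produces a rectified oscillation whose temporal mean exceeds r₀ (Jensen's
inequality on the rectifier). Without it — a frozen/drifting raw
sinusoid, available as `temporalFilter = "none"` — the population mean
LGN rate would be identical between static and drifting epochs and the
flow onset would inject no net bottom-up surge, so no laminar response
could emerge. With r₀ = 8 Hz, r₁ = 55 Hz per unit contrast and 0.8
contrast, a 2 Hz drift roughly doubles the mean unit rate.

Because the drive amplitude is direction-independent in this front-end
(direction only shifts each unit's temporal phase), downstream responses
are nearly uniform across the 8 drift directions: most classified
neurons come out perturbation-sensitive and few come out
direction-selective. Orientation/direction tuning of the responses, and
any specific temporal-frequency preference, are properties of the
replaced filter bank that this package does not claim to reproduce;
`classifyAcrossDirections()` and `preferredFrequency()` implement the
definitions and are exercised on synthetic label sets.

## 4. Analysis chain

* **Rheobase.** 1000 ms rectangular pulses from rest, starting at 1 pA
  and incrementing by 0.01 pA with a reset between pulses; the result is
  the first firing grid current. For ASC-free parameters it brackets the
  finite-pulse analytic bound g(v_th−E_L)/(1−α^1000) within one
  increment (tested over a 20-set parameter sweep).
* **Response.** I₀ is the mean total current over the 500 ms before the
  perturbation (per trial, then averaged — algebraically identical to
  averaging first); ΔI is the sum of the four source means over the
  1000 ms perturbation window minus I₀. The decomposition identity
  ΔI = ⟨I_in⟩+⟨I_noise⟩+⟨I_rec⟩+⟨ΣI_m⟩−I₀ holds to machine precision by
  construction and is asserted at 10⁻¹².
* **Classification.** Strict thresholds at ±0.05·θ_rheo; boundary values
  remain unclassified. Sign-flipping every ΔI swaps the dVf and hVf
  counts exactly.
* **Firing rates.** Spike trains are binned at 60 Hz and smoothed with a
  Gaussian kernel. "A 150 ms Gaussian filter" is interpreted as kernel
  standard deviation 150 ms, truncated at ±3σ and normalized to unit
  mass (spike count preserved up to ≤1% edge truncation); this is an
  interpretation, flagged as such.
* **Effective weights.** W_eff = (1/Δt) Σ W·x_i(t) per synapse,
  aggregated by presynaptic type, in the 500 ms windows before and after
  the perturbation; trial-averaged presynaptic spike counts enter the
  sum. Verified against brute-force loops at 10⁻¹⁰.
* **Ripley's K.** K(t) = (A/n²) Σ_i Ñ_i(t) on the column disk, each
  neighbour count divided by the in-domain fraction of the search circle
  (analytic two-circle lens area). The estimator is checked against an
  all-pairs brute force with the same weights, against deterministic
  quadrature of the lens area, against the worked three-point example
  (K = 200π/9), and against the CSR null — 100 realizations of 10,000
  uniform points stay within 2% of πt² up to t = 0.3R.
* **Statistics.** More than two groups: one-way ANOVA gate at p < 0.01,
  then pairwise two-sided Welch t-tests; exactly two groups: Welch
  directly. Stars at 0.05/0.01/0.001/0.0001. These are standard
  `stats` routines (`aov`, `t.test`) behind the package's interface.

## 5. Numerical and design choices

* δt = 1 ms everywhere; epoch durations must be whole numbers of steps.
* Closed-form checks at 10⁻⁹ relative: the membrane test uses the exact
  solution E_L + (I/g)(1−e^(−t/τ)) + (v(0)−E_L)e^(−t/τ).
* Preferred-frequency ties break toward the lower frequency.
* Effective weights are reported in pA·spikes/step with the window in
  steps.
* Serialization is YAML (configuration) + CSV (tables) + JSON
  (manifests); the R interface and orchestration functions
  (`buildColumn`, `runExperiment`, `runSweep`, `runOnsetHalt`,
  `analyzeExperiment`) are the package's entry points.
* Problem sizes in the shipped tests: the emergent-behavior experiment
  uses the full default column (~4,900 neurons, 20 analyzed trials, the
  8-direction sweep plus a halt run); oracle comparisons use ≤200-point
  instances; the CSR null uses the full 100 × 10,000 construction.

## 6. What the tests do and do not show

The test suite establishes that the integrator is exact where exactness
is provable, that the generator's statistical laws hold (distance law
within binomial error, overdispersion, targeting rules, sign
discipline, determinism), and that the emergent two-class behavior with
its LGN in-degree signature and halt reversal appears in the synthetic
column under the default conditions. It does not show that the specific
class percentages of any full-scale data-driven model or of biological
V1 are reproduced — the column is three orders of magnitude smaller,
uses one GLIF parameter set per cell class rather than per-cell fits,
has no retinotopic weight gradients, no top-down or locomotion input,
and a deliberately simplified thalamic front-end. Those population
numbers are out of scope by design.
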