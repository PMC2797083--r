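---
title: "Synchronization as protection from intrinsic noise: models, bounds, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization as protection from intrinsic noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscnet)
```

## The problem

Neurons, cardiac cells and many other biological oscillators operate under
substantial *intrinsic* noise — random fluctuations whose intensity does not
depend on the inputs.  A single FitzHugh–Nagumo (FN) oscillator subjected to
strong white noise loses both its temporal waveform and its spectral
signature: the limit cycle survives only as a broad bump in the power
spectrum, with no clear harmonics.  Averaging over many *independent* noisy
nonlinear oscillators does not recover the signal either: the fluctuations
average out, but so does the oscillation, because the units drift out of
phase and the nonlinearity prevents the population mean from following the
single-unit dynamics.

Mutual diffusive (gap-junction-like) coupling changes the picture
qualitatively.  When the units synchronize, each one — and their population
mean — behaves like a *noise-free* oscillator, even at noise intensities
that completely disrupt an isolated unit.  This package simulates that
phenomenon, computes the stochastic-contraction bounds that quantify it,
and provides the diagnostics (spectra, harmonic matching, a nonlinear state
observer) that certify it.

## Models

The network is

$$dx_i = \Big[f(x_i, t) + u(t)\,e_{\mathrm{in}} + \sum_j w_{ij}\,(x_j - x_i)\Big]dt
  + \sigma\, dW_i, \qquad i = 1,\dots,N,$$

with $f$ the single-unit drift, $u(t)$ a common input, $w_{ij} \ge 0$ the
weight of the connection from unit $j$ into unit $i$, and $W_i$ independent
Wiener processes of constant intensity $\sigma$ acting on the noise-masked
components (the membrane potential, by default).

Two neuron models ship as presets, with all constants in
`inst/extdata/model_presets.yaml` (one source of truth; nothing numeric is
hard-coded in R):

* **FitzHugh–Nagumo** in FitzHugh's classical parameterization
  $\dot v = c(v + w - v^3/3) + I$, $\dot w = -(v - a + bw)/c$ with
  $a = 0.3$, $b = 0.8$, $c = 3$.  These values give a stable limit cycle at
  zero input (period $\approx 10.4$ time units, $|v| \lesssim 2$), which is
  what the protection experiments need; $b < 1$ and $c > 1$ also put the
  recovery variable on the slow timescale $c/b$ that the bound derivation
  uses.
* **Hindmarsh–Rose**, the standard three-dimensional
  spiking/bursting model with the textbook constants $a=1$, $b=3$, $c=1$,
  $d=5$, $s=4$, $x_r=-1.6$, $r=0.006$; the common input may be
  time-varying, provided all units receive the same signal.  The
  contraction bounds are *not* claimed for this model — it is simulated,
  not bounded.
* **Time-varying linear systems** $\dot x = A(t)x + b(t)$, including the
  Ornstein–Uhlenbeck (OU) unit used to validate the integrator and the
  classical $1/\sqrt N$ averaging law.

User models plug in through `oscillator_model()` with a vectorized drift;
curvature information can be supplied in closed form or obtained from a
finite-difference fallback (central differences with step
$10^{-6}(1+|x|)$, maximized over a grid in the operating ball).

## Networks

`coupling_graph()` stores the weight matrix with the *row-receives*
convention ($w_{ij}$: influence of $j$ on $i$), asserted in the tests.  A
network is **balanced** when every node's incoming weight sum equals its
outgoing sum; any symmetric network is balanced.  Balance is the structural
assumption behind everything that concerns the population mean: summing the
diffusive terms over nodes cancels them exactly, so the mean feels only the
averaged drift and the averaged noise.

Three generators cover the designs used here: `build_all_to_all()`,
`build_probabilistic()` (each unordered pair connected with probability
$p$, symmetrically — realizations are not forced to be connected; a
disconnected draw only triggers a warning, since nothing forbids simulating
one), and arbitrary matrices.  `to_quorum_star()` rewrites the all-to-all
network in quorum-sensing form: $k\sum_j (x_j - x_i) = Nk(\bar x - x_i)$,
i.e. local damping plus attraction to one shared mean signal — $N$
connections instead of $N^2$, and identical dynamics to floating point
(the tests require agreement to $10^{-10}$ over $10^4$ steps under a shared
noise stream).

## Integration

`euler_maruyama()` implements the explicit Euler–Maruyama scheme, the
standard choice for additive-noise SDEs; no adaptive stepping is attempted
(step control is ill-posed pathwise under white noise).  Per step:
drift + coupling + input times $dt$, then $\sigma\sqrt{dt}$ times
independent standard normals on the noise-masked components.  Runs are
bitwise reproducible given `(seed, config)`; `noise_stream()` provides
self-contained generators with private RNG state for matched-noise designs
(quorum-star equivalence, coarse/fine step comparisons with a shared
Brownian path).  A divergence guard aborts when any component exceeds
$10^6$ — cubic drifts explode if $dt$ is too large.

Numerical accuracy matters in one specific place: the stationary variance
of an explicitly integrated linear mode with damping $\lambda$ is inflated
by a factor $\approx 1/(1 - \lambda\,dt/2)$.  Where a simulated statistic
is compared against a theoretical *upper bound* (the coupling sweep below),
the step is therefore tied to the fastest damped mode,
$\kappa\,dt \le 0.0125$ with $\kappa = Nk$, keeping the inflation near
0.6%; halving $dt$ moves the statistic by well under 2%.  Elsewhere
(spectral work) $dt = 10^{-3}$ suffices.

Initial conditions are drawn uniformly from per-model boxes covering the
noise-free attractor with margin (`ic_box` in the presets file) — random
starts without a stated law, made concrete and seedable.

## The synchronization error and its bound

The **synchronization error** is the expected sum over ordered pairs of
squared distances, $\sum_{i,j} E\|x_i - x_j\|^2$, estimated ergodically:
one long run, time-averaged after the transient window.  (The equally
common convention that averages over pairs is a flag on `sync_error()`; the
sum convention is the package-wide default and all bounds use it.)  The
identity

$$\sum_{i,j} \|x_i - x_j\|^2 = 2N \sum_i \|x_i - \bar x\|^2$$

links it to distances from the center of mass $\bar x$; `sync_error()`
computes both sides independently and refuses to proceed if they disagree
beyond $10^{-12}$ relative.

For $N$ FN units all-to-all coupled at strength $k$, every pairwise
difference obeys a two-dimensional linear system with time-varying cubic
feedback $\alpha(t) = (v_i^2 + v_i v_j + v_j^2)/3 \ge 0$ and total voltage
damping $\kappa = Nk$ (each pair is uncoupled from every other pair).  In
the strong-coupling regime the difference system splits into a fast voltage
mode (rate at least $\kappa - c$, driven by the noise difference at
intensity $\sigma\sqrt2$) and a slow recovery mode (rate $b/c$, reached by
the noise only through the mode mixing, at intensity
$\sigma\sqrt2/(c\kappa)$).  The eigenmode change of variables
(`eigenmode_transform()`, $y_1 = V - (c/\kappa)W$, $y_2 = W - V/(c\kappa)$)
decouples the modes to leading order; stochastic contraction bounds each
stationary mode variance by (intensity)$^2/(2\cdot$rate$)$.  Summing over
the $N(N-1)$ ordered pairs:

$$\sum_{i,j} E\|x_i - x_j\|^2 \;\le\; C
  = N(N-1)\,\sigma^2\left[\frac{1}{Nk - c} + \frac{1}{b\,c\,(Nk)^2}\right],$$

after exponential transients of rate $\min(Nk - c,\; b/c)$.  The bound is
zero without noise (noise-free networks synchronize completely), strictly
decreasing in $k$, proportional to $\sigma^2$, and $\approx (N-1)\sigma^2/k$
for large $k$, vanishing as $k \to \infty$.  `pair_bound()` is the $N = 2$
building block; the consistency of the pair decomposition
(`sync_bound_all_to_all(2, k, σ) = 2 · pair_bound(k, σ)`, and the general
bound as $N(N-1)$ copies of the pair expression at damping $Nk$) is
asserted exactly in the tests, and the expression as a whole is pinned by
the monotonicity/limit tests rather than by any particular printed numbers.
The derivation assumes $\kappa$ dominates the system parameters;
`sync_bound_all_to_all()` warns when $\kappa$ is below ten times the
largest parameter scale.

Empirically the bound is not tight but respects a consistent margin: along
the shipped coupling sweep the ergodic estimate sits at 91–98% of $C$,
because the worst case $\alpha = 0$ underestimates the actual damping
(on the limit cycle $\overline{v^2} \approx 1.8$, so the cubic term *adds*
contraction most of the time).

## The population mean

Averaging the network equations over $i$ (balance cancels the coupling)
leaves the mean driven by the averaged drift and the averaged noise.  Two
terms separate the mean from noise-free dynamics:

* **Nonlinear distortion.**  By Taylor with remainder, averaging the drift
  over units differs from the drift at the center of mass by at most
  $(Q/2)\cdot \frac1N\sum_i\|x_i - \bar x\|^2$, where $Q$ bounds the
  largest absolute Hessian eigenvalue of every drift component over the
  operating region (`hessian_bound()`: $2cR$ for FN over $|v|\le R$,
  exactly 0 for linear dynamics — linear components, inputs included,
  never distort the mean).  `taylor_mismatch()` evaluates both sides on
  snapshots; the inequality holds sample-wise along every simulated
  trajectory whose radius respects the $Q$-region.
* **Averaged noise.**  The $N$ intrinsic noises are independent, so their
  average has intensity $\sigma/\sqrt N$.

`mean_impact_bound()` combines them as $Q\,C/(4N^2) + \sigma/\sqrt N$:
with $Q = 0$ only the classical inverse-square-root averaging law remains
(the package verifies the $-0.5$ log–log slope over $N \in \{1,4,16,64\}$
OU units and the closed-form stationary variance $\sigma^2/(2aN)$), and
with synchronization ($C \to 0$ as $k$ grows) plus averaging
($N \to \infty$) the whole impact of noise on the mean vanishes — the
collective enhancement of precision.

## The observer diagnostic

How close is one noisy *synchronized* unit to a noise-free oscillator?
`run_observer()` integrates a model copy with output injection of the
measured voltage, $\dot{\hat x} = f(\hat x) + k_e(v - \hat v)e_v$.  The
injection gives the error system the same contracting two-mode structure
as a coupled pair (damping $k_e$ in place of $\kappa$), so on noise-free
input the observer converges exponentially from *any* initial condition —
the tests require decay of the squared distance below $10^{-6}$ of its
initial value with a log-linear fit of $R^2 > 0.99$ and final states
agreeing to $10^{-8}$ across starts.  The default gain $k_e = 30 = 10c$
puts the fast error mode well above the system scales so the slow $b/c$
mode dominates visibly; the gain is a free design parameter, not a
modeling commitment.  The measured signal is held constant over each step
(zero-order hold on the recorded grid — record with `record_stride = 1`
for observer work).

The time-averaged squared observer distance of a noisy unit then certifies
its closeness to noise-free behavior: it decreases with both $N$ and $k$,
and for an uncoupled unit at the same noise level it is orders of magnitude
larger.  The accompanying `observer_bound()` assembles a reference curve
from the synchronization bound and the mean-impact term via the squared
triangle inequality through the population mean ($C/N^2 + c\sigma^2/(bN)$);
it is a deliberately conservative package-level construction, used as a
plotting reference rather than a sharp claim.

## Spectral diagnostics

`power_spectrum()` is a mean-removed one-sided FFT periodogram
(rectangular window by default — Parseval-consistency with the series
variance to $10^{-8}$ is asserted; a Hann taper is available).
`dominant_frequency()` takes the largest peak above a noise floor of
median power + 6 dB and refines it with the power-weighted centroid of the
bins within ±25% of the peak — robust to the symmetric broadening that
phase diffusion produces, where 3-point interpolation is noisy.
`harmonic_match()` compares two spectra harmonic by harmonic; *clarity* is
peak power in dB over the local background (median power in the annulus
25–50% of the fundamental away from the harmonic).  A spectrum has *clear
harmonics* when its first harmonic ($2f_0$) clears 16 dB; the threshold is
configurable — "clear" is qualitative, and 16 dB is simply the midpoint of
the gap this package's own simulations produce between the synchronized
(≈22–26 dB) and uncoupled (≈7–12 dB) regimes at the preset noise level.

Raw trajectory distances between noisy and noise-free oscillators are
reported too (`trajectory_distance()`), but without phase re-alignment:
slow phase diffusion dominates raw distances at long horizons, which is
precisely why the frequency-domain comparison is the primary instrument.

## Experiment presets

`run_experiment()` packages seven self-contained designs
(`experiment_presets()` lists the defaults; every number below is a
default, overridable per call):

| preset | design | key output |
|---|---|---|
| `fig1_protection` | noise-free vs. noisy-uncoupled vs. noisy-synchronized FN unit (N=20, k=10, σ=0.5) | dominant-frequency match, harmonic clarity |
| `fig2_spatial_mean` | population mean of 20 uncoupled vs. synchronized units, shared initial conditions and noise | mean-readout amplitude and clarity |
| `fig3a_bound_sweep` | ergodic sync error vs. C over (N, k) ∈ {5,10}×{10,20} | empirical/bound ratios |
| `fig3b_observer_sweep` | observer distance of a synchronized unit vs. k | monotone decrease, reference bound |
| `fig4_probabilistic` | random symmetric network, N=30, p=0.3 | unit spectrum vs. noise-free |
| `fig5_hindmarsh_rose` | HR ensemble under a common step input | input tracking by the synchronized mean |
| `linear_sqrtN` | OU ensembles, N ∈ {1,4,16,64} | −0.5 slope, closed-form variance |

Scales are desk-scale: horizons of a few hundred time units, ensembles of
tens of units, chosen so each preset runs in well under two minutes on one
CPU; the manifests mark every run `scaled_down`, and each manifest (preset,
parameters, seed, config hash, package version) makes every number in the
outputs reproducible from the config alone.  Trajectories and summaries
serialize to plain CSV with JSON provenance — portable text formats that
diff and version cleanly.

What the synthetic data do **not** emulate: real neurons are not identical,
their noise is neither white nor purely additive, conduction introduces
delays, and gap junctions are not constant conductances.  Passing tests
demonstrate the mathematical mechanism — balance, contraction, averaging —
at its stated assumptions, not the physiology.

## Numerical choices and degenerate inputs

* Balance tolerance $10^{-9}$ absolute (floating-point row/column sums);
  self-loops are an error, not silently ignored.
* The eigenmode transform is refused (classed error) when its determinant
  $1 - 1/\kappa^2$ falls below $10^{-8}$ — outside the strong-coupling
  validity regime.
* `sync_bound_all_to_all()` returns `Inf` when $Nk \le c$ with $\sigma>0$
  (the fast-mode bound degenerates; the trivial bound is the honest
  answer) and exactly 0 when $\sigma = 0$.
* Spectra require ≥ 16 uniform samples; non-uniform grids are an error.
* `harmonic_match()` flags an undetectable fundamental as a `no_peak`
  result instead of erroring — absence of harmonics is a finding.

## Known limitations

The synchronization bound is asymptotic in the coupling: below
$\kappa \approx 10c$ the mode-splitting derivation degrades and only the
warning, not the math, tells you so.  The bound is stated for the FN preset
masks (noise and coupling on the voltage); other masks simulate fine but
are not covered by the bound.  Hindmarsh–Rose is simulated, never bounded.
The Euler–Maruyama scheme is first-order weak; statistics tied to bounds
must respect the $\kappa\,dt$ rule above, which the presets do for you.
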