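# oscnet

Simulation and analysis of **diffusively coupled networks of noisy
nonlinear oscillators**, built around one question from computational
neuroscience and systems biology: when identical units (neurons, cells)
operate under strong intrinsic noise, how does mutual gap-junction-like
coupling protect each unit — and their population mean — from that noise?

A single FitzHugh–Nagumo oscillator under strong white noise loses its
waveform and its spectral harmonics, and the average of many *independent*
noisy oscillators carries almost no signal: the noise averages out, but so
does the oscillation.  When the same units are coupled and synchronize,
each one behaves like a noise-free oscillator again.  `oscnet` simulates
this collective enhancement of precision, computes the
stochastic-contraction bounds that quantify it, and ships the diagnostics
that certify it.

## What it computes

For the network
$dx_i = [f(x_i,t) + u(t)e_{\mathrm{in}} + \sum_j w_{ij}(x_j - x_i)]\,dt + \sigma\,dW_i$:

* **Models** — FitzHugh–Nagumo ($\dot v = c(v+w-v^3/3)+I$,
  $\dot w = -(v-a+bw)/c$), Hindmarsh–Rose (3-D spiking/bursting),
  time-varying linear systems, and user-supplied drifts; curvature bounds
  `Q` via `hessian_bound()`.
* **Networks** — all-to-all, probabilistic symmetric, arbitrary weighted
  graphs; balance checks (incoming = outgoing weight per node); the
  quorum-sensing star reformulation of all-to-all coupling
  (`to_quorum_star()`, `N` connections instead of `N²`, identical dynamics
  to 1e-10).
* **Simulation** — seeded, bitwise-reproducible Euler–Maruyama
  (`euler_maruyama()`), noise-free references, reproducible noise streams
  for matched-noise designs.
* **Bounds** — the stationary bound on the ordered-pair synchronization
  error for all-to-all FN networks,
  $\sum_{i,j} E\|x_i-x_j\|^2 \le N(N-1)\sigma^2[ (Nk-c)^{-1} + (b c (Nk)^2)^{-1}]$,
  its two-oscillator building block, the eigenmode transform behind it,
  the Taylor-remainder bound on the mean drift distortion, and the
  mean-impact bound $QC/(4N^2) + \sigma/\sqrt N$.
* **Observer** — a model-based nonlinear state estimator driven by the
  measured voltage; its squared distance certifies how close a noisy unit
  is to noise-free behavior.
* **Analysis** — ergodic synchronization error (with the exact
  pairwise/center-of-mass identity asserted), population-mean series, FFT
  power spectra, dominant-frequency and harmonic-clarity comparison,
  trajectory distances.
* **Experiments** — seven config-driven presets (`run_experiment()`)
  covering unit protection, population-mean readout, bound sweeps,
  observer sweeps, probabilistic networks, Hindmarsh–Rose step tracking,
  and the linear $1/\sqrt N$ law, each with a reproducibility manifest.

Everything user-facing takes/returns tibbles and composes with the pipe;
results have `tidy()`, `glance()` and `autoplot()` methods.  A thin CLI
(`inst/exec/oscnet`) wraps simulation, bound sweeps, experiments and the
observer.

## Worked example

```r
library(oscnet)

r <- run_experiment("fig1_protection", seed = 1)
as.data.frame(r$summary)
#>    n  k sigma period_free     f_free   f_sync f_uncoupled rel_freq_diff_sync
#> 1 20 10   0.5     10.3694 0.09665026 0.097014  0.09792012        0.003763462
#>   clarity_sync clarity_uncoupled harmonics_clear_sync harmonics_clear_uncoupled
#> 1     23.08122          10.13446                 TRUE                     FALSE
```

Reading: the noise-free FN preset oscillates with period 10.37 (dominant
frequency 0.0967 cycles/time).  A unit inside the synchronized 20-oscillator
network at noise σ = 0.5 keeps that frequency to 0.38% and shows clear
harmonics (mean clarity 23 dB over background).  The *same* unit uncoupled,
at the same noise, drifts off frequency and fails the clear-harmonics
criterion (10 dB, first harmonic buried).  `autoplot()` on the stored
spectra/trajectories draws the corresponding panels.

The theoretical side of the story:

```r
b <- sync_bound_all_to_all(n = 10, k = 10, sigma = 0.5)
b$bound_value        # 0.2328963  — bound on sum_{i,j} E||x_i - x_j||^2
tidy(b)              # one-row tibble with inputs and transient rate

suppressWarnings(run_experiment("fig3a_bound_sweep", seed = 1))$summary
#>    n  k sigma empirical_C    bound_C ... ratio
#> 1  5 10   0.5  0.09739179 0.10721631 ... 0.9083673
#> 2 10 10   0.5  0.22158671 0.23289626 ... 0.9514395
#> 3  5 20   0.5  0.04997903 0.05175473 ... 0.9656902
#> 4 10 20   0.5  0.11228506 0.11444757 ... 0.9811048
```

The ergodic synchronization error stays below the bound at every grid
point, and both fall with coupling strength.

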