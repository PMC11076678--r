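---
title: "An amyloid-coupled thalamocortical model of alpha-rhythm slowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An amyloid-coupled thalamocortical model of alpha-rhythm slowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalabeta)
```

## The model

Slowing of the EEG alpha rhythm (8–13 Hz) — a drop in alpha peak power and
dominant frequency — is a well-established electrophysiological marker of
Alzheimer's disease. One candidate mechanism is amyloid-beta neurotoxicity in
the inhibitory thalamic reticular nucleus (TRN): by impairing inhibitory
synaptic kinetics, amyloid deposition disinhibits the thalamic relay nucleus
(TCR) and degrades the thalamocortical alpha oscillation. `thalabeta`
implements a minimal neural-mass realization of this hypothesis and the
spectral analysis used to read it out.

The circuit has three populations, each a critically damped second-order
synaptic kernel with a sigmoidal potential-to-rate conversion:

* a **retinal input stage**, driven by the exogenous sensory process $P(t)$;
* the excitatory **TCR**, driven by $S(C_3 x_{ret} - C_2 x_{trn})$ —
  retinal excitation minus TRN inhibition;
* the inhibitory **TRN**, driven by $S(C_1 x_{tcr})$ — the excitatory
  feedback from TCR.

In state-space form, with each population carrying a potential $x_1$ (mV)
and its derivative $x_2$:

$$
\dot x_1 = x_2,\qquad
\dot x_2 = \frac{H}{\tau}\,u(t) - \frac{2}{\tau} x_2 - \frac{1}{\tau^2} x_1,
$$

where $u(t)$ is the population's input rate, $H$ the postsynaptic gain
($H_e$ = 3.25 mV excitatory, $H_i$ = 22 mV inhibitory) and $\tau$ the
synaptic time constant ($\tau_e$ = 10 ms excitatory; $\tau_i$ inhibitory,
set by the amyloid mapping below). The firing-rate sigmoid is

$$
S(v) = \frac{2 e_0}{1 + e^{-\nu (v - s_0)}},
$$

with $e_0$ = 25 s$^{-1}$, slope $\nu$ = 0.56 mV$^{-1}$ and threshold $s_0$ =
6 mV. The model output — the simulated EEG-like signal — is the net input
potential of the relay nucleus,

$$
V = C_3\, x_{ret} - C_2\, x_{trn},
$$

with connectivity gains $C_1$ = 35, $C_2$ = 15, $C_3$ = 7. The exogenous
drive $P(t)$ is Gaussian white noise with mean $\mu_r \in [0, 100]$
spikes/s (86 by default, the operating point of all experiments) and
variance $\phi_r$ = 1.

One deliberate reading is worth flagging: the TRN input is written here as
the excitatory TCR feedback $S(C_1 x_{tcr})$, which is what the circuit
description states ($C_1$ is the relay-to-reticular connection). A literal
self-input variant $S(C_1 x_{trn})$ is also available
(`model_parameters(trn_input = "trn_self")`) for comparison. Parameter
units follow standard neural-mass conventions (gains in mV, time constants
in ms, sigmoid slope in mV$^{-1}$); time constants are converted to seconds
once, inside the right-hand side, so configuration values stay in their
conventional units.

## The amyloid mapping

Amyloid load enters as a single scalar $\beta_a$, a PET-derived standardized
uptake value ratio (SUVR). It sets the TRN inhibitory time constant through
a calibrated decreasing sigmoid:

$$
S_1(\beta_a) = S_{min} + \frac{S_{max} - S_{min}}
  {1 + e^{\,r_{\beta}\,(\beta_a - \beta_0)}},\qquad
\tau_i(\beta_a) = \frac{1}{S_1(\beta_a)},
$$

with slope and midpoint derived from two clinical anchors — the cutoff
$\beta_{off}$ = 1.4 separating normal from pathological load, and the
population maximum $\beta_{max}$ = 2.65:

$$
r_{\beta} = \frac{2 \ln S_{max}}{\beta_{off} - \beta_{max}},\qquad
\beta_0 = \frac{\beta_{off} + \beta_{max}}{2}.
$$

With $S_{max}$ = 0.07 and $S_{min}$ = 0.02 this gives $r_\beta \approx
4.2548$ and $\beta_0 = 2.025$, and $\tau_i$ spans $[1/S_{max}, 1/S_{min}] =
[14.29, 50]$ ms. Below the clinical cutoff the time constant is clamped at
its amyloid-free value 14.29 ms (sub-cutoff loads are treated as "no
pathology"); the clamp introduces a small jump at the cutoff (about 0.7 ms
with the default calibration), which the test suite measures explicitly.
$S_1^{-1}$ is read as the multiplicative reciprocal, not a functional
inverse: that is the only reading under which the stated $\tau_i$ range
equals $[1/S_{max}, 1/S_{min}]$. Likewise the printed form of $S_1$ is
typographically ambiguous; the implementation uses the unique decreasing
sigmoid that ranges over $(S_{min}, S_{max})$ and passes through
$(S_{max}+S_{min})/2$ at the midpoint.

```{r mapping}
cal <- abeta_calibration()
cal
tau_inhibitory(c(0.5, 1.92, 2.10, 2.65, 5.0), cal)
severity_band(c(0.5, 1.92, 2.10, 2.65, 5.0))
```

The severity banding (normal / moderate / moderate-severe / severe at 1.4,
1.95 and 2.15 SUVR) is reported as stated clinically. Note the calibrated
curve reaches $\tau_i$ = 28 ms slightly above 2.15 (near $\beta_a \approx
2.21$); the package reports the computed curve and does not force agreement
at the band edge.

## Numerics

**Integrator.** The reference integrator is fixed-step classical RK4 at
`dt` = 1 ms, written in C++. White noise is made compatible with
deterministic stepping by a zero-order hold: each step's drive value is
drawn once and held for all four stage evaluations of that step. This makes
runs exactly reproducible and makes step-refinement well-posed (halving
`dt` with the noise still held on the 1 ms grid changes post-transient
traces by well under 1% relative RMS — asserted in the tests). An adaptive
Runge–Kutta 4(5) mode over the same held noise
(`integrate_model(method = "rk45")`, via `deSolve`) is provided for
comparison with adaptive-solver practice; an adaptive solver applied to raw
white noise is not a convergent stochastic scheme, which is why it is not
the reference.

**Protocol.** 30 s of simulated time per run; 20 independent noise
realizations ("repeats"), repeat $i$ seeded with `seed + i`; the first 2 s
discarded as transient; initial state zero. Duration and repeat count are
the study protocol; step size, transient and initial state are this
package's choices (the protocol does not state them) and are all
configurable in `simulation_config()`. Integration failure (any state
exceeding 10^6 in magnitude) raises an error naming the time and repeat;
across the entire experimental envelope ($\beta_a \in [0,5]$, $C_1 \in
[0,100]$, $\mu_r \in [0,100]$) no divergence occurs.

**Spectra.** Each repeat's trace is band-pass filtered with a zero-phase
(forward–backward) order-4 Butterworth, passband 1–40 Hz — wide enough not
to distort the alpha peak; a narrow 8–13 Hz reading can be reproduced via
`spectral_config(band_low = 8, band_high = 13)` or the CLI's `--band 8:13`.
The PSD is a Welch averaged periodogram: 4-s Hann segments at 50% overlap
(0.25 Hz resolution on the 28-s post-transient record), per-segment mean
removal, one-sided density scaling. None of these analysis constants are
stated by the protocol; they are standard EEG practice and all live in
`spectral_config()`. Per-repeat PSDs are averaged across repeats — the
phrase "the average was taken" is ambiguous between averaging traces and
averaging spectra, and averaging traces of incoherent noise-driven
oscillations would cancel the rhythm, so spectrum averaging is the headline
pipeline (the trace average is still retained in the simulation result).

**Summaries.** "Peak power" is the maximum PSD value on the closed 8–13 Hz
band (not the integrated band power); "dominant frequency" is its argmax,
with ties broken toward the lower frequency; sub-band powers are
trapezoidal integrals over the five 1-Hz bins 8–9 … 12–13 Hz, with band
edges interpolated onto the frequency grid so the bins tile the alpha band
exactly. Both the peak reading and the integrated sub-band powers are
reported so either convention is available.

## What the experiments show

```{r pipeline}
p <- model_parameters(tau_i = tau_inhibitory(0.001))  # amyloid-free
cfg <- simulation_config(duration = 10, n_repeats = 5, seed = 1)
sm <- analyze_simulation(run_repeats(p, cfg))
sm
```

At the healthy operating point the circuit's TCR–TRN negative-feedback loop
resonates at about 10–11 Hz — inside the alpha band, which is the premise
of the whole exercise. The three sweep drivers then vary one axis each,
holding the rest at the moderate-to-severe operating point ($\beta_a$ =
2.10, $C_1$ = 35, $\mu_r$ = 86); every grid point reuses the same base seed
(common random numbers), so curves reflect the swept parameter rather than
noise re-draws.

```{r sweep, eval = FALSE}
sw <- sweep_beta(grid = c(0.001, 1.92, 2.10, 3.00),
                 sim_config = simulation_config(seed = 1))
sw$table[, c("value", "tau_i_ms", "peak_power", "dominant_freq")]
plot(sw, "psd")
```

* **Amyloid load** ($\beta_a$ from 1.4 to 5.0): alpha peak power falls
  monotonically and then plateaus once $\tau_i$ saturates near 50 ms; the
  dominant frequency does not increase, and at severe loads the spectral
  mass moves below the alpha band. Because $\tau_i(\beta_a)$ is the only
  coupling, sweeping $\tau_i$ directly over [14.29, 50] ms reproduces the
  same curve — asserted in the tests.
* **Connectivity** ($C_1$ upward from 35 at $\beta_a$ = 2.10): stronger
  excitatory afferents to the inhibitory TRN raise alpha peak power —
  partially compensating the amyloid-induced disinhibition.
* **Sensory drive** ($\mu_r$ upward from 86 at $\beta_a$ = 2.10): stronger
  drive raises alpha peak power.

The acceptance tests assert these as rank-correlation trends of the
repeat-averaged summaries across grid points (Spearman $\rho$ strictly
negative for the load sweep at every tested $\mu_r \in \{70, 80, 90,
100\}$, positive for the other two), not as pointwise curve values: the
trends, not absolute PSD magnitudes, are the reproducible claims. Test
problem sizes: the trend assertions run the full 30-s, 20-repeat protocol
(the load sweep over all 19 grid points times four drive means completes in
well under a minute thanks to the compiled core); unit tests use shorter
4–8 s horizons, which already expose every contract.

## What the synthetic data are — and are not

All "data" in this package are generated by the model itself: seeded
Gaussian-white-noise realizations pushed through the circuit. That is
faithful to the study design, which fits no empirical recordings. It also
bounds what passing tests demonstrate: the model reproduces the
*direction* of AD-associated alpha changes under its own assumptions; it
says nothing about fits to real patient EEG, about amyloid biology beyond
the single scalar load, nor about tau pathology, neuroinflammation or
oxidative stress, all of which are outside this model. Real EEG features
the model does not emulate include 1/f background structure, artifacts,
non-stationarity and inter-subject variability.

## Degenerate inputs and edge behaviour

* $\phi_r = 0$ removes all stochasticity: repeats become identical and
  seed-independent (at $\mu_r = 86$ the deterministic system settles on a
  limit cycle; with zero drive it relaxes to its unique fixed point, which
  the tests locate independently by root-finding on the nullclines).
* $C_1 = 0$ disconnects the TRN from the relay feedback; the simulation
  still completes.
* Loads below the cutoff all map to exactly 14.29 ms, so sub-cutoff spot
  values (e.g. the 0.001 used as a "no pathology" placeholder) are
  equivalent.
* Two equal PSD maxima report the lower frequency; a PSD shorter than one
  Welch segment, an alpha band outside the frequency grid, or a passband
  infeasible at the sampling rate raise immediate configuration errors.

## Limitations

The cortical module of antecedent thalamocortical models is intentionally
absent — the equations here contain only the retina/TCR/TRN loop, so the
output is a thalamic, not cortical, surrogate of EEG. The amyloid effect is
a single scalar acting on one time constant; regional heterogeneity and
dynamics of deposition are out of scope. The half-maximum rate $e_0$ = 25
s$^{-1}$ is kept as specified even though related neural-mass literature
often uses 2.5 s$^{-1}$; it is a configuration value, not a hard-coded
constant. The clamp at the clinical cutoff makes $\tau_i(\beta_a)$
discontinuous by design; analyses that need smoothness should evaluate the
sigmoid branch directly via `abeta_transfer()`.
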