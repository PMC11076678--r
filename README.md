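# thalabeta

Neural-mass modelling of amyloid-driven alpha-rhythm slowing.

Slowing of the EEG alpha rhythm (8–13 Hz) is a hallmark electrophysiological
change in Alzheimer's disease. `thalabeta` is for computational
neuroscientists who want a small, fully reproducible model of one candidate
mechanism: amyloid-beta neurotoxicity in the inhibitory thalamic reticular
nucleus (TRN). The package couples a three-population thalamocortical
neural-mass circuit to a scalar amyloid load and provides the EEG-style
spectral pipeline and parameter-sweep experiments that demonstrate the
resulting alpha slowing.

## The model

Three critically damped second-order populations — a retinal input stage,
the excitatory thalamic relay nucleus (TCR) and the inhibitory TRN — each
follow

$$\dot x_1 = x_2,\qquad \dot x_2 = \tfrac{H}{\tau}u(t) - \tfrac{2}{\tau}x_2 - \tfrac{1}{\tau^2}x_1,$$

with a logistic potential-to-rate conversion
$S(v) = 2e_0/(1+e^{-\nu(v-s_0)})$. The retina receives Gaussian white noise
$P(t)\sim\mathcal N(\mu_r,\phi_r)$; TCR receives $S(C_3 x_{ret} - C_2
x_{trn})$; TRN receives $S(C_1 x_{tcr})$. The simulated EEG-like output is
$V = C_3 x_{ret} - C_2 x_{trn}$.

Amyloid load $\beta_a$ (a PET SUVR scalar) lengthens the TRN inhibitory time
constant through a calibrated decreasing sigmoid:

$$\tau_i(\beta_a) = \frac{1}{S_1(\beta_a)},\qquad
S_1(\beta_a) = S_{min} + \frac{S_{max}-S_{min}}{1+e^{r_\beta(\beta_a-\beta_0)}},$$

with $r_\beta = 2\ln S_{max}/(\beta_{off}-\beta_{max})$ and $\beta_0 =
(\beta_{off}+\beta_{max})/2$. With the default anchors
($\beta_{off}=1.4$, $\beta_{max}=2.65$, $S_{max}=0.07$, $S_{min}=0.02$),
$\tau_i$ runs from 14.29 ms (amyloid-free; clamped below the clinical
cutoff 1.4) to 50 ms at saturating load. Simulated output is analysed with
a zero-phase order-4 Butterworth band-pass (1–40 Hz) and a Welch PSD
(4-s Hann segments, 50% overlap), averaged over 20 seeded noise
realizations, then summarized over the alpha band (peak power, dominant
frequency, 1-Hz sub-band powers).

## Worked example

Map four amyloid loads to inhibitory time constants, run the full
20-repeat, 30-s protocol at each, and summarize the alpha band:

```r
library(thalabeta)

tau_inhibitory(c(0.001, 1.92, 2.10, 3.00))
#> [1] 14.28571 19.80458 24.36373 48.12974

sw <- sweep_beta(grid = c(0.001, 1.92, 2.10, 3.00),
                 sim_config = simulation_config(seed = 1))
sw
#> Parameter sweep over beta_a (4 points)
#>   fixed: C1 = 35, mu_r = 86
#>  value tau_i_ms peak_power dominant_freq alpha_power
#>  0.001    14.29  9.680e+02         10.75   3.672e+02
#>  1.920    19.80  1.002e+02         10.00   3.863e+01
#>  2.100    24.36  4.325e+00         10.00   1.705e+00
#>  3.000    48.13  7.667e-05          8.00   2.635e-04
```

Reading the table: at negligible load the loop resonates at 10.75 Hz with
alpha peak power ~968 mV²/Hz. As load rises through moderate (1.92) and
moderate-severe (2.10) to severe (3.00), the inhibitory time constant
lengthens from 14.3 ms towards 50 ms and the alpha peak collapses by seven
orders of magnitude while the dominant frequency drifts down to the band's
lower edge — alpha slowing. `plot(sw, "psd")` overlays the four spectra;
`plot(sw, "subbands")` shows the per-1-Hz-band powers. `sweep_c1()` and
`sweep_mu()` run the companion experiments (raising TCR→TRN connectivity or
sensory drive at fixed pathological load raises alpha peak power), and
`severity_band()` labels loads with their clinical band.

A thin command-line front end over the same functions ships in
`inst/cli/thalabeta.R`:

```sh
Rscript inst/cli/thalabeta.R map-tau --grid 0:5:0.1
Rscript inst/cli/thalabeta.R simulate --beta 2.1 --seed 1 --out run
Rscript inst/cli/thalabeta.R analyze --timeseries run_timeseries.csv --out run
Rscript inst/cli/thalabeta.R sweep-beta --mu 86 --out fig1
```

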