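---
title: "A two-compartment model of inhibitory veto in LSO neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-compartment model of inhibitory veto in LSO neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsoveto)
```

## The scientific problem

Principal neurons of the lateral superior olive (LSO) compare excitation
driven by the ipsilateral ear against glycinergic inhibition relayed from the
contralateral ear.  For impulsive sounds (clicks), this comparison is
extraordinarily sharp in time: over a sub-millisecond range of interaural
time differences (ITDs) the inhibitory volley completely vetoes spiking,
producing deep, narrow, steep-flanked U-shaped ITD tuning.  Conductance-clamp
experiments show that inhibition delivered at the soma alone cannot reproduce
this veto, while anatomy shows glycinergic terminals directly on the axon
initial segment (AIS).  `lsoveto` implements a minimal biophysical model of
this arrangement — a soma compartment and an AIS compartment — to ask
quantitatively how much inhibitory efficacy is gained by placing a few
synapses on the AIS, together with the analysis statistics used to
characterize click-evoked ITD tuning in recorded and simulated data.

## The model

### Passive skeleton from coupling constants

Both compartments are single RC nodes joined by an axial conductance
$g_{ax}$:

$$c_1 U_1' = -g_1 U_1 - g_{ax}(U_1 - U_2) - I_{syn,1},\qquad
\alpha c_1 U_2' = -g_2 U_2 - g_{ax}(U_2 - U_1) - I_{ion} - I_{syn,2}$$

with $U_i$ the deviations from rest ($E_{rest} = -60$ mV) and
$\alpha = 0.12$ the AIS/soma membrane-area ratio, derived from a prolate
spheroid soma of 20.4 × 9.5 µm and a cylindrical AIS of 20 × 1 µm
(`ais_soma_area_ratio()`).

Rather than guessing conductances, the passive skeleton is parameterized by
the steady-state voltage attenuation factors between the compartments, the
*coupling constants* $\kappa_{1\to2} = g_{ax}/(g_{ax}+g_2)$ (soma→AIS) and
$\kappa_{2\to1} = g_{ax}/(g_{ax}+g_1)$ (AIS→soma).  Given
$(\kappa_{1\to2}, \kappa_{2\to1})$ and the soma input resistance
$R_1 = 40\,\mathrm{M\Omega}$, the three conductances are uniquely determined
(`passive_from_coupling()`).  The transfer resistance obeys the exact
identity $R_{12} = R_1\kappa_{1\to2} = R_2\kappa_{2\to1}$, which is also the
heart of the mechanistic argument: a somatic inhibitory input influences the
AIS in proportion to $R_1\kappa_{1\to2}$, an AIS input in proportion to
$R_2$, and since $\kappa_{2\to1} < 1$ always, $R_2 > R_1\kappa_{1\to2}$ —
AIS-targeting inhibition is always the more efficient lever.  For the
default configuration $(\kappa_{1\to2}, \kappa_{2\to1}) = (0.95, 0.6)$ the
identity gives $R_2 = R_1\kappa_{1\to2}/\kappa_{2\to1} = 63.33$ MΩ; the
package always derives $R_2$ from the identity rather than fixing a rounded
value.

The passive model decays on two time scales, and with $\alpha = 0.12$ no
separation-of-time-scales reduction applies.  The effective soma capacitance
$c_1$ is therefore *fitted*: starting from the steady-state holding profile
$U(0) = (1, \kappa_{1\to2})$, `fit_effective_capacitance()` minimizes
$E(c_1) = \int_0^{10\,\mathrm{ms}} (e^{-t/\tau_m} - U_1(t))^2\,dt$ with
$\tau_m = 1$ ms, using golden-section search on a log-spaced bracket with
composite-Simpson quadrature at 1 µs resolution.  The match is approximate
by construction; the test suite asserts an RMS deviation below 0.05 on the
unit scale over $[0, 5\tau_m]$.

### Spike generation and its calibration

Sodium and high-threshold potassium currents sit in the AIS compartment.
The rate functions are a pluggable set; the default
(`kinetics_id = "rm03_m3h_n2"`) uses standard auditory-brainstem
$m^3h$ sodium and $n^2$ high-threshold potassium gating of the
Rothman–Manis type.  The binding contract of the kinetics is behavioral,
not kinetic, and consists of three anchors measured on the calibrated model:

* spike threshold corresponds to a just-subthreshold soma EPSP of about
  10 mV (`calibrate_gna()` adjusts $g_{Na}$ by bisection; the threshold
  drive itself is found by an inner bisection on a continuously scaled
  excitatory conductance);
* $g_{KHT} = 0.1\, g_{Na}$ exactly;
* the backpropagated action potential measured at the soma is ≈30 mV above
  rest at $\kappa_{2\to1} = 0.6$ (which is why that backward coupling is the
  default).

The temperature scale factor ($q = 6$) and sodium reversal
($E_{Na} = 40$ mV) of the default rate set were fixed once so that all
three anchors — and the companion anchor that all-somatic inhibition yields
only modest tuning (minimum spike probability ≈ 0.5, see below) — hold
simultaneously; they are not per-configuration tuning knobs, and the same
rate set is used across the entire backward-coupling sweep.  One numerical
subtlety: exactly at the spike-threshold drive the trajectory can ride the
unstable manifold and produce an inflated graded response, so the
just-subthreshold EPSP is measured 1% below the threshold drive.  At very
large $g_{Na}$ the rest state destabilizes; that limit is treated as a
threshold EPSP of zero, which keeps the outer bisection well-posed.

### Synaptic inputs

Each population consists of identical, perfectly synchronized unitary
conductances (click-evoked volleys are modeled as a single fixed activation
time per population; no jitter).  Unitary kernels are peak-normalized double
exponentials; the `default_invitro` preset uses 0.1/0.18 ms, 2.3 nS for the
20 excitatory inputs and 0.45/2.0 ms, 3.1 nS for the 8 inhibitory inputs,
with activation probabilities 0.84 and 0.92.  A faster `mature_invivo`
preset (0.25/0.4 ms, 1.6 nS, p = 0.82 excitatory; 0.35/0.7 ms, 3.9 nS,
p = 0.92 inhibitory) is shipped as a named configuration.  The inhibitory
probability of 0.92 is the value at which the simulated inhibition-only
soma IPSP statistics land at the in vivo reference (mean ≈ −6.35 mV,
variance ≈ 0.184 mV²), which `ipsp_statistics()` verifies by Monte Carlo.

Inside the model, positive ITD means inhibition leads excitation.  In vivo
conventions instead quote positive ITD when the contralateral (inhibitory-
ear) click leads; for an LSO neuron the two conventions coincide in sign.

### Semi-analytic spike probability

Given the deterministic dynamics, randomness enters only through the
binomial numbers of active inputs.  `build_indicator()` simulates every
combination of active counts once at a given ITD, and
`spike_probability()` weights the binary outcomes by the product of
binomial point masses:

$$P(\mathrm{spike}\mid\mathrm{ITD}) = \sum_{n_E}\sum_{n_{I}}
\mathbf{1}(n_E, n_I, \mathrm{ITD})\,P(b_{N_E,p_E} = n_E)\,
P(b_{N_I,p_I} = n_I).$$

For mixed soma/AIS arrangements the inhibitory sum becomes a double sum
over independent per-compartment binomials, since each synapse is activated
independently.  The Monte-Carlo estimator (`simulate()` on the model) has
exactly this expectation and serves as the sampling cross-check.

## The headline experiment

```{r, eval = FALSE}
m <- lso_model()                      # builds + calibrates; ~2 s
curves <- predict(m, arrangement = c("8+0", "6+2", "0+2"))
plot(curves)
tapply(curves$p_spike, curves$arrangement, min)
#>        0+2        6+2        8+0
#> 0.92605338 0.04345662 0.50330900
```

With all eight inhibitory synapses on the soma the tuning trough only
reaches ≈0.5 — the modest tuning seen with somatic conductance clamp.
Moving just two synapses to the AIS (`"6+2"`) deepens the minimum to
≈0.04, while two AIS synapses alone (`"0+2"`) barely tune at all: the veto
needs both the somatic mass of inhibition and the strategically placed AIS
contingent.  `arrangement_sweep()` repeats this comparison across backward
couplings 0.3–0.9 (recalibrating $g_{Na}$ at each), and the `"6+2"` minimum
never exceeds the `"8+0"` minimum anywhere in that range.

## Analysis statistics

The `metrics` functions operate on plain data frames and mirror standard
practice for click-ITD data:

* `hanning3_smooth()` — normalized [0.25, 0.5, 0.25] smoothing with
  truncated, renormalized endpoints (flat curves are preserved exactly);
  applied before halfwidth/slope measurement.
* `halfwidth()` — ITD span over which the response is suppressed (LSO
  trough) or enhanced (MSO peak) by ≥50% of the curve maximum; crossings by
  linear interpolation (a 0.1 ms grid is too coarse for nearest-sample
  crossings when halfwidths are a few hundred µs).
* `slopes_20_80()` — signed chord slopes between the 20% and 80% crossings
  on each flank; a side is undefined when its threshold is not reached.
* `itd_snr()` — ITD-related variance over total variance of spike counts,
  0 for untuned and 1 for perfectly reliable tuning; requires ≥10
  repetitions by default, and supports ragged tables by per-condition
  weighting on explicit request.
* `summation_ratio()` — median-across-levels monaural/binaural rate ratio
  (LSO orientation) or its inverse (MSO); both ≫1 under strong binaural
  interaction.
* `psp_latency()` — first crossing of 20% of the reference IPSP amplitude
  in the required direction, interpolated.
* `theta_effect_size()` — Mann-Whitney U over the product of sample sizes,
  ties counted ½ (so identical samples give exactly 0.5).
* `cue_map()` / `cue_region()` — combined ITD/IID coordinates with the
  0.05 ms/dB equivalence scale and nearest-site (Voronoi) region
  assignment; distance ties break to the lower site index.
* `cell_average()` — one value per cell before population statistics.

## The synthetic-recording generator

`synth_spec()` + `gen_trial_table()` emulate click-ITD trial tables:
a U-shaped (or, for MSO, peaked) mean-response profile built from two
logistic flanks, parameterized directly by center, halfwidth, floor,
ceiling, and per-flank steepness via closed-form inversion — so the
generative halfwidth, chord slopes, and large-sample ITD-SNR
($\sigma^2_{ITD} / (\sigma^2_{ITD} + \overline{p(1-p)})$ for Bernoulli
spiking) are known exactly (`profile_truth()`).  Principal-LSO tables are
Bernoulli per trial (these cells fire at most one well-timed spike per
click); non-principal and MSO tables draw truncated-Poisson counts so that
doublets occur.  `gen_rate_level()` constructs rate-level functions whose
summation ratio is exact by design, and `gen_psp_trace()` produces
double-exponential PSPs whose onset latency declines at a configurable
10–20 µs/dB with white membrane noise.  All generators derive
per-operation RNG streams from the master seed (`derive_seed()`), so
results do not depend on call order.

What the generator does *not* emulate: adaptation across trials, latency
jitter correlated with amplitude, acoustic crosstalk at high levels, or any
cochlear front-end.  Passing recovery tests therefore demonstrate that the
analysis chain is correct and unbiased on its idealized data model, not
that it is robust to every pathology of real recordings.

## Numerical choices

* Integration: exponential Euler per compartment with fixed
  `dt = 0.002 ms`; gating variables relax analytically toward tabulated
  steady states (0.05 mV lookup tables built per call).  Halving `dt`
  changes peak soma voltage by <0.05 mV and never changes a spike outcome
  in the test suite.
* Spike criterion: first upward crossing of the AIS voltage through
  −20 mV absolute (+40 mV relative to rest), matching the reversal
  potentials' absolute frame.
* Simulations run for 10 ms with stimulus onset buffered at 2 ms, so the
  full ±2 ms ITD range and the slow inhibitory decay fit comfortably.
* Enumeration cost: a tuning curve on the default 0.05 ms grid requires
  21 × 9 × 81 ≈ 15k trial simulations for the all-somatic arrangement
  (about half a minute); the backward-coupling sweep uses a 0.1 ms grid,
  which changes none of the orderings.
* Problem sizes in the shipped tests (500-trial recovery tables, 10⁴
  Monte-Carlo draws, 7-point coupling sweep) are the package's chosen
  desk-scale defaults.

## Known limitations

* The printed AIS input resistance of the reference configuration is
  reported rounded (64 MΩ); the package derives 63.33 MΩ from the exact
  transfer-resistance identity and treats that as authoritative.
* Exact Na/KHT rate functions for the gerbil LSO AIS are not published at
  this level of reduction; any rate set satisfying the behavioral anchors
  is admissible, and absolute $g_{Na}$ values are therefore
  implementation outputs, not biological estimates.
* The model varies only relative PSP timing; intensity-difference effects
  on conductance amplitudes (and hence combined ITD/IID tuning of the
  model cell) are outside its scope — the cue-map tooling applies to
  recorded data instead.
* Synaptic depression, facilitation, stochastic channel gating, and
  temperature dependence are not modeled.
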