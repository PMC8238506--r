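# lsoveto

A two-compartment, conductance-based model of a lateral superior olive
(LSO) principal neuron — soma plus axon initial segment (AIS) — built to
quantify how strategically placed glycinergic synapses on the AIS let the
contralateral ear *veto* the output of the ipsilateral ear within a
sub-millisecond window, together with the analysis statistics used to
characterize click-evoked interaural-time-difference (ITD) tuning.  It is
aimed at auditory-brainstem and computational neuroscientists who want a
tested, scriptable reimplementation of this circuit model and its tuning
metrics.

## The model in brief

Soma (1) and AIS (2) are RC nodes coupled by an axial conductance:

    c1·U1' = −g1·U1 − gax·(U1 − U2) − Isyn,1
    α·c1·U2' = −g2·U2 − gax·(U2 − U1) − Iion − Isyn,2

The passive skeleton is parameterized by the steady-state coupling
constants κ1→2 = gax/(gax+g2), κ2→1 = gax/(gax+g1) and the soma input
resistance R1 = 40 MΩ, inverted uniquely to (g1, g2, gax).  The transfer
resistance obeys R12 = R1·κ1→2 = R2·κ2→1, so AIS-targeting inhibition is
always more effective than soma-targeting inhibition (R2 > R1·κ1→2 since
κ2→1 < 1).  The effective soma capacitance c1 is fitted so the soma decay
approximates exp(−t/τm) with τm = 1 ms; the AIS/soma area ratio α = 0.12
follows from a 20.4 × 9.5 µm spheroidal soma and a 20 × 1 µm cylindrical
AIS.  Spike-generating m³h sodium and n² high-threshold potassium currents
sit in the AIS; g_Na is calibrated so spike threshold corresponds to a
~10 mV soma EPSP, with g_KHT = 0.1·g_Na.

Synaptic input is 20 excitatory (0.1/0.18 ms, 2.3 nS, p = 0.84) and 8
inhibitory (0.45/2.0 ms, 3.1 nS, p = 0.92) synchronized unitary double
exponentials; inhibition is split between soma and AIS by arrangement
("8+0", "6+2", "0+2").  Because the dynamics are deterministic, the spike
probability at an ITD is computed semi-analytically by enumerating all
active-count combinations and weighting with binomial masses:

    P(spike | ITD) = Σ_nE Σ_nI 1(nE, nI, ITD) · P(B(NE,pE)=nE) · P(B(NI,pI)=nI)

## Worked example

```r
library(lsoveto)

m <- lso_model()        # build + calibrate the default (κ = 0.95/0.6) model
m
#> Two-compartment LSO neuron model (soma + AIS)
#>   coupling: kappa_fwd = 0.95, kappa_bwd = 0.60; R1 = 40 MOhm, R2 = 63.33 MOhm
#>   passive: tau_m = 1 ms, alpha = 0.12, c1 = 0.0226 nF
#>   currents: g_Na = 1.1620 uS, g_KHT = 0.1162 uS (rm03_m3h_n2)
#>   synapses (default_invitro): 20E (2.3 nS, p=0.84), 8I (3.1 nS, p=0.92)
#>   calibrated: threshold EPSP = 10.00 mV

curves <- predict(m, arrangement = c("8+0", "6+2", "0+2"))
tapply(curves$p_spike, curves$arrangement, min)
#>        0+2        6+2        8+0
#> 0.92605338 0.04345662 0.50330900
```

With all eight inhibitory synapses on the soma, the ITD tuning trough only
dips to ≈0.5 spikes/click — the shallow tuning seen when inhibition is
delivered by somatic conductance clamp.  Relocating two synapses to the
AIS ("6+2") deepens the trough to ≈0.04 (a near-complete veto), while two
AIS synapses alone ("0+2") barely tune: the veto requires both somatic and
AIS-targeting inhibition.  Inhibition-only Monte-Carlo trials reproduce
the in vivo IPSP statistics:

```r
st <- ipsp_statistics(m, n_trials = 10000, seed = 1)
c(mean = st$mean, variance = st$variance)
#>       mean   variance
#> -6.3703626  0.1870942   # mV, mV^2
```

Analysis statistics (`itd_snr`, `halfwidth`, `slopes_20_80`,
`summation_ratio`, `psp_latency`, `theta_effect_size`, `cue_map`) operate
on plain data frames; `synth_spec()` + `gen_*` generate synthetic trial
tables, rate-level functions, and PSP traces with closed-form ground truth
for end-to-end testing.  See the vignette (`vignettes/lso-veto-model.Rmd`)
for the full account of the model, its calibration anchors, and the
generator's scope.

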