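# thalamod

Conductance-based modelling of **ventromedial (motor) thalamocortical
neurons** and of the current-clamp experiments used to characterize their
intrinsic excitability in brain-slice recordings.

In the dopamine-depleted (parkinsonian) state, neurons of the
basal-ganglia-receiving motor thalamus become hyperexcitable, mainly
through loss of the M-type (Kv7) potassium current `I_M`, with an
accompanying increase in T-type rebound bursting and in the
H-current-mediated sag.  `thalamod` provides the tools to study this in
silico, for electrophysiologists and modellers:

* a **multicompartment cell model**: surrogate or SWC-derived morphology
  (Rall 3/2-power dendritic diameters, 70 um axon initial segment, fixed
  293 um^2 soma), ten Hodgkin–Huxley-style conductances (NaF, NaP, KDR,
  KA, KM, CaL, SK, ANO2, CaT, IH) with region-specific densities, GHK
  calcium flux and three calcium microdomains, integrated implicitly
  (backward Euler + Hines elimination, compiled core);
* **virtual protocols** matching the experimental ones: F-I curves from a
  -64 mV hold, rebound steps from -71 mV, sag steps from rest, and the
  fixed passive pulses (-10 pA/100 ms; -1 nA/0.5 ms);
* **feature extraction** as defined in the experimental methods: dV/dt
  spike threshold, 50-ms onset exclusion, Boltzmann rheobase at 3 Hz,
  `sag% = 100 (1 - V_ss/V_peak)`, rebound counts binned by end-of-step
  hyperpolarization, double-exponential membrane time constant;
* a **Henderson liquid-junction-potential** calculator with the printed
  recording solutions built in;
* a **synthetic cohort generator** for control vs I_M-depleted /
  I_H-enhanced populations with log-normal channel-density variability.

The core quantitative claims the package reproduces are the model's
passive properties, obtained by calibration of the surrogate geometry and
leak against the same virtual protocols:

| property | published | measured here |
|---|---|---|
| input resistance (−10 pA, 100 ms) | 218.2 MΩ | 217.9 MΩ |
| membrane time constant (slowest of 2-exp fit) | 19.1 ms | 19.04 ms |
| capacitance τ/R_in | 87.4 pF | 87.4 pF |
| resting potential | −77.3 mV | −77.12 mV |
| junction potential (K-gluconate vs ACSF) | 14.2 mV | 14.53 mV |

## A worked example

```r
library(thalamod)

# calibrate the default surrogate model to the published passive targets
cal <- calibrate_passive()
cal
#> <passive_calibration: converged after 5 iterations>
#>   Rin 217.9 MOhm (target 218.2)  tau 19.04 ms (19.1)
#>   C 87.4 pF (87.4)  Vrest -77.12 mV (-77.3)

cell <- cal$cell

# F-I curve from a -64 mV hold, with and without the M-current
hold <- find_holding_current(cell, -64)
fi <- run_fi(cell, hold_pA = hold)
rates <- purrr::map_dbl(fi$trace, function(tr) {
  st <- attr(tr, "stimulus")
  firing_rate(detect_spikes(tr), st$onset_ms, st$dur_ms)
})
fit <- fit_fi_boltzmann(dplyr::tibble(current_pA = fi$step_pA,
                                      rate_Hz = rates))
fit
#> <fi_fit: fmax 34.2 Hz, I_half 254.1 pA, k 25.0 pA, rms 1.30 Hz>
rheobase(fit, target_rate_Hz = 3)   # pA at 3 Hz firing
#> [1] 195.5121
autoplot(fit)

blocked <- apply_pharmacology(cell, c(KM = 0))   # virtual XE-991

# sag and rebound
sag <- run_sag(cell)
purrr::map_dbl(sag$trace, ~ sag_percent(.x)$sag_percent)
#> [1] 26.15 28.70 30.59 30.81   # -50, -100, -150, -200 pA

# junction potential of the recording solutions
junction_potential(solution_internal_kgluconate(), solution_acsf())
#> [1] 14.52514
```

Removing the M-current (`KM = 0`) raises firing rates at every tested
current, lowers the rheobase, adds spikes to the post-inhibitory rebound
burst, and slightly increases the sag; doubling `IH` raises the sag
substantially — the signatures observed after dopamine depletion.

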