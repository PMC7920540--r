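---
title: "Modelling motor-thalamic excitability with thalamod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motor-thalamic excitability with thalamod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thalamod)
```

## The model and its purpose

`thalamod` implements a conductance-based multicompartment model of a
thalamocortical (TC) projection neuron of the ventromedial ("basal-ganglia
receiving") motor thalamus, together with the virtual current-clamp
protocols and trace-analysis procedures used to characterize intrinsic
excitability in slice recordings.  The scientific focus is the role of the
M-type (Kv7) potassium current: removing it should lower the rheobase,
raise tonic firing rates, increase post-inhibitory rebound bursting, and
(together with an increase in the H-current) increase the sag response —
the constellation of changes seen in parkinsonian (dopamine-depleted)
animals.

The membrane carries ten conductances: fast (NaF) and persistent (NaP)
sodium; delayed-rectifier (KDR), A-type (KA) and M-type (KM) potassium;
low-threshold T-type (CaT) and high-threshold L-type (CaL) calcium, both
with Goldman–Hodgkin–Katz flux; the hyperpolarization-activated cation
current (IH); and two calcium-activated channels, SK (potassium) and ANO2
(chloride).  Densities are region-specific (AIS, soma, three dendritic
classes) with fixed published values — see `distribution_table()` — and
are never altered by calibration; virtual pharmacology
(`apply_pharmacology()`) scales them per channel.

## Morphology

The default geometry is a parametric surrogate (`build_surrogate()`): a
single-compartment soma of fixed 293 um^2 surface, a 70 um x 1.5 um axon
initial segment, and five primary dendrites branching symmetrically to
third order with 40-um sections.  Dendritic diameters follow the Rall
3/2-power branch rule (`apply_rall_diameters()`) from a stem diameter that
is the main free knob of the passive calibration.  An SWC reader
(`load_swc()`) supports real reconstructions: the axon is truncated to its
initial 70 um (relabelled AIS) and the soma replaced by the standard
fixed-surface compartment.  Sections are mapped to density regions by
branch order with a path-distance override (`region_scheme()`): the region
layout of the published density table ("distal / proximal, 1st order / 2nd
order or above") does not define the three dendritic classes
unambiguously, so the mapping is a configurable scheme rather than a
hard-coded rule.

## Kinetics catalogue

The upstream model this cell descends from imports most channel kinetics
from earlier ventrobasal TC models without restating them, so `thalamod`
ships its own versioned catalogue (`kinetics_catalogue()`) built from
standard published formulations: Traub-style sodium/delayed-rectifier
rates (recentred by `na_v_off`, default -62.5 mV, placing the dV/dt spike
threshold near -44 mV), Huguenard–McCormick
A-current, Destexhe-style T-current with GHK flux, and a
Huguenard–McCormick-style H-current.  Each gate is a `gate_spec` with
closed-form steady-state and time-constant curves, a Q10 and a reference
temperature; everything is evaluated at 27 deg C.  Several constants were
set during model construction so that the fixed density table yields a
working tonic-plus-burst TC cell; the load-bearing choices, and why they
are what they are:

* **KM activation** is the printed offset sigmoid
  `0.025 + 1/(1 + exp(-(v + 36.7)/9.48))` (`km_steady_state()`); the
  additive constant keeps ~2.5% of channels open at any voltage and lowers
  the resting potential.  The *exponent* of the gate is not printed
  anywhere; it is set to 2 because the two readings differ sharply: with a
  first-power gate the M-current's standing conductance at rest exceeds
  the cell's entire measured input conductance (218.2 MOhm ~ 4.6 nS,
  versus ~3.2 nS of first-power resting KM), and near threshold it would
  consume several hundred pA so the model cannot fire below 360 pA.  With
  the squared gate both the passive targets and the published F-I range
  become attainable simultaneously.
* **E_K is -90 mV** (the convention of the classic VB thalamocortical
  models this cell's kinetics descend from), `E_Na = +50`, `E_h = -43`,
  ANO2 fixed at -86 mV; all configurable.
* **IH** couples an activation gate (half-activation -90 mV, slope 10,
  time constant a slow bell peaking ~440 ms near -85 mV; partially open at
  rest, where it supplies the standing inward current that balances the
  resting potassium currents) with a slow inactivation gate whose
  availability falls at extreme hyperpolarization (mid -112 mV, tau
  600 ms).  `shift_ih_inactivation()` translates that gate by -11 mV:
  unshifted, H-current availability drops at the voltages reached by
  -200 pA steps and the sag at -200 pA comes out *smaller* than at
  -150 pA; the shift restores monotonic growth of the sag with step size.
  The wide activation slope keeps recruitment growing over the whole
  -50..-200 pA range, which is what makes the sag percentage increase
  monotonically with step size.
* **NaP** is derived from NaF by translating both gating curves 14 mV in
  the hyperpolarizing direction (`derive_nap_from_naf()`; the sign is
  exposed, hyperpolarizing by default so the persistent current is active
  below the fast-spike threshold).
* **CaT** keeps a near-Destexhe activation position (mid -58 mV) with the
  crest-voltage inactivation slowed (~45 ms effective) so rebound bursts
  ride a sustained low-threshold spike; its window current near rest is a
  genuine inward contribution that, with IH, sets the resting potential,
  and its negative slope conductance amplifies the apparent input
  resistance — classic TC behaviour.
* **KA** follows the Huguenard-McCormick curves with a shortened
  depolarized-side inactivation time constant (10 ms): slower values make
  the recovered A-current clip the rebound low-threshold spike below the
  sodium threshold, faster ones remove the interspike brake that keeps
  the tonic F-I graded.
* **CaL** uses a steep high-threshold activation (mid -10 mV) so that it
  conducts only during spikes; its role here is spike-triggered calcium
  entry for adaptation, not subthreshold dynamics.

## Calcium microdomains and adaptation

Calcium is tracked in three first-order pools per compartment
(`calcium_pools()`): two fed by the CaL flux (25.8% -> SK pool, decay
14 ms; 74.2% -> ANO2 pool, decay 50 ms) and one fed by CaT (decay 50 ms)
that activates nothing and is bookkeeping only.  SK and ANO2 read their
pools through Hill functions (n = 4, EC50 0.3 uM; n = 2, EC50 1 uM).
Those EC50s are bulk-calibration numbers, so the pools are given an
effective dilution depth (45 um, i.e. the influx of one spike raises the
pools by roughly a micromolar) that keeps the channels in their graded
range during tonic firing; with literal 0.1-um submembrane-shell scaling a
single spike drives both pools far past saturation and the cell fires in
doublet-pause stutters instead of adapting tonically.  Sensitivity scans
over this dilution (10-300 um) trade maximal firing rate against
adaptation strength without changing the direction of the M-current
effects.

## Numerical scheme

`integrate_cell()` advances the tree-structured cable equation with
backward Euler on the voltage (Hines elimination; compartments ordered
parent-before-child), exponential-Euler gate updates from tables of
steady-state and `exp(-dt/tau)` values on a 0.05-mV grid, exact
exponential updates of the linear calcium pools, and an explicit GHK flux
tabulated on the same grid.  The default step is 0.025 ms (0.1 ms for
reduced-resolution cohort work), the default spatial resolution 20 um per
compartment (~75 compartments for the default surrogate).  Voltage-clamp
mode freezes the voltage and lets gates evolve, which is how the gate
integrator is verified against the closed-form exponential to below 1e-6
relative error; passive one- and two-compartment models are checked
against RC and eigen-decomposition solutions.  Every protocol starts from
a settled state: a 2-s pre-roll under the holding current is run and
discarded.

## Passive calibration

`calibrate_passive()` tunes the surrogate's free knobs — dendritic stem
diameter (total membrane area, hence capacitance), specific membrane
resistance (leak density, hence input conductance) and leak reversal
(resting potential) — by a damped fixed-point iteration until the model,
*measured with the same virtual protocols as the analysis pipeline*,
reproduces the published passive targets: input resistance 218.2 MOhm
(deflection at 100 ms of a -10 pA pulse), membrane time constant 19.1 ms
(slowest term of a double-exponential fit to the decay after a -1 nA /
0.5 ms pulse), capacitance 87.4 pF (= tau/Rin), and resting potential
-77.3 mV.  The default model converges in ~6 iterations to a stem
diameter near 3.1 um, rm near 24 kOhm cm^2 (close to the published value
read as 26 kOhm cm^2) and a leak reversal near -85 mV.  Channel densities are
deliberately not calibration knobs.

Note that the measured input resistance is not a passive quantity: the
M-current contributes its standing conductance, the H-current and the
T-window current contribute relaxation terms of opposite sign during the
100-ms pulse.  This is why calibration optimizes the *measured* values
rather than closed-form passive formulas.

## Protocols and features

The protocol layer reproduces the experimental procedures: `run_fi()`
(2-s depolarizing steps, 30–360 pA, from a bias current holding the soma
near -64 mV to inactivate the T-current), `run_rebound()` (-100 pA steps
of 200/500/2000 ms from ~-71 mV, with a 1-s post-step window),
`run_sag()` (2-s hyperpolarizing steps from rest) and `run_passive()`
(the fixed -10 pA/100 ms and -1 nA/0.5 ms pulses).  Holding currents are
found by bisection on the settled somatic voltage
(`find_holding_current()`), since the experiments specify target voltages,
not currents.

Feature extraction follows the experimental definitions: spikes are
upward crossings of dV/dt > 10 mV/ms followed by a peak above -10 mV
within 5 ms, with the threshold voltage read at the crossing sample;
firing rates exclude the first 50 ms of each step; the rheobase is the
current at which the F-I relationship crosses 3 Hz (10 Hz variant
available), read off a Boltzmann sigmoid fit by default with a
linear-interpolation fallback (`rheobase()`), because the source methods
mention a linear fit while every figure legend specifies the Boltzmann;
sag% is `100 (1 - V_ss/V_peak)` with the steady state read 2000 ms after
onset and a 100-ms pre-step baseline; cells with sag% strictly above 15
are classed sag-expressing; rebound spikes are counted in a 500-ms
post-offset window and binned by the hyperpolarization reached at the end
of the step (0–20/20–40/40–60 mV).  The unstated windows (baseline 100 ms,
rebound window 500 ms, post-step observation 1 s) are package choices;
bursts complete well within them.  Two time-constant estimators are
provided and method-tagged, since the experimental "time to decay to 33%
of peak" is a raw time (for a single exponential it equals
`tau ln(1/0.33)`, about 1.11 tau) whereas the model value is the slowest
term of the double-exponential fit.

`junction_potential()` evaluates the stationary Henderson equation with a
bundled limiting-mobility table.  The built-in solution compositions
decompose the printed recipes into ionized species (HEPES partially
deprotonated at pH 7.2, Mg-ATP as a 2- complex) and close the charge
balance with the potassium added by the KOH titration; gluconate's
mobility (24.3 S cm^2/equiv) is the dominant uncertainty and the bundled
value is the one distributed with standard junction-potential calculators.
The computed correction is reported but, matching the experimental
convention, never subtracted from simulated voltages.

## The synthetic cohort

`generate_cohort()` emulates the study's two groups: each cell is the
calibrated template with every channel density multiplied by an
independent log-normal factor (median 1, CV 0.15 by default — broad,
overlapping feature distributions like the experimental histograms),
then the condition scaling: control leaves channels untouched; "lesioned"
removes KM entirely (the experimental hallmark is a complete loss of
XE-991 sensitivity) and doubles IH (the published model uses a 200%
increase, with 300% as the stronger variant, available via `ih_scale`).
`run_cohort()` measures resting potential, rheobase (3 and 10 Hz), spike
threshold, a rebound count and sag% per cell; `effect_table()` reports
signed median differences.  Rebound spikes are counted at a matched
end-of-step hyperpolarization (22 mV, the centre of the experimental
20-40 mV bin, reached by rescaling the step amplitude after a -100 pA
probe): comparing at matched current instead conflates rebound
excitability with the input-resistance and H-current differences between
cells — precisely the confound the experimental binning of rebound data
by end-of-step hyperpolarization was designed to avoid.  The generator emulates between-cell channel
variability only: it does not model morphological diversity, correlated
channel regulation, recording noise or biological effect sizes, so
passing direction-of-effect checks says the pipeline recovers the sign
structure of the published group differences, not their magnitudes.

At the default "reduced" resolution the cohort protocols use a 0.1-ms
step, 0.8–1.2-s settling, a four-step F-I ladder (120–480 pA) with
linear-interpolation rheobase, one sag amplitude (-100 pA) and one
rebound duration (2000 ms); cohort templates are discretized at 45 um
per compartment (which changes the passive properties by <0.1%).  The
direction-of-effect checks in the test suite run 20 seed replicates of 8
cells per group at this resolution; the full resolution reproduces the
complete experimental ladders.

## Known limitations

* The kinetics catalogue is a reconstruction from standard published
  formulations, not the upstream model's exact parameter set; printed
  quantities (densities, the KM activation curve, shifts, passive targets,
  protocol definitions) are reproduced exactly, but unprinted curve shapes
  and time constants are package choices and are all exposed as
  parameters.
* The leak reversal that calibration selects compensates for the net
  standing current of the channel set at rest; it is an effective
  parameter, not a measured one.
* No synapses, spines, detailed axon, stochastic gating, or network
  context; voltage clamp exists only as a gate-testing mode.
* Experimental effect *sizes* (e.g. the measured rheobase difference
  between groups) reflect biological variability the cohort generator
  does not model; only directions of effects are claimed.  The rebound
  effect in particular is the weakest of the four headline directions: at
  matched end-of-step hyperpolarization the M-current block adds about two
  spikes to bursts of ten, so with eight cells per group and 15% density
  variability the sign of the group-median difference is recovered in most
  but not all seed replicates (about four in five), whereas the rheobase,
  resting-potential and sag directions are recovered almost always.
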