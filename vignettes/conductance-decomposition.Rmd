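---
title: "Methods: conductance decomposition, spike metrics and the synthetic ganglion cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conductance decomposition, spike metrics and the synthetic ganglion cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synconduct)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices that affect results.

## The measurement problem

On-type midget and parasol ganglion cells of the primate retina fire
tonically under steady background light.  That background rate is what
lets them modulate firing down as well as up — the basis of more linear
contrast coding in the On-pathway than the Off-pathway.  The analyses
here quantify three views of the same underlying tonic excitatory drive:

1. **Spiking**: background, peak and sustained firing rates from
   peristimulus time histograms under a contrast-modulated spot.
2. **Subthreshold noise**: the mean and SD of membrane voltage (spikes
   blanked) and of holding current, which index the tonic synaptic
   barrage directly.
3. **Conductance**: decomposition of voltage-clamp I-V families into
   excitatory, inhibitory and NMDA-type synaptic conductances as
   functions of time.

Pharmacological conditions (a CP-AMPAR antagonist, an NMDA-receptor
antagonist, a gap-junction blocker, an inhibitory cocktail) dissect which
circuit component carries each part of the response.

## Data model and units

Sweeps carry current in pA (voltage clamp) or voltage in mV (other
modalities), sampling rate in Hz, and conductances are reported in nS
with time in ms; `nS × mV = pA` keeps the forward model unit-consistent.
Inward current is negative.  Time starts at sample 0 = 0 s and all bins
are half-open `[t, t + Δ)`.

Liquid-junction-potential corrections are dataset metadata, never
hard-coded: the ganglion-cell Cs-internal correction (−16 mV), the
correction used inside the conductance analysis (−13 mV) and the AII-cell
correction (−15 mV) are all representable, because recordings and
conductance fits may legitimately carry different corrections.  A
correction is additive, applies only to voltage-valued fields, flips the
`ljp_corrected` flag and refuses double application.  The on-disk format
is a plain TSV samples table plus JSON sidecar so fixtures are
inspectable and diff-able.

## The stimulus

A square-wave contrast-modulated spot on a steady background, with
contrast defined as `100 (L_max − L_min) / L_background`.  A square wave
"at 80% contrast about a fixed background" is only well-posed once a
split convention is chosen; we use symmetric modulation
(`L_max − L_background = L_background − L_min`), the standard choice, so
80% contrast on 600 Rh\*/rod/s gives 840/360.  Contrast above 100% would
drive `L_min` negative and is rejected.  The first half-cycle after
`phase_zero` is the On-phase.

## Shot-noise drive and Campbell's theorem

The tonic excitatory drive is modelled as Poisson shot noise: unitary
conductance events with instant rise, peak `A`, and exponential decay
`τ`, arriving at rate `ν(t)`.  For this kernel the stationary moments are
closed-form (`∫w = τ`, `∫w² = τ/2`):

- mean current `= ν A F τ`
- current variance `= ν (A F)² τ / 2`

with `F` the driving force.  `campbell_moments()` implements this and is
the *independent oracle* for the simulated drive: the generator draws
event times in continuous time (thinning against the piecewise-constant
rate trace) and evaluates the kernel exactly at the sample grid, so the
sampled moments are unbiased against the continuous-time theory — a
discrete per-sample approximation would carry an `O(dt/τ)` bias on the
mean large enough to fail a 3-standard-error comparison.  A warm-up of
ten decay constants precedes each returned trace so it starts stationary.

The defaults (`A = 0.27` nS, `τ = 2` ms, `ν = 2000` Hz) were chosen once
so that the simulated cell reproduces the reported magnitude of the
phenomenon: a standing inward current of roughly 65–80 pA with an SD of
roughly 23–29 pA at hyperpolarised holding potentials, i.e. *few, large*
unitaries — high variance at moderate mean, which is exactly the
configuration in which a variance-driven background spike rate is
plausible.  The light-modulation gain of 1.1 per unit Weber contrast
suppresses roughly 45% of the tonic current during the Off-phase.

## The synthetic ganglion cell

Four components compose the drive (`build_synaptic_drive()`):

| component | carrier | default |
|---|---|---|
| tonic excitation | shot noise, rate modulated by contrast phase | 0.27 nS / 2 ms / 2000 Hz, gain 1.1 |
| transient excitation | deterministic exponential at On onsets, rectified | 8 nS, 10 ms latency, 60 ms decay |
| NMDA conductance | fraction of expected excitatory envelope | fraction 0.3 |
| transient inhibition | deterministic exponential at On onsets | 2 nS, 5 ms latency, 30 ms decay |

Drugs are multiplicative factor maps on these components
(`default_drug_sensitivity()`): the CP-AMPAR antagonist and the
gap-junction blocker both zero the tonic component (they interrupt the
same pathway at different points), the NMDA antagonist zeroes the NMDA
scale, the inhibitory cocktail zeroes inhibition.  Because factors
multiply, conditions compose exactly and two conditions that zero the
same component occlude one another — the simulated analogue of "adding
the antagonist after the gap-junction blocker changes nothing".  The NMDA
component follows the *post-drug* excitatory envelope, since the NMDA
receptors sit at the ganglion-cell synapse downstream of whatever drive
survives the drug.

The membrane is a conductance-based leaky integrate-and-fire neuron
(default 60 pF, 4 nS leak at −65 mV, threshold −50 mV, reset −56 mV,
3 ms refractory), integrated with the exponential-Euler scheme, which is
exact for piecewise-constant conductances; a too-coarse time step
(`Δt > τ_m/10`) is rejected rather than silently integrated.  At each
threshold crossing the crossing time is recorded as ground truth, a
stereotyped 0.6-ms depolarising transient (60 mV) is pasted into the
output for detector realism, and the membrane is reset.  The clamp in
`simulate_voltage_clamp()` is ideal — no series-resistance error — so
simulated currents are exact ground truth for conductance recovery.

Design choices made deliberately: spikes need *times* and realistic
detector input, not action-potential biophysics, so integrate-and-fire
with a pasted waveform suffices; drugs are parameter transforms, not
receptor kinetics; there is no multi-compartment or network model — the
circuit lives in the factor maps, not in equations.

What the generator does **not** emulate: spike-rate adaptation (onset
peak rates therefore run higher than typical recorded midget rates, ~250
vs ~130 Hz, though *relative* drug effects behave correctly), synaptic
depression, series-resistance and space-clamp artefacts, and correlated
(non-Poisson) release.  Passing recovery tests on this generator
therefore validates the analysis arithmetic and its statistical
behaviour, not robustness to those biological nuisances.

## Spike detection, blanking, PSTH

Detection takes the first difference of the trace (removing slow drift),
computes the SD of the *whole* derivative trace, and takes
positive-going crossings of 3 SD with a 1-ms lockout (the biphasic
derivative of a spike would otherwise double-count).  Two properties are
worth stating plainly:

- On a spike-free noise trace the 3-SD rule is *not* silent: a Gaussian
  derivative upcrosses 3 SD about 1.3 times per thousand samples.  The
  test suite checks the false-positive count against that analytic rate.
- With spikes present, the spikes themselves inflate the full-trace SD
  (this is why the SD is computed over the whole trace, not a quiet
  segment), which pushes the threshold far above the noise; sensitivity
  and false discovery are then measured against simulator ground truth
  (≥ 99% and ≤ 1% at signal-to-noise ≥ 5 in the acceptance suite).

Blanking replaces `[t − 1 ms, t + 3 ms]` around each spike with the
straight line between the window's boundary samples, merging overlapping
windows first and anchoring clipped windows at the trace edge.  On a
linear ramp this reproduces the ramp exactly; it is idempotent; samples
outside the merged windows are untouched.  Blanked voltage SDs still
contain the slow depolarisation into and after-hyperpolarisation out of
each spike — they are "spike-reduced", not purely subthreshold.

PSTHs use 20-ms bins and trial counts in multiples of 20; the rate is
`count / (n_trials × bin width)`, so the integral conserves the spike
count exactly, and across-block SDs come from block-wise PSTHs.  A
non-multiple trial count is an error rather than a silent trim.

The background / peak / sustained windows are *not* published numbers —
measurement points on histograms rarely are — so they are configuration,
defaulting to: background = 300 ms immediately pre-stimulus, peak = max
bin in the first 150 ms of the On-phase, sustained = mean over the last
250 ms of the On-phase.  They are recorded in every result.  Reported
percent changes are rounded half-away-from-zero to integers (matching
the usual reporting style) with the exact value kept in an attribute.

## Conductance analysis

Net light-evoked currents subtract, per holding potential, the mean over
a pre-stimulus baseline window (default 300 ms; a configuration key,
since the window is not a published number).  Currents are averaged in
10-ms bins; per bin the I-V relation is solved by (optionally weighted)
least squares for

\[ I(V) = G_{exc}(V - E_{exc}) + G_{inh}(V - E_{inh}) +
   G_{NMDA}\,B(V)\,(V - E_{exc}) \]

with `E_exc = 0`, `E_inh = −70` mV fixed by assumption, and the NMDA
term optional per cell type (off for cells whose excitation is linear in
V, as in parasol-like fits).  Solutions are **unconstrained in sign**:
an apparently negative excitatory conductance during the Off-phase is a
meaningful observation (suppression of the pre-stimulus baseline
conductance), so non-negativity would destroy the very effect of
interest.

The magnesium block uses the standard sigmoid
`B(V) = 1/(1 + (Mg/c) e^{−V/k})` with defaults Mg = 1 mM, c = 3.57 mM,
k = 16.13 mV (the classic `1/(1+e^{−0.062V}[Mg]/3.57)` fit).  Published
conductance analyses typically import these parameters from earlier
work without restating them, so the form and defaults here are the
package's own, are configurable, and are *recorded in every
decomposition result* along with the potentials used and the design
condition number; a near-collinear design (B(V)·V against V over the
supplied potentials) raises a warning rather than failing silently.

On full-rank noise-free synthetic I-V series the decomposition inverts
the forward model to solver tolerance; it is linear, hence equivariant
under current scaling; `reconstruct_currents()` re-evaluates the forward
model (the "re-calculated currents" overlay check); and with two
potentials and no NMDA term it reduces to the 2×2 closed form.  The
drug-difference conductance is a plain component-wise subtraction, which
requires identical grids *and* identical B(V) records — differencing
fits made under different nonlinearities would be meaningless.
Time-course similarity uses the closed-form least-squares scale
`s = Σab/Σb²` plus a Pearson correlation; it is invariant under common
rescaling, and a zero denominator trace is flagged rather than producing
an infinite scale.

## Statistics layer

Group comparisons run a Shapiro-Wilk normality check (advisory only — a
warning flag, no automatic switch to a nonparametric test, since the
analyses being mirrored specify none), a two-tailed paired or unpaired
t-test (two-tailed is an assumption, recorded here, where the sidedness
is unstated), and Bonferroni adjustment `min(1, m·p)`.  Degenerate
zero-variance comparisons report p = 1 (equal means) with a flag instead
of erroring.  Variability is reported as SD, matching the reporting
convention of per-cell physiology; n is the number of cells, with no
hierarchical modelling — the per-cell value is the unit of analysis.

## Expression summaries

The companion module reproduces dot-plot statistics: per (gene, cluster)
mean and SD of log(TPM+1) **including zeros**, and percent expressing
(> 0).  Zeros are included because published cluster means with SDs of
comparable magnitude are consistent with zero-inflated per-cell values;
an expressing-only mean is available behind a flag.  The "log fold
difference" between clusters is implemented as the *ratio of mean
log(TPM+1) values*, because that reading reproduces the published pairs
(0.90/0.85 → 1.06); one published pair (1.07/0.97, printed as 1.11)
gives 1.10 from the printed means, presumably because the original was
computed from unrounded means — the discrepancy is documented, not
resolved.  The generator draws a Bernoulli expressing mask times a Gamma
positive part whose moments are solved so the zeros-included mean/SD
converge to the targets; the AII-cluster mean (0.31) is back-computed
from the four published fold ratios, and expressing fractions, which are
not published for these clusters, are set to plausible dot-plot values.
Real-data import (dense CSV or MatrixMarket plus a cluster-label CSV) is
isolated from the synthetic path; no clustering or normalisation is
performed — cluster labels are taken as given.

## Problem sizes and determinism

The validation suites use: 100 seeded 2.5-s current-clamp trials for
detector sensitivity/false-discovery; 20 trials per potential at 9
potentials for noisy conductance recovery; 100 repeats of 1-s traces for
the Campbell comparison; 1000 paired t-tests on Gaussian nulls for
type-I calibration and 400 ten-comparison families for the family-wise
error rate.  These sizes put Monte-Carlo error comfortably inside the
3-standard-error bands being asserted while keeping a full run around a
minute.  Every stochastic operation takes an explicit integer seed;
identical seeds give bit-identical traces, and derived seeds stay below
2³¹.

## Known limitations

- The detector is a single fixed-threshold rule: no spike sorting, no
  amplitude clustering; it assumes single-unit recordings.
- The LIF cell has no adaptation, so absolute onset rates are high;
  conclusions should rest on within-cell condition contrasts, which is
  how the analyses are framed.
- NMDA parameters are assumptions, not fits; every result carries its
  B(V) record so alternative parameterisations can be compared.
- The expression generator matches first and second moments and the
  expressing fraction, not full count distributions; it validates the
  summary arithmetic, not count-model inference.
- NWB input is not currently supported; the native TSV + sidecar format
  and the documented expression formats are the supported paths.
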