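---
title: "Methods: quantifying somato-dendritic coupling from calcium imaging traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying somato-dendritic coupling from calcium imaging traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somadend)
```

## The scientific problem

Layer 5 pyramidal neurons integrate synaptic input in an apical dendritic
tree that can be hundreds of micrometres from the soma. Back-propagating
action potentials (bAPs) invade the apical trunk and tuft but attenuate with
distance; above a critical firing frequency (~50–100 Hz), bAP trains
trigger regenerative dendritic calcium electrogenesis that makes somatic
and tuft calcium signals co-occur. Two-photon imaging of a genetically
encoded calcium indicator (GCaMP6s/6f) in the soma, trunk and tuft of the
same neuron turns this physiology into a statistical question: what
fraction of calcium transients in one compartment has a coincident partner
in another, how does that fraction depend on transient amplitude and
distance, and is it changed by visual stimulation or locomotion?

`somadend` implements the full trace-level analysis chain for this
question, plus a forward simulator that produces traces with known ground
truth so that every stage can be validated by parameter recovery rather
than by eye.

## Pipeline stages and their parameters

### Baseline estimation (ΔF/F0)

The baseline F0 of a raw fluorescence trace is the 5th percentile of the
low-pass-smoothed trace (1 Hz cutoff, 60th-order windowed-sinc FIR,
Hamming window, zero phase), computed per trial and averaged across trials
to a single scalar, so darkness and stimulation periods share one
baseline. ΔF/F0 = (F − F0)/F0.

Numerical choices worth stating explicitly:

* **Zero phase** is achieved by forward–backward filtering with odd
  (point-mirrored) reflection padding, so constant traces pass through
  unchanged and edges carry no startup transient.
* **The FIR taps are renormalised to exact unit DC gain.** The textbook
  windowed-sinc design can have a DC gain several percent away from 1 at
  very low normalised cutoffs, which would bias F0 and break the
  scale-invariance of ΔF/F0; dividing the taps by their sum removes this.
* **Percentile convention** is linear interpolation
  (`stats::quantile`, type 7). Percentile definitions differ across
  ecosystems; the tests pin this one.
* The filter is applied at the trace's **native sampling rate**. An
  alternative reading of the procedure applies it after downsampling; for
  the smooth baselines involved the difference is far below the noise
  floor, but the choice is fixed and documented here.
* A trace without trial structure (e.g. a darkness-only session) is
  treated as a single trial.
* For ex vivo trials the baseline is instead the mean over the 1 s
  pre-stimulus window and a background term is subtracted in the
  denominator: (F − F0)/(F0 − F_bg). Baseline fluorescence in distal
  dendrites can be very low in slices, so the denominator is checked and a
  non-positive value is an error rather than an Inf.

### Resampling

Downsampling (e.g. 120 Hz single-plane data to a 5 Hz analysis rate) is
non-overlapping **bin averaging**, not decimation: integration over bins
suppresses aliasing without an extra filter stage and preserves total
duration to within one output sample. Upsampling is refused.

### Noise estimation and transient detection

The noise SD of a ΔF/F0 trace is the standard deviation of the trace after
a 9th-order, zero-phase high-pass at 0.6 Hz. Indicator transients live
below ~0.6 Hz, so the residual is dominated by noise. The filter is an IIR
Butterworth applied forward–backward; a spectral test checks the estimate
against an ideal frequency-domain high-pass to within 5%. The trace mean
is subtracted before filtering — the high-pass removes DC exactly, so this
only suppresses the numerical startup transient of the recursion.

Detection declares an event at every **strict local maximum** of ΔF/F0
whose height exceeds 2.8 × noise SD. Ties (plateaus) take the left-most
sample of the plateau. No minimum inter-peak distance is imposed, so a
burst may legitimately produce several peaks. Two distinct quantities are
attached to each event:

* the **detection height**, the ΔF/F0 value at the peak, thresholded
  against 2.8 × noise SD;
* the **amplitude**, the peak value minus the minimum of ΔF/F0 over a 2 s
  backward window ending at (and including) the peak, truncated at the
  trace start. Amplitudes are normalised to the maximum amplitude of the
  compartment over the session.

One property of this scheme deserves emphasis because the simulator makes
it visible: because F0 is a low percentile, the ΔF/F0 noise floor sits
slightly above zero, and the absolute-height threshold therefore admits a
small population of noise-driven local maxima whose count is independent
of the noise scale. On real and simulated data these false events are
confined to the lowest normalised-amplitude bins — which is precisely
where the amplitude-specificity analysis already expects near-threshold
behaviour, and why robustness to a ±30% threshold change
(`threshold_sweep()`) is part of the standard analysis rather than an
afterthought.

### Coincidence matching

Two event series from a proximal–distal compartment pair are matched
one-to-one with an **asymmetric window**: a candidate coincidence for a
reference peak must lie within 2 s before to 1 s after it. Candidates are
collected from both reference sides (each compartment serves as reference
for its own specificity measure), pooled, sorted by |Δt| and matched
greedily; each event can participate in at most one match, and no matched
pair can be further apart than 2 s. The greedy rule is a deliberate,
documented choice — the tests verify it against an exhaustive assignment
oracle (maximal match count, then minimal total |Δt|) on instances where
the optimum is unambiguous.

For matched events the Pearson correlation is computed between the two
peak amplitudes. A compartment-specific event still contributes a pair:
the silent side is read out as max − min of its ΔF/F0 in a 3 s window
centred on the detected peak. A permutation null (`shuffle_null()`,
default 1000 seeded permutations of one side's amplitude order) centres at
zero for any amplitude distribution.

The proportion of compartment-specific events is binned by normalised
amplitude (half-open bins of width 0.05; the last bin closes at 1).
Across pairs, per-bin proportions are combined as a weighted mean with
per-pair event counts as weights; the weighted SEM is the square root of
the weighted variance (with a small-sample correction m/(m−1) over the m
contributing pairs) divided by m. Empty bins are reported as missing, not
as zero.

Per-segment frequency losses chain multiplicatively:
`chain_attenuation(c(0.14, 0.08, 0.24))` = 0.3987, i.e. a ~40% compound
loss of transient frequency over three segments. The lag distribution of
matched events is summarised by `match_interval_stats()`; with a lag SD of
0.28 s the ±1 SD band (width 0.56 s) contains ~95% of matched lags.

Nonlinear amplitude changes between compartments are captured by
residuals from a robust linear regression of distal on proximal
normalised amplitudes: iteratively reweighted least squares with Tukey
bisquare weights, tuning constant 4.685, convergence tolerance 1e−8
(`MASS::rlm`). An exact fit drives the IRLS residual scale to zero, where
the convergence test cannot fire; that case is recognised and accepted.
Residuals are grouped by condition labels into empirical cumulative
distributions.

### Behavioural-state segmentation

A sample is **locomotion** when three criteria hold simultaneously:
instantaneous speed ≥ 0.1 cm/s, 0.25 Hz low-passed speed ≥ 0.1 cm/s
(2nd-order zero-phase Butterworth; only the cutoff is prescribed, the
order is our choice), and mean speed over a centred 2 s window ≥ 0.1 cm/s
(window truncated at the trace edges). Gaps between locomotion periods
shorter than 500 ms are merged — after the composite criterion is
evaluated, which is our reading of an order the procedure leaves open.
**Stationary** requires instantaneous speed < 0.1 cm/s; stationary samples
within 3 s after or 0.2 s before locomotion are excluded, as are samples
meeting neither definition (e.g. sub-threshold drift). The speed trace is
interpolated to the imaging analysis rate before classification; the
original acquisition rate of the encoder is not used directly.

`transition_windows()` additionally marks 2 s before to 1 s after each
locomotion onset and 1 s before to 20 s after each offset (truncated if
another bout begins sooner); transition samples are removed from both the
stationary and locomotion masks.

### Orientation tuning

Responses are the mean ΔF/F0 over each 3 s grating presentation, averaged
across trials of the same orientation; the 8 drift directions are
collapsed to 4 orientations (mod 180°) **before** any indexing, so the
orthogonal response is read from the collapsed curve. A trial can be
restricted to a behavioural state; the qualifying rule is "more than half
of the trial's samples in that state".

Two selectivity measures are computed. The index
OSI = (O_pref − O_orth)/(O_pref + O_orth), with the preferred orientation
the argmax of the curve. And the complex resultant
V = Σ R_k e^{2iθ_k} / Σ R_k, whose argument halved gives the preferred
angle mod 180° and whose modulus is a tuning-strength index. Negative
mean responses are floored at zero before the resultant — the formula is
ill-behaved under negative weights and the procedure is silent on this
case. A perfectly uniform curve has |V| = 0 and an undefined angle, which
is reported as missing rather than as 0°.

### Ex vivo sham-calibrated detection

Each slice trial is 6 s with a 1 s baseline; trains of 10 pulses at
5–200 Hz drive the soma (current injection) or the apical dendrite (L1
stimulation). The response amplitude is the peak ΔF/F0 within 1 s after
stimulation cessation, standardised to the maximum evoked signal per
compartment, minus the mean sham-trial peak measured in a matched window.
The null distribution is built leave-one-out over sham trials (each sham
peak re-expressed against the mean of the remaining ones); an amplitude
is a detected event when it exceeds 2.8 null SDs. Monte-Carlo tests
confirm that the false-positive rate on pure-noise trials matches the
empirical 2.8 SD tail of that null.

## The forward simulator

The generator is the package's ground-truth instrument, and its defaults
are the study conditions the analysis assumes, not tuning knobs:

* **Somatic transients** are a Poisson process (default 4 events/min over
  600 s at 4.8 Hz, the per-plane rate of dual-plane imaging). Each
  transient stands for one burst: within-burst spikes are unresolvable by
  the indicator, so the ground truth merges them by construction.
* Each transient carries a **burst frequency** drawn from a categorical
  distribution (defaults 10/25/50/100 Hz with probabilities
  0.35/0.30/0.20/0.15) and a **log-normal amplitude** (meanlog log 0.35,
  sdlog 0.6, in ΔF/F0 units). The true in vivo amplitude distribution is
  unknown; log-normal is a modelling choice, flagged here.
* **Somatofugal propagation** is sequential per segment
  (soma→pTrunk→dTrunk→tuft). Survival across one segment is logistic in
  amplitude (small events attenuate more) and gated fully on at burst
  frequencies ≥ 50 Hz — the simplest model reproducing the observed
  amplitude-dependent specificity curves and the critical-frequency
  physiology. Default midpoints (0.10, 0.06, 0.16 ΔF/F0) give expected
  per-segment survivals near the reported per-segment frequency ratios.
  `mean_survival()` integrates the model over the amplitude and frequency
  distributions, giving the configured truth for recovery tests.
* **Tuft-initiated events** (default 0.05/min) appear in the tuft always
  and reach the soma with probability 0.986, emulating rare
  dendritically-initiated global events.
* **Fluorescence** is baseline × (1 + Σ amplitude × kernel) plus i.i.d.
  Gaussian noise (default SD 0.015 ΔF/F0). The kernel is a
  difference of exponentials normalised to unit peak; defaults 0.18 s
  rise / 1.0 s decay emulate a slow GCaMP6s-like indicator, and
  0.05 s / 0.3 s a fast 6f-like one whose reduced sensitivity makes it
  miss low-frequency somatic events. Photon (shot) noise, neuropil
  contamination, bleaching and motion artefacts are deliberately out of
  scope, so passing recovery tests demonstrate correctness of the
  analysis, not robustness to those artefacts.
* Everything is seeded; a per-neuron stream is derived from the config
  seed, and identical configuration gives bit-identical output.

## What the tests establish, and at what problem sizes

The suite favours independent oracles over re-execution: closed-form
kernel maxima, direct percentile computation, an FFT high-pass for the
noise estimator, a brute-force local-maximum scan for detection, an
exhaustive assignment search for matching, the textbook Pearson formula,
direct complex summation for the resultant, least-trimmed-squares for the
robust fit, and a sample-by-sample re-execution of the behaviour rules.
Stochastic recovery tests run at deliberately modest sizes chosen for
tight binomial error at interactive runtimes: ~500–1500 simulated events
for attenuation recovery, 1000 adversarial event-series pairs for the
matching-window bound, 1000 permutations for the shuffle null, ~3000
Monte-Carlo trials for the sham-null calibration, and 200 simulated tuned
neurons (24 trials each) for orientation recovery, of which ≥95% must
recover the configured preferred orientation within half the orientation
spacing (22.5°).

## Known limitations

* The simulator's Poisson event timing has no refractoriness or burst
  clustering beyond the merged-burst convention; inter-event intervals
  shorter than the indicator decay produce overlapping transients that
  detection may merge or split, exactly as on real data.
* Amplitude normalisation is per compartment and session; comparing
  normalised amplitudes across sessions assumes comparable maxima.
* The sham-calibrated ex vivo detector assumes exchangeable sham trials;
  slow drift across a slice session would violate the null.
* The analysis emits per-neuron tables (events, matches, specificity,
  residuals, tuning); the downstream ANOVA/t-test family applied to those
  tables in a typical study is out of scope here, by design.

## Interfaces

All stages are ordinary R functions operating on small S3 containers
(`trace`, `event_series`, `pair_coupling`, `behavior_labels`,
`tuning_curve`), with CSV/JSON/YAML I/O (`read_traces()`,
`write_events()`, `read_pipeline_config()`) and a single orchestration
entry point, `run_pipeline()`, that stamps every run with its seed and a
configuration hash. These functions, driven from R or `Rscript`, are the
package's interface; no separate shell tool is shipped.
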