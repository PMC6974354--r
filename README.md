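# somadend

Trace-level analysis of somato-dendritic coupling in two-photon calcium
imaging of cortical layer 5 pyramidal neurons — for anyone who has
fluorescence time series from paired neuronal compartments (soma, apical
trunk, apical tuft) and wants to quantify how calcium transients
co-occur, attenuate and co-vary across them, under different behavioural
and stimulus conditions.

## What it computes

Given raw fluorescence traces F(t) per region of interest, the pipeline:

1. **ΔF/F0** — baseline F0 is the 5th percentile of the 1 Hz
   low-pass-smoothed trace (zero-phase, 60th-order FIR), per trial,
   averaged to one scalar per session; ΔF/F0 = (F − F0)/F0.
2. **Transient detection** — noise SD σ is estimated from the 0.6 Hz
   high-passed ΔF/F0; events are strict local maxima with height
   > 2.8 σ. Each event's amplitude is peak minus the local minimum in a
   2 s backward window, normalised to the compartment's session maximum.
3. **Coincidence matching** — one-to-one matching across a
   proximal–distal pair with an asymmetric window (2 s before, 1 s after
   the reference peak; no matched pair further apart than 2 s), Pearson
   correlation *r* of matched amplitudes (silent sides read out as
   max − min in a centred 3 s window), a seeded permutation null for *r*,
   the distal/proximal frequency ratio, amplitude-binned proportions of
   compartment-specific events (bin width 0.05, weighted mean ± weighted
   SEM across pairs), and residuals from a robust (bisquare IRLS) fit of
   distal on proximal amplitudes.
4. **Behavioural state** — stationary / locomotion / transition /
   excluded labels from treadmill speed (0.1 cm/s threshold on
   instantaneous, 0.25 Hz-low-passed and 2 s-mean speed; sub-500 ms gaps
   merged; exclusion zones 3 s after and 0.2 s before locomotion;
   transition windows −2/+1 s around onsets and −1/+20 s around offsets).
5. **Orientation tuning** — per-orientation trial-averaged responses
   (8 drift directions collapsed mod 180°),
   OSI = (O_pref − O_orth)/(O_pref + O_orth), and the complex resultant
   V = Σ R_k e^{2iθ_k} / Σ R_k whose argument halved is the preferred
   orientation.
6. **Ex vivo calibration** — sham-calibrated detection of evoked
   transients (peak within 1 s after stimulation, leave-one-out sham
   null, 2.8 null-SD threshold) and per-frequency compartment-specific
   proportions.

A forward simulator (`synth_config()`, `generate_neuron()`) produces
traces with hidden ground truth — Poisson somatic transients with burst
frequencies, log-normal amplitudes, logistic amplitude-dependent
somatofugal survival gated at a 50 Hz critical frequency, rare
tuft-initiated global events, unit-peak difference-of-exponential
indicator kinetics, Gaussian noise — so every stage is testable by
parameter recovery.

## Worked example

```r
library(somadend)

cfg  <- synth_config(duration = 600, seed = 42)   # 10 min at 4.8 Hz
sim  <- generate_neuron(cfg, neuron_id = 1)
dffs   <- lapply(sim$traces, compute_dff)
events <- lapply(dffs, detect_events)
sapply(events, function(e) nrow(e$events))
#>   soma pTrunk dTrunk   tuft
#>     76     64     62     61

pc <- pair_coupling(events$soma, events$tuft, dffs$soma, dffs$tuft)
round(c(r = pc$r, freq_ratio = pc$frequency_ratio), 3)
#>          r freq_ratio
#>      0.731      0.803

shuffle_null(pc, n_perm = 1000, seed = 1)$mean
#> [1] -0.0024

unlist(match_interval_stats(pc)[c("mean", "sd", "width")])
#>   mean     sd  width
#> -0.008  0.224  0.448

chain_attenuation(c(0.14, 0.08, 0.24))
#> [1] 0.398688
```

Read: the soma fired 76 detectable transients, of which ~20% attenuated
below detection by the distal tuft (frequency ratio 0.80); matched
amplitudes correlate at r = 0.73 while the shuffled-order null sits at
≈ 0; matched peaks are essentially simultaneous (lag SD 0.22 s, so the
±1 SD band of width 0.45 s contains ~95% of lags). Chaining per-segment
frequency losses of 14%, 8% and 24% gives a ~40% compound loss from soma
to distal tuft. `binned_specificity(pc)` adds the amplitude dependence:
compartment-specific events concentrate in the lowest amplitude bins.

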