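---
title: "Methods: telemetry EEG/EMG and open-field analysis in neurotelem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: telemetry EEG/EMG and open-field analysis in neurotelem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotelem)
```

`neurotelem` analyzes multi-day wireless telemetry from mice — EEG, neck
EMG and locomotor activity at 500 samples/s, body temperature at 10
samples/s — together with one-hour open-field sessions tracked by pose
estimation. This vignette documents the models and procedures, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Recording model and data hygiene

A `telemetry_recording` holds per-channel samples, rate, and a boolean
validity mask. Sample `i` of a channel covers `[i/rate, (i+1)/rate)`
seconds from the wall-clock start (half-open convention). All times are
reduced to Zeitgeber time, `zt(t) = (clock(t) − lights_on) mod 24` hours,
with lights-on at 07:00 by default; ZT 0–12 is the light (resting) phase
for mice, ZT 12–24 the dark (active) phase.

Out-of-range samples — |EEG/EMG| > 2 mV, activity < 0 counts, temperature
≤ 25 °C — are transmitter noise, not physiology. `clip_artifacts()` masks
them *individually* rather than deleting them or widening to whole
segments (the narrower of the two defensible readings; masking keeps the
time axis intact so downstream binning is unaffected). Bin averages use
valid samples only, and bins with under 50% valid samples are flagged and
excluded — the source procedure removes noise but states no bin-validity
rule, so the 50% rule is this package's choice, reported per bin in every
output. Recordings split by a stop (e.g. for dosing) are merged on a
common wall-clock axis with masked-invalid gap fill, so valid duration is
conserved exactly.

EDF is the on-disk interchange format (16-bit; one data record per
second). The physical calibration is written at the 8-character header
precision and digitization uses those same rounded bounds, so a
write–read round trip is within one quantization step; validity masks are
not part of EDF and live only in the in-memory container, which keeps
full float precision.

## Epileptiform spike detection

The detection chain is: zero-phase FIR high-pass (Kaiser design, passband
edge 6.3 Hz, transition band 5.0 Hz wide, ≥ 60 dB stopband) → baseline SD
→ threshold crossing → gates.

*Baseline.* Three 2-min windows, one from each third of the recording,
chosen automatically as the candidate (30-s grid) minimizing the 99th
percentile of |signal| — an explicit stand-in for the human choice of
windows with "little to no spikes". The baseline SD is the mean of the
three window SDs; a constant signal is rejected as degenerate.

*Gates.* Candidate events are maximal runs with |x| > k·σ (k = 10
baseline SDs); runs closer than 5 ms (the minimum event duration) merge.
Duration is measured between the k/2·σ crossings around the peak — the
measurement points are not prescribed anywhere, so half-threshold
crossings were chosen as the convention least sensitive to noise — and
events outside 5–80 ms are rejected. Thresholding is on |x| since
discharges may be negative-going. A sharpness floor (|peak|/duration,
default off) stands in for the proprietary, manually supervised template
matching used in the original workflow; this substitution is the largest
methodological replacement in the package and is deliberately exposed as
three plain parameters (`k`, `dur_range`, `slope_floor`) instead of an
opaque template.

*Refractory window.* A zero-phase high-pass filter turns a slow
(60–80 ms) transient into an oscillatory one: its ringing lobes can cross
threshold tens of ms away from the main deflection and would be counted
as separate events. Detections are therefore clustered within a 100-ms
refractory window and only the largest-amplitude member is kept. On
synthetic recordings this removes essentially all duplicate detections
(precision rises from ~0.8 to ~1.0) without touching genuine events,
which the generator spaces ≥ 250 ms apart.

Counts are aggregated 1-min → 15-min, and multi-day circadian averaging
is shared with every other variable (below).

## Sleep staging

Staging is a deterministic rule cascade at 5-s epochs on four features:
epoch EEG RMS, delta (1.5–5 Hz) and theta (6–12 Hz) component RMS from
zero-phase Butterworth band-passes, and rectified-mean EMG:

* REM if θ/δ > 1 and EMG < 0.011 mV;
* else NREM if EEG RMS > 0.035 mV, delta RMS > 0.022 mV, EMG < 0.007 mV;
* else Wake.

Two interpretation choices are worth stating. First, the REM ratio
threshold appears in the source material only as a corrupted token; it is
implemented as 1.0 (the value the surrounding text implies) and exposed
in `staging_thresholds()`. Second, the amplitude statistic behind
thresholds like "EEG > 0.035" is unspecified; RMS in mV was chosen
because it puts the printed thresholds on the natural signal scale; the
original acquisition-software script carries further tuning knobs with
undocumented semantics, which are deliberately not reproduced — staging
here is exactly the explicit inequalities above and nothing else. Epochs
with under 50% valid samples copy the previous label
(first epoch defaults to Wake). The hypnogram is deliberately *not*
smoothed: the phenotype of interest includes fragmentation, which
smoothing would suppress.

Hypnogram metrics: a transition is any label change between consecutive
epochs, with Wake→Sleep pooling entries into NREM and REM; a bout is a
maximal run of one label; spikes are attributed to the stage of their
onset epoch. All metrics are split day/night (phase of the first epoch
involved) and averaged across recording days.

## Spectral analysis

*Band power.* Welch short-time power with Hann windows of 1024 samples at
500 samples/s — numerically 0.488 Hz per bin, implemented as stated and
labeled nominally 0.5 Hz; at other rates the FFT length is rescaled to
keep ≈ 0.5 Hz. Window overlap is not prescribed; 50% is used. Band power
is the sum of the spectral bins whose centers fall inside the band, and
two schemes coexist without mixing: the canonical power bands (delta
1.5–5, theta 6–12, beta 11–15/15–25, gamma 30–80 with 30–60/60–80
sub-bands) and the periodic-fit bands (theta 6–12, beta 11–15/15–25,
gamma 25–40/40–70). Overlaps between bands (beta-low vs theta) are by
design of the band scheme.

*Multitaper mean spectra.* 5 Slepian tapers on 0.5-s non-overlapping
windows averaged in 10-s bins. Only the taper count is prescribed;
NW = 3 is used because 2NW − 1 = 5 is the standard number of
well-concentrated tapers. Tapers come from the symmetric tridiagonal
eigenproblem, computed in-package because no installed package provides
them.

*Aperiodic/periodic parameterization.* The fixed-mode aperiodic model is
`log10 P(f) = b − χ·log10 f`, fit over 15–70 Hz by a robust two-pass
regression (fit, drop bins more than 1 SD above the fit, refit) so
oscillatory peaks do not bias the slope. Gaussian peaks are then fit to
the flattened spectrum over 4–70 Hz — bandwidth limited to 3–30 Hz,
unlimited count (capped at 12 as a numerical safety), minimum height 0,
and a stopping threshold of 1 SD of the flattened residual (the "1" in
the algorithm settings is interpreted in SD units, the convention of the
algorithm family) — first by iterative extraction, then a joint bounded
least-squares refinement, after which the aperiodic component is re-fit
on the peak-removed spectrum. The fit has no random initialization and is
exactly reproducible. Per-band metrics report the largest in-band peak's
log-power height and the trapezoid AUC between the full model and the
aperiodic curve in linear power units. The hour-long day/night segments
for aperiodic analysis are cut at local clock 10:00 and 22:00 of
recording day 2.

One known artifact: with 0.5-s windows the multitaper bandwidth is
±6 Hz, which smooths steep 1/f spectra upward near the low-frequency edge
of the periodic range and can produce spurious near-edge "peaks" on pure
noise. The aperiodic exponent, fit from 15–70 Hz, is unaffected (median
recovery error ≈ 0.04 on one-hour synthetic segments).

## Circadian profiling

Every 1-min series (spike counts, activity, band power, temperature) maps
to 96 15-min ZT slots: slot mean within each recording day, then mean and
SEM across days. Equal-frequency ("rest-to-active") binning rank-orders a
subject's 15-min values with ties broken by temporal order (so repeated
zero-activity bins distribute deterministically) and cuts them into k
contiguous blocks differing by at most one observation — computed per
subject, which keeps the 20%-per-bin guarantee exact for each animal;
per-band power quintiles are likewise per band and per subject. Treatment
designs divide each value by the subject's week-1 (baseline) mean, so the
baseline week is 1 by construction and a non-positive baseline flags the
subject for exclusion. Group-level inference (GLMM, post-hoc corrections)
is intentionally out of scope: outputs are tidy per-bin tables ready for
external statistics.

## Open-field spatial analysis

The arena is a circle (12-inch inner diameter by default, so radius
15.24 cm) supplied by configuration — geometry detection from video is
out of scope, with the minimum enclosing circle of the trajectory as a
fallback. The center zone is the disk of 0.6× the radius, boundary
inclusive, so uniform occupancy gives a center fraction of 0.6² = 0.36.
Frames with pose likelihood below 0.9 (the usual pose-export convention)
or non-finite coordinates are invalid; frames beyond the nominal radius
are kept for distance but zoned "out" and excluded from center/periphery
denominators. Distance sums Euclidean steps between consecutive valid
frames per 10-min bin, skipping gaps without interpolation (how missing
pose frames were handled upstream is unstated; skipping is the
conservative choice). The habituation index is the 0–10 min distance over
the 50–60 min distance, 1 meaning no habituation. Per-motif (30) and
per-community (9) center time is the percent of that label's in-arena
frames lying in the center, at session level and in 10-min bins; a
frame-count-weighted average over labels recovers the whole-session
center time exactly. Spatial heatmaps are Gaussian KDEs with Scott's rule
(per-axis bandwidth `sd · n^(−1/6)`, via `MASS::kde2d`; the
full-covariance variant differs only for correlated clouds) on a 200×200
grid over the arena extent, divided by their maximum and masked below 10%
of it; a common maximum can be supplied when comparing groups. Outlier
sessions are removed only from a configuration-supplied list, never by a
data-driven rule.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth. It
emulates, per vigilance state: a 1/f^χ EEG background (spectral shaping
of white noise, exponent applied over 1–100 Hz and held flat below 1 Hz
to avoid divergence) plus sinusoidal band components at 3.25, 9, and
55 Hz; EMG as white noise scaled to a target rectified mean; Poisson
spikes with state-dependent rates; day/night Markov sleep dynamics at the
5-s epoch; Poisson activity counts (day/night Wake means, sleep at 5% of
Wake — the transmitter's proprietary activity algorithm is not emulated,
counts are arbitrary non-negative integers); and temperature as a
circadian cosine peaking at ZT 18 plus noise. Open-field sessions are
reflected Gaussian random walks with an outward radial drift proportional
to an anxiety parameter, a step length decaying as
`exp(−habituation_decay · t)`, and zone-conditional categorical motif
labels (a 2-zone emission mixture — it guarantees known zone-conditional
motif frequencies for testing and does not model real motif dynamics).

Defaults are the study conditions where stated (500/10 samples/s sampling,
12:12 light/dark from 07:00, spike amplitude 12× background SD with 5–80
ms durations) and otherwise calibrated once to realistic values: the
state-conditional features straddle the staging thresholds with a margin
(e.g. NREM delta RMS ≈ 0.032 mV vs the 0.022 mV threshold), spike rates
are highest in NREM, and locomotion is nocturnal (40 vs 10 counts/min).
Two generator choices deserve emphasis. The spike template is an
asymmetric difference of Gaussians (a dominant sharp deflection with a
0.3× opposite wave, random polarity) whose main-lobe width at the
detector's half-threshold is calibrated to the nominal duration, so
"duration" means the same thing to the generator and the detector. And
the amplitude multiple is defined on the *high-passed* channel — each
template is scaled so its filtered peak is `multiple × SD` — because both
the detection threshold and the baseline SD live on that scale; without
the compensation the filter attenuates 60–80 ms spikes by ~30% and the
nominal multiple would be a fiction for slow events.

What the generator does not emulate bounds what passing tests show:
biophysically realistic EEG (no phase-amplitude structure, no spindles or
real theta dynamics), amyloid pathology, transmitter dropouts beyond
masked gaps, correlated pose noise, or real motif label dynamics. Tests
passing on this substrate demonstrate that the *pipeline arithmetic* is
correct under known truth — not that the thresholds would score real
mouse sleep at any particular accuracy.

## Problem sizes and determinism

Unit and acceptance tests run the generator at 250 samples/s (a reduced
rate mode; all parameters are in physical units and rate-independent) on
recordings of two hours or less, with one-hour segments for exponent
recovery — sizes chosen so the whole suite completes in a few minutes
while every statistical tolerance retains comfortable margin. Every
stochastic stage takes an explicit seed and the analysis stages have no
randomness at all, so the full pipeline is bit-identical across runs with
the same configuration; `run_telemetry_pipeline()` exercises this end to
end.

## Known limitations

The sharpness gate is a stand-in, not a reconstruction, of the original
template-based spike review; staging thresholds are fixed rules with no
learning or scorer-concordance claim; knee-mode aperiodic fitting and
cosinor rhythm modeling are not provided; and EDF support covers the
continuous 16-bit layout used here, not the full EDF+ annotation
standard.
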