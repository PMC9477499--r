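---
title: "Methods: sleep EEG oscillation analysis in nremtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep EEG oscillation analysis in nremtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nremtools)
```

`nremtools` analyzes overnight sleep EEG for the thalamocortical
oscillations of non-REM sleep — sleep spindles (10–16 Hz sigma bursts)
and slow waves (large negative half-waves below 4 Hz) — and for their
phase coupling, which indexes limbic–thalamo–cortical dialogue during
memory consolidation. This vignette describes each model and procedure,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data validation does and does not establish.

## Data model and conditioning

A recording is a channels-by-samples matrix in microvolts with a
sampling rate, carried by `eeg_recording()`; scored sleep stages arrive
as a 30-s-epoch `hypnogram()` (`W`, `N1`, `N2`, `N3`, `REM`, `ART`).
`read_edf()`/`write_edf()` handle the 16-bit EDF interchange format
with a symmetric physical/digital mapping, so a round trip is exact to
one quantization step. `condition_signal()` resamples to 128 Hz
(polyphase, anti-aliased) and detrends with a 0.25 Hz second-order
Butterworth high-pass applied forward–backward (zero phase; ≥ 20 dB
attenuation well below the cutoff). All downstream defaults assume
128 Hz.

`sleep_architecture()` computes the standard polysomnography summary.
Two conventions are deliberate, since reference points are often left
implicit in clinical reports: N1 latency is referenced to the start of
the recording, REM latency to the first sleep epoch, and sleep
efficiency uses the whole hypnogram duration as its denominator (a
time-in-bed proxy when lights-off is unrecorded). `ART` epochs count
toward total time but never toward sleep.

## Epoch-level artifact rejection

Artifact screening operates on the pooled N2+N3 epochs of each channel
independently, in a fixed order; each rejected epoch records the first
criterion that fired.

1. **Flanking band power** (`flanking_band_rejection()`). An epoch is
   rejected when its delta (1–4 Hz) power exceeds the mean + 2.5 SD, or
   its beta (16–25 Hz) power the mean + 2 SD, of up to 7 pooled N2/N3
   epochs on each side (fewer at the record edges; under 3 available
   flankers the epoch passes with a warning). Band powers are compared
   on the decibel scale. This matters: linear delta power across epochs
   is strongly right-skewed by the natural epoch-to-epoch variation in
   slow-wave counts, and a mean + k·SD rule on the linear scale rejects
   on the order of 10% of clean epochs; on the log scale — the
   conventional unit for EEG band power — the same rule is calibrated
   (a few percent) while still flagging injected delta or beta
   artifacts with essentially unit sensitivity.
2. **Clipped samples** (`clipping_rejection()`). An epoch is rejected
   when more than 5% of its samples equal the channel's global minimum
   or maximum (saturation). A constant channel, where every sample
   equals both extremes, is rejected wholesale with a warning.
3. **Iterative RMS/Hjorth screening** (`iterative_rejection()`). Three
   cycles; in each, the RMS and the three Hjorth parameters (activity,
   mobility, complexity) are computed per surviving epoch and for the
   whole surviving signal, and an epoch is rejected when any metric
   exceeds twice the whole-signal value. Later cycles recompute the
   reference from the reduced set, so removing a gross outlier can
   expose a marginal epoch in the next cycle. We considered the
   alternative reading — z-scoring each metric across epochs and
   rejecting |z| > 2 — and rejected it: trimming at 2 SD over four
   metrics and three cycles removes roughly 5% of clean epochs per
   cycle under *any* continuous metric distribution, which is
   incompatible with a screening step meant to spare clean data. The
   whole-signal-multiple reading rejects essentially no clean epochs
   while still catching a ×10-RMS epoch trivially. The threshold is
   one-sided (artifacts inflate these metrics).

`apply_mask()` and `surviving_segments()` convert the keep/reject mask
into contiguous sample runs so that filtering and detection never cross
an epoch-rejection discontinuity.

## Spectral estimation and the aperiodic component

`welch_psd()` implements the averaged modified periodogram: a 4-s Hann
window advanced in 2-s steps, epoch-wise averaging for long inputs,
one-sided density in µV²/Hz on a 0.25 Hz grid over 0.25–20 Hz, with a
dB view floored at −300 dB for zero-power bins. `welch_psd_zscored()`
standardizes the signal in the time domain first, removing broadband
amplitude differences between subjects (useful because overall EEG
power falls steeply across adolescence). `multitaper_spectrogram()`
uses Slepian tapers (30-s window, 10-s step, 1 Hz bandwidth, hence
time-half-bandwidth 15 and 29 tapers); the tapers are computed from the
symmetric tridiagonal eigenproblem and memoised per geometry.

`irasa()` separates each spectrum into *fractal* (aperiodic, 1/f) and
*oscillatory* parts by irregular resampling: for each factor h in
1.10, 1.15, …, 1.90 (the method authors' default set), the signal is
resampled by h and by 1/h, the PSD of each is taken on the nominal
grid, and the pair is combined by geometric mean; the median across
factors estimates the fractal spectrum, which resampling leaves
invariant while oscillatory peaks are displaced and cancelled. The
oscillatory spectrum is defined as the residual `raw − fractal` in
linear power, so the decomposition identity is exact by construction
(and the oscillatory part may be legitimately negative in any one bin).

`fit_aperiodic()` fits `log P = intercept − slope · log f` by least
squares over 1–20 Hz by default — the lower edge avoids the high-pass
shoulder; the range is configurable. On a noiseless power law the fit
is exact; on 10-minute simulated 1/f background the slope is recovered
within a few hundredths for exponents 1–2. `peak_sigma_frequency()`
returns the frequency of maximum oscillatory power in 10–16 Hz; when no
bin in the band is positive (no sigma peak), it falls back to 13 Hz and
says so — the fallback keeps the downstream spindle detector defined
for low-sigma subjects.

`spectral_summary()` emits the 12 spectral measures per channel:
slow-delta power, sigma power and peak sigma frequency from the
oscillatory component of the z-scored signal (N2 and N3 separately),
and the aperiodic slope and intercept from the fractal component of
the raw signal (N2, N3 and REM separately). The slow-delta band
defaults to 0.25–1.5 Hz; parts of the literature use an upper edge of
1.25 Hz, so the band is a parameter. Surviving same-stage segments are
concatenated before estimation — the standard practice in sleep
spectral analysis; boundary transients are negligible at these segment
lengths — and a stage with under 60 s of surviving data yields `NA`
measures rather than unstable estimates.

## Spindle detection

Spindles are detected on the surviving N2+N3 signal by a
median-relative wavelet detector at an individualized centre frequency
(per subject and channel, from the peak sigma frequency; children and
adolescents at these ages typically show a single sigma peak, so no
fast/slow split is attempted).

The kernel is a complex frequency B-spline wavelet
ψ(t) = √fb · sinc(fb·t/m)^m · e^{2πi·fc·t} with order m = 2 and
bandwidth fb = 2, evaluated directly at the centre frequency fc. Read
this way the kernel has a fixed ±1 Hz spectral envelope (an order-2
B-spline) around fc — an appropriate spindle-band filter — whereas a
constant-Q rescaled mother wavelet would have a ±fc bandwidth and no
selectivity. The magnitude of the transform is smoothed with a 0.1-s
centred moving average.

Candidates are runs above 3× the median magnitude (median over the
whole analyzed signal, per channel — making detection exactly invariant
to amplitude rescaling), extended outward to the flanking 1.5× median
crossings. Two numerical details: candidates touching a segment edge
are discarded (their duration cannot be verified), and when a shared
secondary-threshold region would fuse two distinct main-threshold runs,
the extension is cut at the magnitude minimum between them — the
wavelet's ~1 s temporal support otherwise welds events ~2.5 s apart
into one overlong pseudo-candidate that the duration rule would then
delete, silently costing recall. Durations must lie in 0.5–3 s; events
separated by under 0.5 s are merged unless the merged span would exceed
3 s, in which case both are kept unmerged (discarding them would bias
density downward).

Each candidate must pass a band-ratio quality metric
(`spindle_quality()`): its sigma-band (10–16 Hz) power increase over
the whole-signal baseline PSD must exceed the mean of the delta (1–4),
theta (4–8) and beta (16–25 Hz) increases over theirs. For event
windows statistically identical to the baseline the strict inequality
fails in expectation; its empirical pass rate sits just under one half,
so the metric is a discriminator against non-sigma transients, not a
null-calibrated test.

Features: amplitude is the maximum consecutive peak-to-trough excursion
of the sigma-filtered signal (10–16 Hz linear-phase FIR, order 960,
applied with exact group-delay compensation); frequency is the
reciprocal of the mean interval between positive voltage peaks, with
parabolic sub-sample interpolation of each peak — at 128 Hz, integer
peak positions alone quantize frequency by about 0.1 Hz, which would
dominate the feature's error budget. Events with fewer than two
positive peaks keep their amplitude and report a missing frequency.

## Slow-wave detection

The signal is band-passed 0.25–4 Hz (Hamming-windowed sinc FIR, order
1536, zero-phase) per contiguous segment, and every negative half-wave
— positive-to-negative zero crossing to the next negative-to-positive
crossing — is enumerated. A candidate becomes a slow wave when its
trough depth exceeds 2× the median trough depth and its duration lies
in 0.5–2 s. This is deliberately liberal (no absolute amplitude
threshold), because absolute thresholds bias detection against older
children whose EEG amplitude is lower.

The reference median is computed over the *duration-eligible* (0.5–2 s)
half-waves. Sub-0.5-s noise ripples outnumber slow-wave-scale
half-waves several-fold and have far smaller troughs; pooling them
collapses the median and admits background half-waves wholesale
(measured: 7–20% of background half-waves pass, dozens of spurious
events per 10 minutes), while the duration-restricted median admits
about 0.1%. One consequence worth stating plainly: a median-relative
threshold assumes slow waves are a minority of the eligible half-waves.
When true waves approach half of the pool (very high densities), the
median migrates into the slow-wave amplitude cluster and detection
saturates — a pure sinusoid, where every half-wave equals the median,
yields no detections by the same logic.

The reported amplitude is the raw signal's peak negative deflection
inside the half-wave, not the filtered trough: the 0.25 Hz high-pass
removes an isolated half-wave's lowest-frequency content and would
understate its depth by 30–40%. Duration is measured between the
filtered-trace zero crossings, as defined.

## Spindle–slow-wave coupling

`sw_phase_series()` assigns each sample an instantaneous slow-wave
phase from the analytic (Hilbert) signal of the 0.25–4 Hz trace,
remapped so 0° is the positive-to-negative zero crossing, 90° the
trough, 180° the rising crossing and 270° the peak. With physiological
coupling just after the down-state, mean angles land around 10–30° in
this convention.

A spindle overlaps a slow wave when its peak lies within ±1.5 s of the
trough; a spindle in range of several waves goes to the nearest trough,
ties to the earlier one. From the phases θⱼ at paired spindle peaks,
`coupling_stats()` returns the mean resultant length
MRL = |mean e^{iθ}| and the mean angle arg(mean e^{iθ}).

Raw overlap and MRL are z-scored against shuffle nulls (1000 shuffles
by default, deterministic given a seed): the overlap null repositions
every spindle peak uniformly within its own 30-s epoch; the MRL null
repositions each paired peak uniformly within its host slow wave's
extent. The phrase "within the overlapping slow wave" could also mean
the ±1.5 s matching window; both are implemented
(`mrl_null_z(domain=)`), with the wave-extent reading as default.
Shuffled peaks landing where phase is undefined (segment edges) are
redrawn up to 100 times, then dropped from that shuffle. Degenerate
nulls (zero SD) and small samples (under 5 pairs) yield flagged `NA`
z-scores rather than infinities. Under a uniform-phase null the MRL
z-score is calibrated: across 100 synthetic null datasets its mean is
near 0 and its SD near 1.

`sw_locked_average()` and `sw_locked_scalogram()` provide trough-locked
views: the scalogram evaluates the same B-spline wavelet over 8–16 Hz
in a ±2 s window, z-scoring each frequency row against the 2–1.5 s
pre-trough baseline before averaging across waves; rows with zero
baseline SD are flagged missing.

## Circular and cluster statistics

`rayleigh_test()` tests phase uniformity via the resultant length with
the standard large-sample p approximation;
`watson_williams()` compares two samples' mean directions with the
concentration-corrected F statistic (correction 1 + 3/(8κ̂), κ̂ by
Fisher's approximation), warning when the pooled resultant falls below
0.45 — the test assumes concentrated samples. `cluster_correct()`
implements cluster-based permutation correction generically: supra-
threshold units (two-sided on |stat| by default) are clustered under a
supplied adjacency (chain adjacency over frequencies;
distance-based adjacency over 2-D electrode coordinates with a default
radius of 1.5× the median nearest-neighbour distance), cluster mass is
the sum of |stat|, and corrected p-values compare observed masses to
the permutation distribution of the maximum mass with the +1 convention
(no zero p-values). The per-unit statistic is an injected callback —
the default `unit_t_stats()` is a Welch t contrast of subject-level
values — because the correction machinery, not any particular
group-level model, is the reusable deliverable. The cluster-forming
threshold defaults to the two-sided α = 0.05 t quantile at the
available degrees of freedom and is configurable. Under a null with no
group difference the family-wise positive rate measures ~0.05 at 500
permutations.

## The synthetic generator: what it emulates, and what it does not

`simulate_recording()` builds recordings with known ground truth:

* a 1/f background (FFT-shaped white noise, amplitude ∝ f^(−β/2),
  shaping held flat below 0.25 Hz to avoid unbounded drifts, rescaled
  to a target RMS) — default exponent 1.5 and 5 µV RMS;
* slow-wave negative half-sines (default 8/min, log-normal amplitudes
  of mean 100 and SD 30 µV, durations uniform on 0.8–1.5 s) and
  Hann-enveloped sigma bursts (default 2/min, 13 Hz, 15 µV envelope,
  0.8–1.5 s), Poisson-placed in N2/N3 epochs only with a 1-s minimum
  same-type gap (infeasible densities raise an error naming the
  feasible maximum);
* coupling: a configurable fraction of spindles (default one half) has
  its peak placed at the sample, within ±1.5 s of a host trough, whose
  instantaneous phase of the noiseless filtered slow-wave train is
  nearest a von Mises draw (default μ = 30°, κ = 3; Best–Fisher
  sampler). Uncoupled spindles are placed away from slow waves by
  default, or uniformly (`sp_avoid_sw = FALSE`) when a chance-overlap
  null is wanted;
* artifact injection (`inject_artifact_epochs()`) for the four
  rejection fixtures: added 2 Hz or 20 Hz sinusoids, sample pinning at
  the channel extreme, and epoch-wise ×10 scaling.

Event amplitudes and densities are calibration choices of this
generator, not empirical claims: the source literature reports no
amplitude distributions for real events. The defaults are chosen so
that events are individually visible against the background — a
deliberately favourable signal-to-noise regime. Channels are
independent realizations; there is no volume conduction, no topography,
no K-complexes, no EOG/EMG/ECG, no stage-transition dynamics beyond the
scripted hypnogram, and real artifacts are not i.i.d. sinusoids.
Passing the recovery suite therefore shows the *algorithms* are
implemented correctly and calibrated under their stated assumptions; it
does not show that detection performance on clinical recordings will
match these figures.

Everything is deterministic given `seed`; with the seed fixed the whole
pipeline — `run_pipeline()` down to the written feature table — is
byte-identical across runs.

## Validation problem sizes

The test suite and the acceptance script use 10-minute single-channel
recordings for detector and rejection fixtures (10–20 seeds), one
80-minute recording for coupling recovery (~200+ coupled spindles), 100
synthetic null datasets for the MRL z calibration, and 100–200 null
runs at 500 permutations for the cluster correction's family-wise
error rate. These sizes give the recovery statistics standard errors
comfortably inside the asserted tolerances while keeping a full run in
the minutes range on one CPU.

## Known limitations

* The spectral pipeline assumes 128 Hz input; other rates are handled
  only through `condition_signal()`.
* Median-relative slow-wave detection saturates when slow waves
  dominate the eligible half-wave pool (see above), and the 0.25 Hz
  high-pass makes half-waves longer than ~2 s unrepresentable in the
  filtered trace, so the upper duration bound is rarely the binding
  constraint.
* The Watson–Williams test is only trustworthy for concentrated
  samples; the warning threshold follows standard practice.
* The quality metric's null pass rate is near one half by construction;
  it screens against non-sigma transients rather than controlling a
  false-positive rate.
* EDF support is plain 16-bit EDF with one rate across channels; EDF+
  annotations are out of scope, and hypnograms travel as sidecar text.
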