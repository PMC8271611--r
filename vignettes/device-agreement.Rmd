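---
title: "Quantifying between-device agreement of ECG-derived HRV features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying between-device agreement of ECG-derived HRV features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvagree)
```

## The problem

When a new, inexpensive ECG acquisition device is proposed for
psychophysiological research, the question is not whether its readings
*correlate* with those of a medical-grade amplifier but whether the two
instruments *agree*: can one be substituted for the other without changing
the derived physiological quantities? `hrvagree` implements the complete
analysis chain for answering that question on paired single-lead ECG
recordings — two devices recording the same heart simultaneously during a
blocked experimental session — together with a synthetic-data generator
that makes every stage testable against known ground truth.

The dependent variables are the standard short-term HRV set: heart rate
(HR, beats/min), the root mean square of successive RR differences (RMSSD,
ms), spectral power of the RR tachogram in the low-frequency
(LF, 0.04–0.15 Hz) and high-frequency (HF, 0.15–0.40 Hz) bands (ms²), and
their ratio LF/HF. The agreement statistics are the intraclass correlation
ICC(2,1) (two-way model, single measurement, absolute agreement) with its
F-based lower 95% confidence bound, and Bland–Altman limits of agreement
for repeated measurements.

## The synthetic session

Real paired recordings of this kind are rarely public, so the package
ships a generator whose defaults *are* the study conditions the analysis
is meant for: 23 participants, seven consecutive 300 s blocks (three
fixation baselines interleaved with four affective-picture blocks), two
simultaneously recording devices at 1000 Hz.

### RR process

One participant's heart rhythm is modelled as

$$RR(t) = \bar{RR} + a_{LF}\sin(2\pi\,0.1\,t) + a_{HF}\sin(2\pi\,0.25\,t)
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_j^2),$$

realized beat by beat (each interval evaluated at its own onset). Two
fixed-frequency sinusoids were chosen deliberately: every downstream
feature then has a closed form — a tone of amplitude $a$ contributes
$a^2/2$ ms² to its band, and the mean squared successive difference of a
sinusoid sampled every $T$ seconds is $2a^2\sin^2(\pi f T)$ — so the whole
pipeline can be validated by parameter recovery rather than by comparing
one estimator against another.

Defaults (all per-participant values in ms): mean HR 73.065 bpm with a
10.190 bpm between-subject SD, $a_{LF} = 72$, $a_{HF} = 41$,
$\sigma_j = 3$. At 73 bpm these give RMSSD $\approx$ 44 ms and LF/HF
$\approx$ 3.1, the magnitudes typical of seated picture-viewing sessions.
Conditions shift HR additively (pleasant $-0.44$, unpleasant $-1.55$
bpm relative to fixation); HRV amplitudes are condition-independent.

Two generator details are worth recording:

* **Beat-sampling compensation.** Beats sample the modulation
  preferentially where intervals are short, so a naive realization has a
  beat-averaged interval below $\bar{RR}$ by approximately
  $\mathrm{var}(\text{mod})/\bar{RR}$ (up to ~1 bpm at the default
  amplitudes). The base interval carries that second-order correction, so
  measured HR matches configured HR to within a few hundredths of a bpm.
* **Between-subject HRV dispersion.** Agreement statistics are driven by
  the ratio of between-row to residual variance, so the population must
  vary in more than mean HR. The LF and HF amplitudes are scaled
  per participant by independent log-normal factors (`amp_sdlog`, default
  0.4 on the log scale, mean 1), producing an RMSSD coefficient of
  variation of ~0.4 and an LF/HF spread comparable to what seated
  protocols report. Within-participant block-to-block HR varies with SD
  `block_hr_sd` (default 1 bpm) — a quantity rarely reported, exposed as a
  parameter rather than asserted.

### Device models

The shared waveform — a sum of Gaussian P-QRS-T bumps centred on the beat
times, R amplitude strictly the per-beat maximum — passes through each
device model: a zero-phase Butterworth band (BrainAmp-like preset
0.016–250 Hz; BITalino-like preset 0.5–40 Hz; 3rd order per edge), a
constant clock offset (drawn per participant from 19–28 ms for device B,
rounded to the nearest sample and recorded in the ground truth), white
measurement noise at a configurable SNR (study default 20 dB), and
motion-artifact bursts (0.5–2 s, 8× the R amplitude, a 4 Hz oscillation
under a half-sine envelope so the burst survives the analysis band;
default 0.2/min). Device filters are applied forward–backward so that the
clock offset is the *only* systematic timing difference between channels —
this isolates the alignment problem from filter phase lags.

What the generator does **not** emulate: real QRS morphology and its
inter-individual variation, respiratory sinus arrhythmia with drifting
frequency, ectopic beats, baseline wander correlated with movement, and
electrode-contact physics. Passing tests therefore demonstrate that the
*processing and statistics* are correct under the stated signal model, not
that any particular hardware pair agrees.

## The processing chain

Stage order per participant: provisional zero-phase band-pass (1–40 Hz,
3rd order) on both raw streams → R-peak detection → cross-device
alignment → artifact handling → final detection and beat correction →
block segmentation → features. Alignment precedes the main processing;
because the band-pass is zero-phase and the alignment shift is a whole
number of samples, the provisional filtered copies are reused afterwards
(filtering and integer shifts commute).

* **Detection.** Candidate peaks are local maxima of the positive-clipped
  squared signal above 0.4× the local squared-signal maximum (2 s tiles,
  neighbourhood max). A 480 ms refractory rule (125 bpm) keeps the larger
  of any violating pair; together with the 1500 ms gap cap (40 bpm) this
  implements the physiologic 40–125 bpm constraint.
* **Artifact flagging.** Artifact marking is automated (reproducibility
  over manual marking): the recording is tiled into 1 s windows, each
  summarised by its peak absolute deviation from the recording median,
  and windows exceeding 6 robust SDs (MAD across windows) above the
  median window amplitude are flagged and merged. The MAD is floored at
  5% of the median window amplitude because an ECG is spiky by
  construction — on a clean recording every window peaks at the R
  amplitude, the raw MAD collapses, and any per-sample robust score would
  flag the QRS complexes themselves. Flagged spans are replaced by a
  natural cubic spline through the four boundary samples on each side.
* **Beat correction.** Intervals under 480 ms drop the peak with smaller
  amplitude support. Intervals above 1500 ms, or above 1.5× the mean of
  the five preceding corrected intervals, are treated as missed beats and
  filled at that five-interval mean (evenly distributed across the gap,
  flagged `interpolated`). The 1.5× trigger is a design choice — the
  five-period mean defines the insertion *value*, not the missingness
  rule — and the absolute caps come from the allowed bpm range. The
  operation is idempotent.
* **Alignment.** For each reference-stream peak the nearest peak of the
  other stream within ±100 ms is its match (ties to the earlier peak,
  one-to-one, greedy in time order); the offset estimate is the mean
  matched difference, and the other stream is shifted by its negative,
  rounded to a sample. The estimator is exactly linear in an injected
  constant shift.

## Features and spectra

HR is defined through the mean interval (60000/mean RR) — robust to
partial intervals at block edges. RMSSD uses successive differences within
the block only. Spectra are computed on the tachogram: cubic-spline
resampling of the RR series onto a 4 Hz grid, mean removal, Welch
periodogram (Hann taper, 120 s segments, 50% overlap), band powers by
integrating the density over 0.04–0.15 / 0.15–0.40 Hz. The band edges
follow the short-term HRV convention and are configurable; blocks must
span 120 s for spectral features, hold at least 30 intervals to be usable
at all, and an HF power of exactly zero flags the ratio undefined (the
row is then dropped pairwise from agreement tables and counted).

Intervals are kept in ms and powers in ms² throughout; the output writer
offers a seconds-mode toggle (`units = "s"`) because published tables in
this area sometimes mix unit labels and magnitudes, and comparability
should not require touching the analysis code.

## Agreement statistics

**ICC(2,1).** From the two-way decomposition of the n×2 table
(rows = participant × block, columns = devices):
$$\widehat{ICC} = \frac{MS_R - MS_E}{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)},$$
with the F-based lower 95% bound using Satterthwaite degrees of freedom.
Negative estimates are reported as computed, not truncated. Two
conventional thresholds are evaluated: estimate > 0.90 (adequate for
clinical measurement) and lower bound > 0.75 (interchangeable use). A
table with zero total variance is degenerate and reported as 1 with a
flag; an error-free but non-constant table collapses the interval to the
estimate.

**Bland–Altman for repeated measurements.** Differences $d = B - A$ per
(participant, block); bias is the grand mean. Because the measured
quantity varies between blocks, the SD of differences combines within-
and between-subject components from a one-way ANOVA of $d$ on participant
(the repeated-measurements variant for a quantity that changes between
repeats), with the effective replicate count handling unbalance; when any
participant contributes fewer than two blocks the estimator falls back to
the classical pooled SD. LoA are bias ± 1.96 SD (multiplier
configurable), and the outside-LoA fraction is recomputed from the
returned limits. Normality of the differences is reported via
Shapiro–Wilk and Q-Q data, but the analysis proceeds with untransformed
differences regardless, recording the flag; a log-of-measurements option
exists (differences of logs, since differences themselves can be
negative — the sensible reading of "log-transformed differences").

## Numerical choices and degenerate inputs

* Timestamps are absolute ms from recording start; block membership is
  half-open (`[start, start+duration)`), so a boundary onset belongs to
  the later block; peak matching windows are closed.
* Zero-phase filtering means the effective attenuation is the squared
  one-pass Butterworth magnitude; the test suite checks this against the
  analytic $|H(f)|^2$ at 0.1 Hz to 5%.
* Welch segments of 120 s put the 0.1 and 0.25 Hz generator tones exactly
  on bin centres (df = 1/120 Hz), so leakage does not couple the bands.
* The degenerate zero-noise limit (identical acquisition chains) yields
  bit-identical streams, hence ICC exactly 1 and LoA width exactly 0. On
  a noise ladder (40/20/10 dB) the spectral LoA widths widen and ICCs
  fall monotonically; HR and RMSSD widths instead sit on a floor set by
  the 1 ms beat-time discretization — shrinking noise below ~40 dB cannot
  shrink them further.
* Constant signals produce an empty artifact mask with a warning; a mask
  covering more than half the recording aborts the participant with a
  recorded exclusion reason; every excluded (participant, block, device)
  appears in the exclusion table so that rows in = rows used + rows
  excluded for every output table.

## Problem sizes

The shipped tests validate operations on 1–5 minute signals and run the
full end-to-end replication (23 participants × 7 × 300 s blocks, both
devices, ~97 million samples) once; parameter recovery uses 100 seeded
300 s blocks; the ICC implementation is checked against a brute-force
sums-of-squares oracle on 1000 random tables and against an independent
Python implementation (pingouin) on a fixed table. Determinism is
asserted byte-for-byte on written result tables under a fixed seed.

## Known limitations

* The generator's two-tone RR model cannot probe estimator behaviour
  under drifting spectral peaks or nonstationary variance within a block.
* Artifact flagging is amplitude-based; low-amplitude waveform
  distortions (electrode repositioning, gain drift) would pass unflagged.
* The alignment model is a constant offset per participant; slow clock
  drift within a session is not estimated (the matched-peak differences
  in `alignment$differences_ms` would reveal it, but no correction is
  applied).
* XDF containers are not read; recordings are exchanged through the
  documented CSV dialect.
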