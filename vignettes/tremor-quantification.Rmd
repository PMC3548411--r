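---
title: "Quantifying pathological tremor from consumer accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pathological tremor from consumer accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorkit)
```

## The measurement problem

Pathological tremor — parkinsonian rest tremor, essential tremor, cerebellar
intention tremor — is an oscillation of a limb at roughly 3–10 Hz whose
amplitude fluctuates over minutes, hours and days. Clinical practice rates
it by eye on ordinal scales during short visits; a smartphone's built-in
accelerometer can instead sample it continuously, but a consumer sensor
(tens of Hz, coarse amplitude resolution, three electronically coupled
axes) is a very different instrument from a laboratory accelerometer
(kHz-rate, high resolution, single axis). `tremorkit` packages the full
validation workflow: the trial-level metrics, the statistics that compare
two instruments measuring the same trials, the amplitude-anchored clinical
scale, and a simulator that stands in for the original hardware experiment.

The recording protocol the package models is a battery of 10-s trials in
four tasks — rest (arm hanging), postural (arm outstretched), intention
(fingertips approaching) and kinetic (phone brought to the ear and back) —
with only the trailing 8.5 s analysed, so the hand-positioning transient is
excluded. At the 60 Hz phone rate that window is exactly
`floor(8.5 * 60) = 510` samples.

## The analysis chain

Each axis of a trial passes through:

1. **window extraction** — last `floor(keep_s * rate)` samples;
2. **demeaning** — removes the gravity projection;
3. optionally, **displacement conversion** (below), when amplitudes are
   needed in millimetres;
4. **metrics** — RMS amplitude; regularity (SD across the RMS of
   consecutive non-overlapping 1-s epochs of the z-normalized window — a
   trailing partial epoch is dropped, so an 8.5-s window contributes
   exactly 8 epochs); and the spectral set computed from the 1–20 Hz
   one-sided FFT power spectrum: the 3–7 Hz power percentage, median power
   frequency (MPF), peak frequency, the two 68% power-dispersion widths,
   and the harmonic index.

The FFT uses the raw rectangular window zero-padded to the next power of
two (512 for 510 samples, so the bin width is 60/512 ≈ 0.117 Hz). No taper
is applied at this stage: leakage is then deterministic and testable, and
every reported frequency-domain quantity refers to the same grid.

Numerical conventions that the definitions leave open are fixed as
follows, and the test suite pins each one against an independent
brute-force oracle:

* **MPF interpolation.** Each bin is treated as a uniform slab of width
  `df` centred on its frequency; the 50% crossing is located linearly
  inside the crossing bin and clamped to the band. Reported values are
  therefore continuous rather than multiples of `df`.
* **Dispersion growth.** The 68% band starts at the bin nearest the centre
  and grows one bin at a time, alternating sides starting with the lower
  side, clipping at the spectrum edges; the width is the distance between
  the outermost bin centres. "Centred" bands are therefore symmetric
  whenever the spectrum allows it, and the rule is deterministic.
* **Peak ties** resolve to the lowest frequency.
* **Harmonic index** uses the retained band as the rectangle width, which
  reduces to `1 - mean(power)/max(power)`: exactly 0 for a flat spectrum
  and `1 - 1/n` for a single occupied bin among `n`.
* **Degenerate inputs.** A zero-variance window yields regularity 0 with a
  warning; a zero-power spectrum is a hard error (never silent NaN); a
  sampling rate at or below 40 Hz cannot cover the 20 Hz band edge and is
  rejected.

## Acceleration to displacement

Clinically meaningful amplitude is displacement: the 1-mm exclusion
threshold and the centimetre-anchored clinical scale both live in
displacement units, while the sensor reports acceleration. The package
converts by frequency-domain double integration restricted to the 1–20 Hz
analysis band: each Fourier component at frequency `f` is divided by
`-(2*pi*f)^2`, out-of-band components are zeroed, and the inverse
transform is returned in mm. Band-limiting avoids the drift that makes
time-domain double integration unusable on short windows.

One numerical subtlety dominated the design: the `1/f^2` weighting
amplifies rectangular-window leakage near the 1 Hz band floor by up to
`f^4` in power, so a naive implementation misstates the RMS of a 5 Hz tone
by ~19% and of a 15 Hz tone by >100%. The implementation therefore applies
a Tukey taper (`alpha = 0.5`) before the transform and compensates the
taper's known RMS gain afterwards. For a single in-band tone this keeps
the displacement RMS within 1% of the analytic value across 2–15 Hz at
60 Hz sampling (measured worst case 0.66%); the conversion stays exactly
linear. The cost is that the first and last quarter of the returned series
are amplitude-shaped by the taper, so pointwise edge values are not
trustworthy — window-level statistics are. Mirror extension and
endpoint-matching detrending were evaluated and rejected: both inject
worse low-frequency leakage (phase-flip and sawtooth components
respectively) than they remove.

Whether the original on-device amplitude was computed on acceleration or
displacement is ambiguous in the source material; both pathways are
exposed (`characterize(pathway = "displacement" | "acceleration")`).
Displacement is the default because the threshold and the clinical scale
need millimetres. The algorithm-equivalence comparisons (device chain vs
independent offline recomputation of the same stored series) use the
acceleration pathway, where the two routes must agree to machine
precision.

## Cross-instrument comparison

The laboratory channel is downsampled to the phone rate before analysis,
using a centred moving average of `round(rate_in/rate_out)` samples as the
anti-alias stage followed by linear interpolation onto the exact output
grid — this handles the non-integer 2048/60 ratio while preserving
duration to within one output sample. The moving average has a sinc
roll-off (≈4.5% attenuation at 10 Hz for the 34-sample window), which is a
property of the comparison procedure, not of the sensors; for that reason
the simulator's channel-fidelity guarantee (the phone is never closer to
the generating truth than the laboratory channel) is stated and tested at
native rates.

Agreement between paired metric tables is summarised per metric and task
by Pearson r with its t-based p-value, Bland–Altman bias, SD of the
differences and 1.96-SD limits of agreement, and Lin's concordance
correlation coefficient with biased (1/n) moments, which penalises
location and scale shift and satisfies `|CCC| <= |r|`. Cells with fewer
than three surviving pairs are flagged insufficient rather than computed.
Thresholded tables recompute p-values on the reduced n. Inter-rater
reliability uses ICC(2,1) — two-way random effects, absolute agreement,
single rater — with the F-based 95% CI; this form is chosen because every
rater rates every trial and the validity question is absolute agreement,
not consistency. Contiguous-score comparisons use pooled-variance Student
t-tests (Welch available via `var_equal = FALSE`), Holm step-down
adjustment at family level 0.05, and post-hoc power from the noncentral t
at the observed effect size.

## The clinical scale

Scores 0–5 anchor to visible peak-to-peak excursion: 0 = no visible
tremor, then half-open bins `(0, 1.5]`, `(1.5, 3]`, `(3, 4.5]`,
`(4.5, 6]` cm and open-ended above 6 cm, so "up to 1.5 cm" includes the
boundary. The bridge from recorded RMS to judged excursion assumes a
sinusoidal oscillation, `excursion = 2*sqrt(2) * RMS`: what a rater sees
is peak-to-peak travel, what the device computes is RMS, and the sinusoid
factor is the only parameter-free link. For multi-axis recordings the
highest per-axis RMS is retained. During the kinetic task the slow
(< 3 Hz) voluntary movement dominates RMS, so the 3–7 Hz power percentage
substitutes as the severity marker; it rises with tremor power while
ignoring the voluntary component.

## What the simulator emulates — and what it does not

`synth_battery()` reproduces the validation battery: `n_per_task` trials
per task (default 48, i.e. 192 trials), each defined by a generative spec
drawn once from documented ranges and rendered through two channels from
the same movement (identical oscillation phases; independent sensor-noise
streams). The modeled hand displacement is a tremor tone with a slow
sinusoidal amplitude envelope and an optional second harmonic, plus, in
the kinetic task, a slow large voluntary oscillation. Acceleration is
derived term-wise as `-(2*pi*f)^2` times each displacement term (the
envelope is treated as constant within a cycle, consistent with
sub-1-Hz modulation rates).

Default ranges, chosen once to match the stated experimental conditions
("high variability in tremor amplitude and frequency"; trials straddling
both the 1 mm visibility threshold and the 6 cm scale ceiling):

| Parameter | Range | Why |
|---|---|---|
| tremor frequency | 3–10 Hz uniform | pathological tremor band |
| displacement RMS | 0.1–40 mm log-uniform | ~38% of trials below 1 mm; top of range exceeds the 6 cm excursion ceiling |
| modulation depth / rate | 0–0.3, 0.1–0.8 Hz | slow waxing-waning typical of real tremor |
| harmonic fraction | 0–0.2 | mild waveform asymmetry |
| movement noise SD | 0.005–0.02 m/s² | broadband background |
| voluntary amplitude / frequency | 15–50 mm RMS, 1–2 Hz | slow cm-scale phone-to-ear movement (kinetic only) |
| voluntary in-axis fraction | 0.1–0.4 | the trajectory is mostly perpendicular to the recorded front-back axis |

The two channel models carry the instrument physics. The laboratory
channel is 2048 Hz, quantization 1e-4 m/s², noise 1e-3 m/s². The phone
channel is 60 Hz with quantization step 4g/256 ≈ 0.153 m/s² (an
8-bit-class ±2 g MEMS part) and noise SD 0.05 m/s²; together these place
the phone's displacement-domain noise floor near 0.1 mm, so sub-millimetre
trials lose spectral fidelity while ≥1 mm trials retain it — which is
exactly the phenomenon the 1-mm threshold exists to handle, and the tests
verify that thresholding improves phone-vs-lab regularity and MPF
agreement in ≥9 of 10 seeded replicates. The phone additionally has an
axis-crosstalk fraction (0.15) through which it sees the off-axis part of
the voluntary movement, including harmonics of the direction reversals;
the single-axis laboratory channel does not. This is the mechanism that
degrades kinetic-task spectral agreement in the simulation, mirroring the
hypothesised cause in the original instrumentation study. Both phone
constants are deliberately surfaced in `default_run_config()` rather than
hard-coded.

A simulated rater perturbs the true excursion with Gaussian noise in
scale-step units (1 step = 1.5 cm) before binning, scoring 0 below the
0.1 cm visibility floor. One step of rater noise puts score-vs-amplitude
correlations in the 0.6–0.95 band on static tasks; five raters at half a
step give ICC(2,1) ≈ 0.91.

The simulator is a stated world, not a biophysical model: it contains no
neural oscillator dynamics, no reflex loops, no inter-axis mechanical
coupling, no end-of-trial vibration artifact, and its amplitude
distribution is a documented choice (no distribution was stated for the
original battery). A green test therefore establishes that the analysis
chain, the statistics and the threshold/crosstalk mechanisms behave as
specified under this world — it does not establish agreement levels for
any particular real device, nor reproduce numeric cells that derive from
the original human recordings.

## Known limitations

* Displacement edges: the Tukey taper makes the first/last quarter of a
  converted series unreliable pointwise (window-level statistics only).
* The moving-average downsampler attenuates the upper analysis band
  (sinc roll-off), a faithful property of the procedure it models.
* Regularity on the displacement pathway inherits the taper's envelope;
  comparisons between identically processed channels are unaffected.
* The clinical bridge assumes sinusoidal tremor; strongly harmonic
  waveforms bias the excursion estimate by up to ~20%.
* The CLI's config format is a flat key-value subset of YAML, by design.
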