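# tremorkit

Quantification of pathological tremor (Parkinson's disease, essential
tremor, and related disorders) from acceleration time series recorded with
consumer devices such as smartphones.

Clinicians rate tremor by eye on coarse ordinal scales during clinic
visits, while tremor amplitude fluctuates within a day. A phone's built-in
accelerometer can instead record tremor continuously — but a 60 Hz,
coarse-resolution consumer sensor must be validated against laboratory
instrumentation before its numbers mean anything. `tremorkit` implements
that validation workflow end to end, for researchers in movement disorders
and digital health:

* the preprocessing chain used for short tremor trials: trailing
  analysis-window extraction (last 8.5 s of a 10 s trial), demeaning to
  remove gravity, moving-average downsampling (e.g. 2048 Hz → 60 Hz), and
  band-limited frequency-domain double integration from acceleration
  (m/s²) to displacement (mm);
* the eight standard time/frequency-domain tremor metrics, computed from
  the 1–20 Hz power spectrum of one analysis window;
* method-agreement statistics: Pearson r, Bland–Altman bias and limits of
  agreement, Lin's concordance correlation coefficient (CCC), ICC(2,1)
  inter-rater reliability, and Holm-adjusted contiguous-score t-tests with
  post-hoc power;
* a 0–5 clinical rating scale anchored to visible tremor excursion in
  1.5 cm steps, and its comparison against recorded amplitude;
* a seeded synthetic tremor simulator that renders the same simulated
  movement simultaneously through a coarse "phone" channel (60 Hz,
  8-bit-class quantization, MEMS crosstalk) and a fine "laboratory"
  channel (2048 Hz), so the whole phone-vs-laboratory experiment can be
  reproduced without hardware.

## The metrics

For a demeaned window `x(t)` with one-sided power spectrum `P(f)`
restricted to 1–20 Hz:

| Metric | Definition |
|---|---|
| RMS | `sqrt(mean(x²))` — tremor amplitude (mm on the displacement pathway) |
| Regularity | SD of per-1-s-epoch RMS of the z-normalized window; lower = steadier |
| Pow.Dist | `100 · Σ_{3≤f≤7} P(f) / Σ P(f)` — % of power in the 3–7 Hz tremor band |
| MPF | median power frequency: `f` with half the power below it (within-bin interpolation) |
| Peak | frequency of the maximum-power bin (ties → lowest) |
| Disp. | width of the band centred at the MPF containing 68% of total power |
| Disp.Peak | same, centred at the peak frequency |
| HI | harmonic index `1 − mean(P)/max(P)`: 1 for a pure line, 0 for a flat spectrum |

Amplitude thresholding (trials with displacement RMS < 1 mm excluded, the
level at which tremor becomes clinically visible) is applied before
agreement analyses, and the clinical scale maps peak-to-peak excursion
`2√2 · RMS` onto scores 0–5 with 1.5 cm bins.

## Worked example

```r
library(tremorkit)

# one synthetic postural trial: 5.2 Hz tremor, 6 mm RMS displacement,
# rendered through the 60 Hz phone channel
spec  <- simulation_spec(tremor_freq = 5.2, displacement_amp = 6,
                         task = "postural", seed = 42)
phone <- synth_trial(spec, channel_model("phone"))
phone
#> <tremor_recording> postural_0042 | task=postural | 1 axes (x) | 600 samples @ 60 Hz (10.00 s)

characterize(phone)      # displacement pathway: RMS in mm
#>        trial_id     task axis  rms regularity pow_dist  mpf peak  disp disp_peak   hi
#> 1 postural_0042 postural    x 6.03      0.364     94.9 5.19 5.16 0.234     0.234 0.99
```

The recovered RMS (6.03 mm) and MPF (5.19 Hz) match the generating
parameters (6 mm, 5.2 Hz); 94.9% of power sits in the 3–7 Hz band and the
harmonic index 0.99 flags a nearly pure oscillation. The clinical mapping
gives `rms_to_excursion(6.03) = 1.7` cm → score 2 ("1.5–3 cm").

```r
# phone vs laboratory agreement over a 48-trial battery (12 per task),
# lab channel downsampled 2048 -> 60 Hz, 1-mm threshold applied
bat <- synth_battery(12, seed = 1)
res <- analyze_battery(bat)
agreement_table(res$phone, res$lab, metrics = c("rms", "mpf"),
                by_task = FALSE, threshold_mm = 1)
#>   metric task  n     r        p   bias    sd   ccc insufficient
#> 1    rms  all 37 0.983 1.67e-27 0.8282 2.122 0.980        FALSE
#> 2    mpf  all 37 0.995 1.88e-36 0.0504 0.293 0.995        FALSE
```

37 of 48 trials survive the 1-mm threshold; above it the phone tracks the
laboratory channel closely (r ≥ 0.98, CCC ≥ 0.98). The positive RMS bias
comes from the kinetic trials, where MEMS axis crosstalk inflates the
phone's amplitude — run with `by_task = TRUE` to see it isolated there.

A command-line interface wires the same steps into reproducible runs:

```sh
Rscript -e 'tremorkit::tremor_cli(commandArgs(TRUE))' simulate --seed 7 --out runs
Rscript -e 'tremorkit::tremor_cli(commandArgs(TRUE))' analyze runs/battery
Rscript -e 'tremorkit::tremor_cli(commandArgs(TRUE))' agree runs/battery/metrics_phone.csv runs/battery/metrics_lab.csv
```

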