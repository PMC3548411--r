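# Seeded synthetic tremor generator: renders the same simulated movement
# through a coarse "phone" channel and a fine "laboratory" channel.

#' Generative parameters of one synthetic tremor trial
#'
#' The modeled hand displacement (mm) is
#' `env(t) * [A1 sin(2 pi f t + p1) + A2 sin(4 pi f t + p2)] + voluntary(t)`
#' with a slow sinusoidal amplitude envelope
#' `env(t) = 1 + mod_depth * sin(2 pi mod_rate t + pm)`. `displacement_amp`
#' is the RMS displacement target of the tremor component; `harmonic_frac`
#' is the fraction of tremor power carried by the second harmonic. The
#' voluntary component (kinetic task only) is a slow (< 3 Hz) cm-scale
#' oscillation emulating the phone-to-ear movement.
#'
#' @param tremor_freq Tremor frequency in Hz, inside (1, 20), typically
#'   3-10.
#' @param displacement_amp Tremor RMS displacement in mm.
#' @param mod_depth Amplitude-modulation depth, proportion >= 0.
#' @param mod_rate Modulation rate in Hz, < 1.
#' @param harmonic_frac Power fraction at twice the tremor frequency, in
#'   [0, 1).
#' @param noise_sd Broadband movement/sensor acceleration noise SD (m/s^2).
#' @param voluntary_amp Voluntary-movement RMS displacement in mm (kinetic
#'   task; 0 otherwise). This is the magnitude of the whole phone-to-ear
#'   trajectory; only `voluntary_inaxis` of it projects onto the recorded
#'   front-back axis, the rest moves off-axis.
#' @param voluntary_freq Voluntary-movement frequency in Hz, < 3.
#' @param voluntary_inaxis Fraction of the voluntary trajectory along the
#'   recorded axis, in [0, 1].
#' @param duration_s Trial duration in seconds, >= 10.
#' @param task Task label.
#' @param seed Integer seed making the trial reproducible.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tremor_freq = 5, displacement_amp = 3,
                            mod_depth = 0.1, mod_rate = 0.3,
                            harmonic_frac = 0.05, noise_sd = 0.01,
                            voluntary_amp = 0, voluntary_freq = 1.2,
                            voluntary_inaxis = 0.25,
                            duration_s = 10, task = "rest", seed = 1L) {
  stopifnot(tremor_freq > 1, tremor_freq < 20,
            displacement_amp >= 0, mod_depth >= 0, mod_rate < 1,
            harmonic_frac >= 0, harmonic_frac < 1, noise_sd >= 0,
            voluntary_amp >= 0, voluntary_freq < 3,
            voluntary_inaxis >= 0, voluntary_inaxis <= 1, duration_s >= 10)
  task <- match.arg(task, TASKS)
  structure(list(tremor_freq = tremor_freq,
                 displacement_amp = displacement_amp,
                 mod_depth = mod_depth, mod_rate = mod_rate,
                 harmonic_frac = harmonic_frac, noise_sd = noise_sd,
                 voluntary_amp = voluntary_amp,
                 voluntary_freq = voluntary_freq,
                 voluntary_inaxis = voluntary_inaxis,
                 duration_s = duration_s, task = task,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Acquisition-channel model
#'
#' Describes how a sensor renders the underlying movement: sampling rate,
#' additive Gaussian sensor noise, and amplitude quantization (ADC
#' resolution). The default phone channel is a 60 Hz, 8-bit-class sensor
#' (quantization step 4 g / 256 ~ 0.153 m/s^2); the default laboratory
#' channel is a 2048 Hz high-resolution accelerometer.
#'
#' In a 3-axis MEMS chip a fraction of the off-axis acceleration leaks
#' electronically into the recorded axis (`crosstalk`); a one-axis
#' laboratory accelerometer has no such leakage. This matters during the
#' kinetic task, whose large voluntary movement has off-axis components.
#'
#' @param label `"phone"` or `"lab"`.
#' @param rate Sampling rate in Hz (> 40).
#' @param quant_step Acceleration resolution in m/s^2 (0 = continuous).
#' @param noise_sd Sensor noise SD in m/s^2.
#' @param crosstalk Off-axis leakage fraction in [0, 1].
#' @return Object of class `channel_model`.
#' @export
channel_model <- function(label = c("phone", "lab"), rate = NULL,
                          quant_step = NULL, noise_sd = NULL,
                          crosstalk = NULL) {
  label <- match.arg(label)
  defaults <- list(
    phone = list(rate = 60, quant_step = 4 * 9.80665 / 256, noise_sd = 0.05,
                 crosstalk = 0.15),
    lab   = list(rate = 2048, quant_step = 1e-4, noise_sd = 1e-3,
                 crosstalk = 0))[[label]]
  if (is.null(rate)) rate <- defaults$rate
  if (is.null(quant_step)) quant_step <- defaults$quant_step
  if (is.null(noise_sd)) noise_sd <- defaults$noise_sd
  if (is.null(crosstalk)) crosstalk <- defaults$crosstalk
  stopifnot(rate > 40, quant_step >= 0, noise_sd >= 0,
            crosstalk >= 0, crosstalk <= 1)
  structure(list(label = label, rate = rate, quant_step = quant_step,
                 noise_sd = noise_sd, crosstalk = crosstalk),
            class = "channel_model")
}

# displacement (mm) and exact term-wise acceleration (m/s^2) on a time grid;
# the slow envelope is treated as constant within each oscillation cycle
synth_movement <- function(spec, t, phases) {
  amp1 <- spec$displacement_amp * sqrt(2) * sqrt(1 - spec$harmonic_frac)
  amp2 <- spec$displacement_amp * sqrt(2) * sqrt(spec$harmonic_frac)
  env <- 1 + spec$mod_depth * sin(2 * pi * spec$mod_rate * t + phases[3L])
  f <- spec$tremor_freq
  acc <- -(2 * pi * f)^2 * env * amp1 * sin(2 * pi * f * t + phases[1L]) / 1000 -
    (4 * pi * f)^2 * env * amp2 * sin(4 * pi * f * t + phases[2L]) / 1000
  if (spec$task == "kinetic" && spec$voluntary_amp > 0) {
    av <- spec$voluntary_amp * spec$voluntary_inaxis * sqrt(2)
    fv <- spec$voluntary_freq
    acc <- acc - (2 * pi * fv)^2 * av * sin(2 * pi * fv * t + phases[4L]) / 1000
  }
  acc
}

# off-axis movement during the kinetic task: the phone-to-ear trajectory
# has components perpendicular to the recorded axis, with harmonics from
# the direction reversals; only crosstalk-affected channels see this
synth_offaxis <- function(spec, t, phases) {
  if (spec$task != "kinetic" || spec$voluntary_amp == 0)
    return(numeric(length(t)))
  fv <- spec$voluntary_freq
  gains <- c(1, 0.4, 0.15)  # fundamental + reversal harmonics
  off <- spec$voluntary_amp * sqrt(max(0, 1 - spec$voluntary_inaxis^2))
  acc <- 0
  for (k in 1:3) {
    ak <- off * sqrt(2) * gains[k]
    acc <- acc -
      (2 * pi * k * fv)^2 * ak * sin(2 * pi * k * fv * t + phases[4L + k]) / 1000
  }
  acc
}

#' Render one synthetic trial through an acquisition channel
#'
#' Samples the modeled movement at the channel rate, adds movement and
#' sensor noise, and quantizes to the channel resolution. The oscillation
#' phases are drawn from a stream seeded by `spec$seed` (identical across
#' channels, as both sensors observe the same movement); sensor-noise draws
#' are seeded independently per channel.
#'
#' @param spec A [simulation_spec()].
#' @param channel A [channel_model()].
#' @return A `tremor_recording` (single axis `"x"`), deterministic for a
#'   fixed spec.
#' @export
synth_trial <- function(spec, channel = channel_model("phone")) {
  n <- round(spec$duration_s * channel$rate)
  t <- (seq_len(n) - 1L) / channel$rate
  set.seed(spec$seed)
  phases <- stats::runif(7L, 0, 2 * pi)
  acc <- synth_movement(spec, t, phases)
  if (channel$crosstalk > 0)
    acc <- acc + channel$crosstalk * synth_offaxis(spec, t, phases)
  noise_sd <- sqrt(spec$noise_sd^2 + channel$noise_sd^2)
  if (noise_sd > 0) {
    set.seed((spec$seed + 7919L * match(channel$label, c("phone", "lab"))) %%
               2147483647L)
    acc <- acc + stats::rnorm(n, 0, noise_sd)
  }
  if (channel$quant_step > 0)
    acc <- round(acc / channel$quant_step) * channel$quant_step
  tremor_recording(acc, rate = channel$rate, axes = "x", task = spec$task,
                   trial_id = sprintf("%s_%04d", spec$task, spec$seed %% 10000L))
}

#' Default parameter ranges for the simulated battery
#'
#' Tremor frequency spans the pathological 3-10 Hz range; RMS amplitude is
#' log-uniform over 0.1-40 mm so the battery straddles both the 1 mm
#' visibility threshold and the 6 cm clinical-scale ceiling; the kinetic
#' task adds a slow cm-scale voluntary oscillation.
#'
#' @return Named list of 2-element ranges.
#' @export
default_sim_ranges <- function() {
  list(tremor_freq = c(3, 10), displacement_amp = c(0.1, 40),
       mod_depth = c(0, 0.3), mod_rate = c(0.1, 0.8),
       harmonic_frac = c(0, 0.2), noise_sd = c(0.005, 0.02),
       voluntary_amp = c(15, 50), voluntary_freq = c(1, 2),
       voluntary_inaxis = c(0.1, 0.4))
}

#' Generate a paired phone/laboratory trial battery
#'
#' Emulates the validation recording battery: `n_per_task` trials of each of
#' the four tasks with high between-trial variability in tremor amplitude
#' and frequency, each trial rendered simultaneously through the phone and
#' laboratory channels from a shared generative spec. Deterministic per
#' seed.
#'
#' @param n_per_task Trials per task (default 48, i.e. 192 trials).
#' @param seed Integer master seed.
#' @param ranges Parameter ranges as from [default_sim_ranges()];
#'   `displacement_amp` is drawn log-uniformly, everything else uniformly.
#' @param phone,lab Channel models.
#' @param tasks Tasks to simulate.
#' @return Object of class `tremor_battery`: list with `trials` (each a
#'   list `spec`, `phone`, `lab`) and `manifest` (data frame of trial_id,
#'   task and generative parameters — the ground truth for recovery tests).
#' @export
synth_battery <- function(n_per_task = 48, seed = 1L,
                          ranges = default_sim_ranges(),
                          phone = channel_model("phone"),
                          lab = channel_model("lab"),
                          tasks = TASKS) {
  stopifnot(n_per_task >= 1)
  for (rg in ranges)
    if (length(rg) != 2L || rg[2L] < rg[1L]) stop("degenerate parameter range")
  set.seed(seed)
  runifr <- function(rg) stats::runif(1L, rg[1L], rg[2L])
  trials <- list()
  rows <- list()
  i <- 0L
  for (task in tasks) for (k in seq_len(n_per_task)) {
    i <- i + 1L
    spec <- simulation_spec(
      tremor_freq = runifr(ranges$tremor_freq),
      displacement_amp = exp(runifr(log(ranges$displacement_amp))),
      mod_depth = runifr(ranges$mod_depth),
      mod_rate = runifr(ranges$mod_rate),
      harmonic_frac = runifr(ranges$harmonic_frac),
      noise_sd = runifr(ranges$noise_sd),
      voluntary_amp = if (task == "kinetic") runifr(ranges$voluntary_amp) else 0,
      voluntary_freq = runifr(ranges$voluntary_freq),
      voluntary_inaxis = runifr(ranges$voluntary_inaxis),
      task = task,
      seed = sample.int(2147483646L, 1L))
    ph <- synth_trial(spec, phone)
    lb <- synth_trial(spec, lab)
    id <- sprintf("%s_%03d", task, k)
    ph$trial_id <- lb$trial_id <- id
    trials[[i]] <- list(spec = spec, phone = ph, lab = lb)
    rows[[i]] <- data.frame(
      trial_id = id, task = task, tremor_freq = spec$tremor_freq,
      displacement_amp = spec$displacement_amp, mod_depth = spec$mod_depth,
      mod_rate = spec$mod_rate, harmonic_frac = spec$harmonic_frac,
      noise_sd = spec$noise_sd, voluntary_amp = spec$voluntary_amp,
      voluntary_freq = spec$voluntary_freq,
      voluntary_inaxis = spec$voluntary_inaxis, seed = spec$seed,
      stringsAsFactors = FALSE)
  }
  structure(list(trials = trials, manifest = do.call(rbind, rows)),
            class = "tremor_battery")
}

#' Analyze a simulated battery through both channels
#'
#' Runs the full metrics chain on every trial: the phone channel is
#' characterized directly at its native rate, while the laboratory channel
#' is first moving-average downsampled to the phone rate (the standard
#' cross-instrument comparison procedure) and then characterized.
#'
#' @param battery A `tremor_battery`.
#' @param pathway Metrics pathway, see [characterize()].
#' @param downsample_lab Downsample the lab channel to the phone rate before
#'   analysis (default `TRUE`).
#' @return List of two `tremor_metrics` data frames, `phone` and `lab`,
#'   row-aligned by trial.
#' @export
analyze_battery <- function(battery, pathway = "displacement",
                            downsample_lab = TRUE) {
  one <- function(rec, target_rate = NULL) {
    if (!is.null(target_rate) && rec$rate > target_rate) {
      y <- downsample_moving_average(rec$samples[, 1L], rec$rate, target_rate)
      rec <- tremor_recording(y, rate = target_rate, axes = rec$axes,
                              task = rec$task, trial_id = rec$trial_id)
    }
    characterize(rec, pathway = pathway)
  }
  phone_rate <- battery$trials[[1L]]$phone$rate
  ph <- do.call(rbind, lapply(battery$trials, function(tr) one(tr$phone)))
  lb <- do.call(rbind, lapply(battery$trials, function(tr)
    one(tr$lab, if (downsample_lab) phone_rate else NULL)))
  list(phone = ph, lab = lb)
}

#' Write a battery to disk
#'
#' One CSV pair per trial (`<id>_phone.csv`, `<id>_lab.csv`) plus a
#' `manifest.csv` holding the generative ground truth and file paths.
#'
#' @param battery A `tremor_battery`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_battery <- function(battery, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- battery$manifest
  man$phone_file <- paste0(man$trial_id, "_phone.csv")
  man$lab_file <- paste0(man$trial_id, "_lab.csv")
  for (tr in battery$trials) {
    write_recording(tr$phone, file.path(dir, paste0(tr$phone$trial_id, "_phone.csv")))
    write_recording(tr$lab, file.path(dir, paste0(tr$lab$trial_id, "_lab.csv")))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a battery written by [write_battery()]
#' @param dir Battery directory containing `manifest.csv`.
#' @return A `tremor_battery` (without generative `spec` objects).
#' @export
read_battery <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(man)), function(i) {
    list(spec = NULL,
         phone = read_recording(file.path(dir, man$phone_file[i]),
                                trial_id = man$trial_id[i]),
         lab = read_recording(file.path(dir, man$lab_file[i]),
                              trial_id = man$trial_id[i]))
  })
  structure(list(trials = trials, manifest = man), class = "tremor_battery")
}

#' Simulated clinical rater
#'
#' Applies the clinical scale to a true visible excursion perturbed by
#' Gaussian rater noise expressed in scale-step units (one step = the width
#' of the first bin). Perturbed excursions below the visibility floor
#' (1 mm = 0.1 cm, where tremor stops being clinically visible) score 0.
#'
#' @param true_excursion_cm True peak-to-peak excursion in cm (vectorized).
#' @param noise_sd_steps Rater noise SD in scale steps (>= 0).
#' @param seed Optional integer seed.
#' @param scale A [clinical_scale()].
#' @param visibility_cm Visibility floor in cm (default 0.1).
#' @return Integer score(s) in 0-5.
#' @export
synth_rater <- function(true_excursion_cm, noise_sd_steps = 0.5, seed = NULL,
                        scale = clinical_scale(), visibility_cm = 0.1) {
  stopifnot(noise_sd_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  step_cm <- scale$boundaries[1L]
  e <- true_excursion_cm +
    stats::rnorm(length(true_excursion_cm), 0, noise_sd_steps * step_cm)
  e <- pmax(e, 0)
  s <- score_from_amplitude(e, scale)
  s[e < visibility_cm] <- 0L
  s
}
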