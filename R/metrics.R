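# The eight time/frequency-domain tremor characteristics.

#' RMS amplitude of a demeaned window
#'
#' @param x Demeaned numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms_amplitude <- function(x) {
  if (length(x) < 1L) stop("empty window")
  sqrt(mean(x^2))
}

#' Tremor regularity
#'
#' Amplitude stability over time: the window is z-normalized (mean removed,
#' divided by SD), split into consecutive non-overlapping 1-s epochs (a
#' trailing partial epoch is dropped), the RMS of each epoch is taken, and
#' the SD across epoch RMS values is returned. A steadier tremor gives a
#' lower value.
#'
#' @param x Numeric window.
#' @param rate Sampling rate in Hz.
#' @return Non-negative scalar; 0 (with a warning) for a zero-variance
#'   window.
#' @export
regularity <- function(x, rate) {
  if (length(x) / rate < 2) stop("window must be at least 2 s for regularity")
  s <- stats::sd(x)
  if (s == 0) {
    warning("zero-variance window; regularity defined as 0")
    return(0)
  }
  z <- (x - mean(x)) / s
  per <- floor(rate)
  n_ep <- floor(length(z) / per)
  ep <- matrix(z[seq_len(n_ep * per)], nrow = per)
  stats::sd(sqrt(colMeans(ep^2)))
}

#' One-sided power spectrum restricted to the tremor band
#'
#' FFT power of the (already demeaned) window, zero-padded to the next power
#' of two, one-sided, with bins outside the 1-20 Hz tremor band discarded.
#' No taper is applied (rectangular window), so leakage behaviour is
#' deterministic. For a 510-sample window at 60 Hz the FFT length is 512 and
#' the bin width is 60/512 ~ 0.117 Hz.
#'
#' @param x Demeaned numeric window, length >= 2.
#' @param rate Sampling rate in Hz; must exceed 40 so the Nyquist frequency
#'   covers the 20 Hz band edge.
#' @param band Retained band in Hz, default `c(1, 20)`.
#' @return Object of class `tremor_spectrum` with fields `freqs`, `power`,
#'   `df`, `total_power`, `band`.
#' @export
power_spectrum <- function(x, rate, band = c(1, 20)) {
  if (length(x) < 2L) stop("window too short for a spectrum")
  if (rate <= 2 * band[2L])
    stop("sampling rate ", rate, " Hz puts Nyquist below the ", band[2L],
         " Hz band edge")
  nfft <- 2^ceiling(log2(length(x)))
  X <- stats::fft(c(x, rep(0, nfft - length(x))))
  df <- rate / nfft
  half <- seq_len(nfft %/% 2 + 1L)
  pw <- Mod(X[half])^2 / (nfft * rate)  # one-sided periodogram density
  pw[-c(1L, length(half))] <- 2 * pw[-c(1L, length(half))]
  fr <- (half - 1L) * df
  keep <- fr >= band[1L] - 1e-12 & fr <= band[2L] + 1e-12
  tremor_spectrum(fr[keep], pw[keep], df, band)
}

#' Construct a tremor spectrum object
#'
#' @param freqs Strictly increasing bin-centre frequencies (Hz).
#' @param power Non-negative power per bin.
#' @param df Bin width (Hz).
#' @param band The retained band (Hz).
#' @return `tremor_spectrum` object.
#' @export
tremor_spectrum <- function(freqs, power, df, band = range(freqs)) {
  if (length(freqs) != length(power)) stop("freqs/power length mismatch")
  if (any(power < 0)) stop("negative spectral power")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  structure(list(freqs = freqs, power = power, df = df,
                 total_power = sum(power), band = band),
            class = "tremor_spectrum")
}

#' @export
print.tremor_spectrum <- function(x, ...) {
  cat(sprintf("<tremor_spectrum> %d bins, %.4g-%.4g Hz, df=%.4g Hz, total power %.4g\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$df, x$total_power))
  invisible(x)
}

#' Percentage of power in a frequency band
#'
#' The 3-7 Hz band harbours the majority of power in most pathological
#' tremors; the fraction of total 1-20 Hz power falling there separates
#' tremor from voluntary movement (< 3 Hz) and noise.
#'
#' @param spec A `tremor_spectrum`.
#' @param band Two-element band in Hz, default `c(3, 7)` (inclusive).
#' @return Percentage in [0, 100].
#' @export
power_distribution <- function(spec, band = c(3, 7)) {
  if (spec$total_power <= 0) stop("zero total power")
  inb <- spec$freqs >= band[1L] - 1e-12 & spec$freqs <= band[2L] + 1e-12
  100 * sum(spec$power[inb]) / spec$total_power
}

#' Median power frequency
#'
#' The frequency below which half the spectral power lies. Each bin is
#' treated as a uniform slab of width `df` centred on its bin frequency and
#' the 50% crossing is located by linear interpolation inside the crossing
#' bin, giving a continuous value.
#'
#' @param spec A `tremor_spectrum`.
#' @return Frequency in Hz.
#' @export
median_power_frequency <- function(spec) {
  if (spec$total_power <= 0) stop("zero total power")
  target <- spec$total_power / 2
  cp <- cumsum(spec$power)
  k <- which(cp >= target)[1L]
  prev <- if (k == 1L) 0 else cp[k - 1L]
  f <- spec$freqs[k] - spec$df / 2 + spec$df * (target - prev) / spec$power[k]
  # slab edges of the outermost bins can poke just past the band; clamp
  min(max(f, spec$band[1L]), spec$band[2L])
}

#' Peak power frequency
#'
#' Frequency of the maximum-power bin; ties resolve to the lowest
#' frequency.
#'
#' @param spec A `tremor_spectrum`.
#' @return Frequency in Hz.
#' @export
peak_power_frequency <- function(spec) {
  if (spec$total_power <= 0) stop("zero total power")
  spec$freqs[which.max(spec$power)]
}

#' Power dispersion
#'
#' Width of the frequency band, centred at `center`, containing `fraction`
#' (default 68%) of total power. The band starts at the bin nearest the
#' centre and grows one bin at a time, alternating sides starting with the
#' lower side, clipping at the spectrum edges, until the contained power
#' first reaches the target. A sharply tuned tremor gives a narrow band.
#'
#' @param spec A `tremor_spectrum`.
#' @param center Centre frequency in Hz (typically the median or peak power
#'   frequency).
#' @param fraction Power fraction to enclose, default 0.68.
#' @return Band width `high - low` in Hz (distance between the outermost
#'   bin-centre frequencies; 0 if a single bin suffices).
#' @export
power_dispersion <- function(spec, center, fraction = 0.68) {
  if (spec$total_power <= 0) stop("zero total power")
  target <- fraction * spec$total_power
  k <- which.min(abs(spec$freqs - center))
  lo <- hi <- k
  acc <- spec$power[k]
  n <- length(spec$power)
  grow_low <- TRUE
  while (acc < target && (lo > 1L || hi < n)) {
    if (grow_low && lo > 1L) {
      lo <- lo - 1L
      acc <- acc + spec$power[lo]
    } else if (hi < n) {
      hi <- hi + 1L
      acc <- acc + spec$power[hi]
    } else {
      lo <- lo - 1L
      acc <- acc + spec$power[lo]
    }
    grow_low <- !grow_low
  }
  spec$freqs[hi] - spec$freqs[lo]
}

#' Harmonic index
#'
#' Spectral purity on [0, 1]: consider the rectangle whose width is the
#' retained frequency band and whose height is the maximum spectral power;
#' the harmonic index is the proportion of that rectangle's area lying above
#' the spectrum, i.e. `1 - mean(power) / max(power)`. A pure oscillation
#' approaches 1; a flat spectrum gives 0.
#'
#' @param spec A `tremor_spectrum`.
#' @return Proportion in [0, 1].
#' @export
harmonic_index <- function(spec) {
  if (spec$total_power <= 0) stop("zero total power")
  1 - mean(spec$power) / max(spec$power)
}

#' Full per-axis tremor characterization
#'
#' Runs the complete analysis chain on each axis of a recording: extract
#' the trailing analysis window, demean, optionally convert to band-limited
#' displacement (mm), then compute the eight tremor metrics. On the
#' displacement pathway RMS and regularity are computed on displacement and
#' the spectrum on the same displacement series; on the acceleration pathway
#' everything is computed on demeaned acceleration (RMS then in m/s^2).
#'
#' @param rec A `tremor_recording` admitting an 8.5-s window.
#' @param pathway `"displacement"` (default) or `"acceleration"`.
#' @param keep_s Analysis-window length in seconds (default 8.5).
#' @param band Spectral band, default `c(1, 20)` Hz.
#' @param dist_band Power-distribution band, default `c(3, 7)` Hz.
#' @param fraction Dispersion power fraction, default 0.68.
#' @return A data frame of class `tremor_metrics`, one row per axis, with
#'   columns `trial_id`, `task`, `axis`, `rms`, `regularity`, `pow_dist`,
#'   `mpf`, `peak`, `disp`, `disp_peak`, `hi`.
#' @export
characterize <- function(rec, pathway = c("displacement", "acceleration"),
                         keep_s = 8.5, band = c(1, 20), dist_band = c(3, 7),
                         fraction = 0.68) {
  pathway <- match.arg(pathway)
  win <- extract_analysis_window(rec, keep_s = keep_s)
  rows <- lapply(seq_along(win$axes), function(j) {
    x <- demean(win$samples[, j])
    if (pathway == "displacement")
      x <- to_displacement(x, win$rate, band = band,
                           source_axis = win$axes[j])$values
    spec <- power_spectrum(x, win$rate, band = band)
    if (spec$total_power <= 0)
      stop("zero total power on axis ", win$axes[j], " of ", win$trial_id)
    mpf <- median_power_frequency(spec)
    pk <- peak_power_frequency(spec)
    data.frame(
      trial_id = win$trial_id, task = win$task, axis = win$axes[j],
      rms = rms_amplitude(x),
      regularity = regularity(x, win$rate),
      pow_dist = power_distribution(spec, band = dist_band),
      mpf = mpf, peak = pk,
      disp = power_dispersion(spec, mpf, fraction = fraction),
      disp_peak = power_dispersion(spec, pk, fraction = fraction),
      hi = harmonic_index(spec),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tremor_metrics", "data.frame")
  out
}

METRIC_COLUMNS <- c("rms", "regularity", "pow_dist", "mpf", "peak",
                    "disp", "disp_peak", "hi")

#' Write a metrics table as CSV
#'
#' One row per (trial, axis) with fixed, documented column order:
#' `trial_id, task, axis` followed by the eight metrics. Rows are sorted by
#' `(trial_id, axis)` so output is deterministic.
#'
#' @param metrics A `tremor_metrics` data frame (rows from [characterize()]
#'   may be `rbind`-ed across trials).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("trial_id", "task", "axis", METRIC_COLUMNS)
  stopifnot(all(cols %in% names(metrics)))
  m <- as.data.frame(metrics)[, cols]
  m <- m[order(m$trial_id, m$axis), ]
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#' @param path CSV path.
#' @return A `tremor_metrics` data frame.
#' @export
read_metrics <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "task", "axis", METRIC_COLUMNS) %in% names(m)))
  class(m) <- c("tremor_metrics", "data.frame")
  m
}
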