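# Independent oracles and shared fixtures, built in code.

# random spectrum on a 1-20 Hz grid; exponential power plus an optional peak
rand_spectrum <- function(nbins = 163, peaked = runif(1) < 0.5) {
  df <- 19 / (nbins - 1)
  freqs <- seq(1, 20, length.out = nbins)
  power <- stats::rexp(nbins)
  if (peaked) {
    k <- sample.int(nbins, 1L)
    power[k] <- power[k] + stats::rexp(1L, rate = 1 / (10 * nbins))
  }
  tremor_spectrum(freqs, power, df)
}

# brute-force MPF: walk bins treating each as a uniform slab of width df
oracle_mpf <- function(spec) {
  half <- spec$total_power / 2
  run <- 0
  for (k in seq_along(spec$power)) {
    if (run + spec$power[k] >= half) {
      frac <- (half - run) / spec$power[k]
      return(spec$freqs[k] - spec$df / 2 + frac * spec$df)
    }
    run <- run + spec$power[k]
  }
  spec$freqs[length(spec$freqs)]
}

# integrate power strictly below frequency f under the same slab convention
oracle_power_below <- function(spec, f) {
  tot <- 0
  for (k in seq_along(spec$power)) {
    lo <- spec$freqs[k] - spec$df / 2
    hi <- spec$freqs[k] + spec$df / 2
    if (f >= hi) tot <- tot + spec$power[k]
    else if (f > lo) tot <- tot + spec$power[k] * (f - lo) / spec$df
  }
  tot
}

# dispersion by explicit stepwise simulation of the symmetric growth rule:
# start at the bin nearest the centre, then take bins lower, upper, lower,
# ... (clipped at the edges) until the enclosed power reaches the target
oracle_dispersion <- function(spec, center, fraction = 0.68) {
  n <- length(spec$power)
  k <- order(abs(spec$freqs - center))[1L]
  picked <- k
  turn <- "low"
  while (sum(spec$power[picked]) < fraction * spec$total_power &&
         length(picked) < n) {
    lo <- min(picked); hi <- max(picked)
    cand_low <- if (lo > 1L) lo - 1L else NA
    cand_high <- if (hi < n) hi + 1L else NA
    nxt <- if (turn == "low" && !is.na(cand_low)) cand_low
           else if (!is.na(cand_high)) cand_high
           else cand_low
    picked <- c(picked, nxt)
    turn <- if (turn == "low") "high" else "low"
  }
  max(spec$freqs[picked]) - min(spec$freqs[picked])
}

oracle_hi <- function(spec) {
  rect_area <- max(spec$power) * length(spec$power) * spec$df
  1 - sum(spec$power) * spec$df / rect_area
}

# sinusoid acceleration recording whose band-limited displacement RMS is
# `amp_mm` (single tone at f Hz)
tone_recording <- function(f, amp_mm, rate = 60, dur = 10, phase = 0.7,
                           task = "rest") {
  t <- (seq_len(round(dur * rate)) - 1L) / rate
  a <- (2 * pi * f)^2 * amp_mm * sqrt(2) / 1000 * sin(2 * pi * f * t + phase)
  tremor_recording(a, rate = rate, task = task, trial_id = "tone")
}

# shared battery cache so the heavier tests reuse one simulation
.battery_cache <- new.env(parent = emptyenv())
test_battery <- function(n_per_task = 48, seed = 11) {
  key <- paste0("b", n_per_task, "_", seed)
  if (is.null(.battery_cache[[key]])) {
    bat <- synth_battery(n_per_task, seed = seed)
    .battery_cache[[key]] <- list(bat = bat, res = analyze_battery(bat))
  }
  .battery_cache[[key]]
}
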