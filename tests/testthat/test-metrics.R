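test_that("rms_amplitude matches closed forms", {
  t <- (0:599) / 60
  x <- 2.4 * sin(2 * pi * 5 * t)   # 50 full cycles
  expect_equal(rms_amplitude(x), 2.4 / sqrt(2), tolerance = 0.01)
  expect_equal(rms_amplitude(rep(0, 10)), 0)
  expect_equal(rms_amplitude(c(3, -3, 3, -3)), 3)
  expect_error(rms_amplitude(numeric(0)), "empty")
})

test_that("regularity follows the 1-s epoch definition", {
  rate <- 60
  t <- (0:509) / rate
  # integer cycles per epoch -> identical epochs -> near-zero SD
  x <- sin(2 * pi * 3 * t)
  expect_lt(regularity(x, rate), 0.01)

  # epochs alternating gain 1 and 3: compare to an explicit hand oracle
  gains <- rep(c(1, 3), each = rate, times = 4)  # 8 epochs
  y <- gains * sin(2 * pi * 3 * (0:479) / rate)
  hand <- {
    z <- (y - mean(y)) / sd(y)
    ep_rms <- sapply(0:7, function(k) {
      seg <- z[(k * rate + 1):((k + 1) * rate)]
      sqrt(sum(seg^2) / rate)
    })
    sd(ep_rms)
  }
  expect_equal(regularity(y, rate), hand)

  # 8.5 s at 60 Hz: exactly 8 epochs, the trailing 0.5 s never enters the
  # epoch stage (only the global normalization)
  w <- sin(2 * pi * 3 * t)
  oracle <- {
    z <- (w - mean(w)) / sd(w)
    ep_rms <- sapply(0:7, function(k)
      sqrt(mean(z[(k * rate + 1):((k + 1) * rate)]^2)))
    sd(ep_rms)
  }
  expect_equal(regularity(w, rate), oracle)

  expect_warning(r0 <- regularity(rep(1, 510), rate), "zero-variance")
  expect_equal(r0, 0)
  expect_error(regularity(1:50, 60), "at least 2 s")
})

test_that("power_spectrum concentrates tones and enforces preconditions", {
  rate <- 60; t <- (0:509) / rate
  sp <- power_spectrum(demean(sin(2 * pi * 5 * t)), rate)
  expect_s3_class(sp, "tremor_spectrum")
  expect_equal(sp$df, 60 / 512)
  expect_true(all(sp$freqs >= 1 & sp$freqs <= 20))
  expect_equal(sp$total_power, sum(sp$power))
  k <- which.min(abs(sp$freqs - 5))
  expect_gt(sum(sp$power[(k - 3):(k + 3)]) / sp$total_power, 0.95)

  set.seed(2)
  spn <- power_spectrum(demean(rnorm(510)), rate)
  expect_gt(spn$total_power, 0)
  expect_true(all(spn$power >= 0))

  two <- demean(sin(2 * pi * 4 * t) + sin(2 * pi * 10 * t))
  sp2 <- power_spectrum(two, rate)
  k4 <- which.min(abs(sp2$freqs - 4)); k10 <- which.min(abs(sp2$freqs - 10))
  p4 <- sum(sp2$power[(k4 - 3):(k4 + 3)])
  p10 <- sum(sp2$power[(k10 - 3):(k10 + 3)])
  expect_equal(p4 / p10, 1, tolerance = 0.05)

  expect_error(power_spectrum(rnorm(100), 40), "Nyquist")
})

test_that("power_distribution separates tremor-band from out-of-band tones", {
  rate <- 60; t <- (0:509) / rate
  expect_gte(power_distribution(power_spectrum(demean(sin(2 * pi * 5 * t)), rate)), 95)
  expect_lte(power_distribution(power_spectrum(demean(sin(2 * pi * 10 * t)), rate)), 5)

  sp <- rand_spectrum()
  expect_equal(power_distribution(sp, band = c(1, 20)), 100)
  inside <- tremor_spectrum(seq(3, 7, by = 0.1), rexp(41), 0.1)
  expect_equal(power_distribution(inside), 100)
})

test_that("median/peak frequency and dispersion match brute-force oracles", {
  # symmetric spectrum about 5 Hz
  fr <- seq(3, 7, by = 0.25)
  pw <- dnorm(fr, 5, 0.8)
  spc <- tremor_spectrum(fr, pw, 0.25)
  expect_equal(median_power_frequency(spc), 5, tolerance = 0.25)

  one <- tremor_spectrum(seq(1, 20, by = 0.5), c(rep(0, 10), 1, rep(0, 28)), 0.5)
  expect_equal(median_power_frequency(one), 6, tolerance = 0.5)
  expect_equal(peak_power_frequency(one), 6)
  expect_lte(power_dispersion(one, 6), 2 * 0.5)

  tie <- tremor_spectrum(c(4, 6, 9), c(1, 0.5, 1), 1)
  expect_equal(peak_power_frequency(tie), 4)

  # uniform spectrum: 68% band about the middle approximates 0.68 * span
  nu <- 191
  uni <- tremor_spectrum(seq(1, 20, length.out = nu), rep(1, nu), 19 / (nu - 1))
  expect_equal(power_dispersion(uni, 10.5), 0.68 * 19, tolerance = 2 * uni$df)

  set.seed(42)
  for (i in 1:200) {
    sp <- rand_spectrum(nbins = sample(10:200, 1))
    expect_lte(abs(median_power_frequency(sp) - oracle_mpf(sp)), sp$df)
    expect_equal(peak_power_frequency(sp), sp$freqs[which.max(sp$power)])
    ctr <- runif(1, 1, 20)
    expect_equal(power_dispersion(sp, ctr), oracle_dispersion(sp, ctr))
  }
})

test_that("harmonic index spans flat to single-peak and is scale invariant", {
  flat <- tremor_spectrum(seq(1, 20, by = 1), rep(2, 20), 1)
  expect_equal(harmonic_index(flat), 0)

  n <- 37
  single <- tremor_spectrum(seq(1, 20, length.out = n),
                            c(rep(0, 20), 5, rep(0, n - 21)), 19 / (n - 1))
  expect_equal(harmonic_index(single), 1 - 1 / n)

  set.seed(9)
  for (i in 1:50) {
    sp <- rand_spectrum()
    expect_equal(harmonic_index(sp), oracle_hi(sp), tolerance = 1e-9)
    sc <- tremor_spectrum(sp$freqs, sp$power * 37.5, sp$df)
    expect_equal(harmonic_index(sc), harmonic_index(sp))
  }
})

test_that("characterize runs the full chain and recovers simulated tremor", {
  spec <- simulation_spec(tremor_freq = 5, displacement_amp = 3, seed = 31)
  rec <- synth_trial(spec, channel_model("lab"))
  m <- characterize(rec)
  expect_s3_class(m, "tremor_metrics")
  expect_equal(m$rms, 3, tolerance = 0.05)
  expect_equal(m$mpf, 5, tolerance = 0.3)
  expect_gt(m$pow_dist, 90)

  # determinism
  expect_identical(m, characterize(rec))

  zero <- tremor_recording(rep(0, 600), rate = 60)
  expect_error(characterize(zero), "zero total power")
})

test_that("metrics invariants hold on every simulator draw", {
  set.seed(123)
  n_draws <- 1000
  for (i in seq_len(n_draws)) {
    spec <- simulation_spec(
      tremor_freq = runif(1, 3, 10),
      displacement_amp = exp(runif(1, log(0.1), log(40))),
      mod_depth = runif(1, 0, 0.3), mod_rate = runif(1, 0.1, 0.8),
      harmonic_frac = runif(1, 0, 0.2), noise_sd = runif(1, 0.005, 0.02),
      task = sample(c("rest", "postural", "kinetic", "intention"), 1),
      voluntary_amp = 30, seed = sample.int(2^31 - 2, 1))
    m <- characterize(synth_trial(spec, channel_model("phone")))
    ok <- m$pow_dist >= 0 && m$pow_dist <= 100 &&
      m$mpf >= 1 && m$mpf <= 20 && m$peak >= 1 && m$peak <= 20 &&
      m$hi >= 0 && m$hi <= 1 && m$disp >= 0 && m$disp_peak >= 0 &&
      m$rms >= 0 && m$regularity >= 0
    if (!ok) fail(sprintf("invariant violated at draw %d", i))
  }
  succeed()
})

test_that("computed MPF tracks generated tremor frequency on static tasks", {
  tb <- test_battery()
  man <- tb$bat$manifest
  lb <- tb$res$lab
  s <- man$task != "kinetic" & lb$rms >= 1
  expect_gt(cor(man$tremor_freq[s], lb$mpf[s]), 0.95)
})

test_that("metrics writer/reader round-trips with fixed column order", {
  d <- withr::local_tempdir()
  tb <- test_battery()
  p <- file.path(d, "m.csv")
  write_metrics(tb$res$phone[1:10, ], p)
  got <- read_metrics(p)
  expect_equal(names(got)[1:3], c("trial_id", "task", "axis"))
  expect_equal(got$rms, tb$res$phone$rms[1:10], tolerance = 1e-12)
})
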