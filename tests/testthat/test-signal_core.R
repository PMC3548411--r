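test_that("recording reader handles columns, headers, units and errors", {
  d <- withr::local_tempdir()

  p3 <- file.path(d, "three.csv")
  writeLines(c("# rate=60 task=postural axes=x,y,z",
               apply(matrix(round(rnorm(1800), 4), ncol = 3), 1,
                     paste, collapse = ",")), p3)
  rec <- read_recording(p3)
  expect_s3_class(rec, "tremor_recording")
  expect_equal(dim(rec$samples), c(600L, 3L))
  expect_equal(rec$rate, 60)
  expect_equal(rec$task, "postural")
  expect_equal(recording_duration(rec), 10)

  p1 <- file.path(d, "zeros.csv")
  writeLines(format(rep(0, 120)), p1)
  rec1 <- read_recording(p1, rate = 60)
  expect_equal(rms_amplitude(demean(rec1$samples[, 1])), 0)

  pna <- file.path(d, "bad.csv")
  writeLines(c("0.1,0.2", "0.3,NaN", "0.5,0.6"), pna)
  expect_error(read_recording(pna, rate = 60), "row 2")

  p4 <- file.path(d, "wide.csv")
  writeLines(c("1,2,3,4,5"), p4)
  expect_error(read_recording(p4, rate = 60), "1-3")

  # explicit time column: inferred rate, and a non-uniform stamp is fatal
  pt <- file.path(d, "timed.csv")
  tt <- (0:99) / 50
  writeLines(paste(tt, round(sin(tt), 6), sep = ","), pt)
  rt <- read_recording(pt)
  expect_equal(rt$rate, 50)
  expect_equal(ncol(rt$samples), 1L)
  tt2 <- tt; tt2[41] <- tt2[41] + 0.01
  writeLines(paste(tt2, round(sin(tt), 6), sep = ","), pt)
  expect_error(read_recording(pt), "non-uniform timestamps")

  pg <- file.path(d, "gunits.csv")
  writeLines(c("0.5", "-0.5", "0.25", "0"), pg)
  rg <- read_recording(pg, rate = 60, unit = "g")
  expect_equal(unname(rg$samples[1, 1]), 0.5 * 9.80665)
})

test_that("recording writer round-trips at 9 significant digits", {
  d <- withr::local_tempdir()
  set.seed(4)
  rec <- tremor_recording(matrix(rnorm(300), ncol = 3), rate = 60,
                          task = "intention", trial_id = "rt")
  p <- file.path(d, "rt.csv")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_equal(back$samples, rec$samples, tolerance = 1e-8)
  expect_equal(back$task, "intention")
  expect_equal(back$axes, c("x", "y", "z"))
  # writing the re-read recording reproduces the file byte-for-byte
  p2 <- file.path(d, "rt2.csv")
  write_recording(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("analysis-window extraction keeps the trailing floor(keep_s*rate)", {
  rec <- tremor_recording(seq_len(600), rate = 60)
  win <- extract_analysis_window(rec)
  expect_equal(nrow(win$samples), 510L)
  expect_equal(win$samples[, 1], 91:600)
  expect_equal(win$task, rec$task)

  # keep the full duration -> identity; re-extraction -> idempotent
  full <- extract_analysis_window(rec, keep_s = 10)
  expect_equal(full$samples, rec$samples)
  expect_equal(extract_analysis_window(win)$samples, win$samples)

  short <- tremor_recording(seq_len(100), rate = 60)
  expect_error(extract_analysis_window(short), "1.667 s available")
})

test_that("demean is exact and idempotent", {
  expect_equal(demean(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(demean(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(510, mean = 3)
  expect_lt(abs(mean(demean(x))), 1e-12 * sd(x))
  expect_equal(demean(demean(x)), demean(x))
  expect_error(demean(numeric(0)), "empty")
})

test_that("moving-average downsampling preserves constants, duration and DC", {
  expect_equal(downsample_moving_average(rep(2.5, 2048), 2048, 60),
               rep(2.5, 60))
  y <- downsample_moving_average(rnorm(round(8.5 * 2048)), 2048, 60)
  expect_length(y, 510L)

  # DC + 1000 Hz tone: the 34-sample average must kill the tone (> 20 dB)
  t <- (0:(2048 * 4 - 1)) / 2048
  x <- 1 + sin(2 * pi * 1000 * t)
  y <- downsample_moving_average(x, 2048, 60)
  resid <- y - 1
  expect_lt(sqrt(mean(resid^2)), (1 / sqrt(2)) * 10^(-20 / 20))

  expect_error(downsample_moving_average(1:10, 60, 60), "rate_out")
})

test_that("displacement conversion matches the analytic double integral", {
  rate <- 60; t <- (0:509) / rate
  f <- 5
  a <- (2 * pi * f)^2 * 0.001 * sin(2 * pi * f * t + 0.3)
  d <- to_displacement(demean(a), rate)
  expect_s3_class(d, "displacement_series")
  # 1 mm amplitude tone -> RMS 1/sqrt(2) mm
  expect_equal(sqrt(mean(d$values^2)), 1 / sqrt(2), tolerance = 0.01)
  expect_lt(abs(mean(d$values)), 1e-9 * sd(d$values))

  expect_equal(to_displacement(rep(0, 510), rate)$values, rep(0, 510))

  # two-tone input: the tones keep their 1/(2 pi f)^2 amplitude ratio,
  # checked by projecting onto the quadrature basis of each frequency in
  # the untapered centre of the window
  a2 <- 2.0 * sin(2 * pi * 5 * t + 1.1) + 3.0 * sin(2 * pi * 8 * t + 0.2)
  d2 <- to_displacement(demean(a2), rate)$values
  basis <- cbind(sin(2 * pi * 5 * t), cos(2 * pi * 5 * t),
                 sin(2 * pi * 8 * t), cos(2 * pi * 8 * t))
  mid <- 150:360
  co <- coef(lm(d2[mid] ~ basis[mid, ] - 1))
  amp5 <- sqrt(sum(co[1:2]^2)); amp8 <- sqrt(sum(co[3:4]^2))
  expect_equal(amp5 / amp8,
               (2.0 / (2 * pi * 5)^2) / (3.0 / (2 * pi * 8)^2),
               tolerance = 0.02)

  expect_error(to_displacement(a, rate, band = c(0, 20)), "band low edge")
})

test_that("displacement conversion is linear and accurate across 2-15 Hz", {
  rate <- 60; t <- (0:509) / rate
  set.seed(7)
  x <- rnorm(510); y <- rnorm(510)
  dxy <- to_displacement(x + y, rate)$values
  expect_equal(dxy, to_displacement(x, rate)$values +
                 to_displacement(y, rate)$values, tolerance = 1e-10)

  for (f in c(2, 3, 5, 7.3, 8, 11.11, 12, 15)) {
    a <- (2 * pi * f)^2 * 0.001 * sin(2 * pi * f * t + 1.9)
    got <- sqrt(mean(to_displacement(demean(a), rate)$values^2))
    expect_lt(abs(got / (1 / sqrt(2)) - 1), 0.01)
  }
})

test_that("amplitude threshold is inclusive at the boundary", {
  expect_false(passes_amplitude_threshold(0.99, 1.0))
  expect_true(passes_amplitude_threshold(1.0, 1.0))
  expect_true(all(passes_amplitude_threshold(c(0, 0.5, 10), 0)))
  expect_error(passes_amplitude_threshold(1, -1), ">= 0")
})
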