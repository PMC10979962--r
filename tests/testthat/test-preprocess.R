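tone <- function(f, fs, dur, amp = 1, phase = 0) {
  amp * cos(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs) + phase)
}

test_that("downsampling preserves theta content and validates rates", {
  fs <- 25000
  s <- signal_session(list(tone(8, fs, 4)), fs, layers = "Pyr")
  d <- downsample(s, 1000)
  expect_equal(d$fs, 1000)
  expect_equal(ncol(d$samples), 4000)
  # spectral peak stays at 8 Hz
  sp <- Mod(fft(d$samples[1, ]))[1:2000]
  fpk <- (which.max(sp) - 1) / 4
  expect_lt(abs(fpk - 8), 0.1)
  # amplitude essentially preserved
  expect_equal(sd(d$samples[1, 500:3500]), sd(s$samples[1, ]), tolerance = 0.02)

  s1k <- signal_session(list(tone(8, 1000, 2)), 1000, layers = "Pyr")
  expect_identical(downsample(s1k, 1000), s1k)
  s500 <- signal_session(list(tone(8, 500, 2)), 500, layers = "Pyr")
  expect_error(downsample(s500, 1000), "downsample")
})

test_that("notch60 removes line noise but spares theta", {
  fs <- 1000
  s60 <- signal_session(list(tone(60, fs, 6)), fs, layers = "Pyr")
  out <- notch60(s60)
  mid <- 1000:5000
  expect_lt(sd(out$samples[1, mid]) / sd(s60$samples[1, mid]), 0.032)

  s8 <- signal_session(list(tone(8, fs, 6)), fs, layers = "Pyr")
  out8 <- notch60(s8)
  expect_equal(sd(out8$samples[1, mid]) / sd(s8$samples[1, mid]), 1,
               tolerance = 0.11)

  z <- signal_session(list(rep(0, 2000)), fs, layers = "Pyr")
  expect_equal(max(abs(notch60(z)$samples)), 0)
})

test_that("theta bandpass is zero-phase and selective", {
  fs <- 1000
  x <- tone(8, fs, 6)
  s <- signal_session(list(x), fs, layers = "Pyr")
  y <- bandpass_theta(s)$samples[1, ]
  mid <- 1000:5000
  expect_equal(sd(y[mid]) / sd(x[mid]), 1, tolerance = 0.05)
  # phase shift below 0.05 rad: cross-correlation peak at zero lag
  cc <- sapply(-3:3, function(l) cor(y[mid], x[mid + l]))
  expect_equal(which.max(cc), 4)
  expect_gt(max(cc), 0.999)

  s60 <- signal_session(list(tone(60, fs, 6)), fs, layers = "Pyr")
  y60 <- bandpass_theta(s60)$samples[1, ]
  expect_lt(sd(y60[mid]) / sd(s60$samples[1, mid]), 0.1)

  sdc <- signal_session(list(rep(5, 4000)), fs, layers = "Pyr")
  expect_lt(max(abs(bandpass_theta(sdc)$samples[1, 1000:3000])), 0.02)
})

test_that("filters are linear within float tolerance", {
  fs <- 1000
  set.seed(8)
  x <- rnorm(3000)
  s1 <- signal_session(list(x), fs, layers = "Pyr")
  s5 <- signal_session(list(5 * x), fs, layers = "Pyr")
  expect_equal(bandpass_theta(s5)$samples, 5 * bandpass_theta(s1)$samples,
               tolerance = 1e-3)
  expect_equal(notch60(s5)$samples, 5 * notch60(s1)$samples, tolerance = 1e-6)
})

test_that("locomotion detection enforces strict >3 s continuity", {
  expect_equal(detect_locomotion(flat_behavior(60, 10)), epochs(0, 60))

  # 2.9 s run is too short
  beh <- flat_behavior(20, 0.1)
  beh$speed[beh$t >= 5 & beh$t < 7.9] <- 10
  expect_equal(nrow(detect_locomotion(beh)), 0)

  # one sub-threshold sample splits a bout (no gap bridging)
  beh2 <- flat_behavior(20, 10)
  beh2$speed[401] <- 0   # the sample nearest t = 8 s
  b <- detect_locomotion(beh2)
  expect_equal(nrow(b), 2)
  expect_equal(b$end[1], 8, tolerance = 0.03)
  expect_equal(b$start[2], 8.02, tolerance = 0.03)
})

test_that("seizure windows expand by 10 minutes and merge", {
  expect_equal(seizure_exclusion(epochs(100, 160)), epochs(100, 760))
  expect_equal(nrow(seizure_exclusion(epochs())), 0)
  expect_equal(seizure_exclusion(epochs(c(0, 500), c(60, 560))),
               epochs(0, 1160))
})

test_that("analysis epochs subtract exclusions and re-apply the bout rule", {
  loco <- epochs(0, 100)
  expect_equal(analysis_epochs(loco, epochs(50, 700)), epochs(0, 50))
  expect_equal(nrow(analysis_epochs(epochs(60, 80), epochs(50, 700))), 0)
  # a 2 s fragment does not survive
  expect_equal(nrow(analysis_epochs(epochs(0, 5), epochs(2, 700))), 0)
  # analyzed time never exceeds locomotion time
  set.seed(13)
  for (i in 1:10) {
    l <- epochs_normalize(tibble::tibble(start = s <- runif(5, 0, 80),
                                         end = s + runif(5, 1, 15)))
    e <- epochs_normalize(tibble::tibble(start = s2 <- runif(3, 0, 80),
                                         end = s2 + runif(3, 1, 20)))
    expect_lte(epochs_duration(analysis_epochs(l, e)), epochs_duration(l))
  }
})
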