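test_that("theta phase generator hits its frequency targets", {
  osc0 <- oscillator_params(f0 = 8, f_jitter = 0, duration_s = 5, fs = 1000)
  th <- gen_theta_phase(osc0, seed = 1)
  tt <- (0:4999) / 1000
  expect_equal(th, 2 * pi * 8 * tt, tolerance = 1e-9)

  oscj <- oscillator_params(f0 = 8, f_jitter = 0.4, duration_s = 60, fs = 1000)
  thj <- gen_theta_phase(oscj, seed = 2)
  fmean <- mean(diff(thj)) * 1000 / (2 * pi)
  expect_gt(fmean, 7.5); expect_lt(fmean, 8.5)
  expect_true(all(diff(thj) > 0))

  expect_identical(gen_theta_phase(oscj, seed = 7), gen_theta_phase(oscj, seed = 7))
})

test_that("shared-oscillator channels hit the coherence oracle", {
  osc <- oscillator_params(duration_s = 120, fs = 500)
  mk2 <- function(g, noise) {
    channel_gen_params(c("Pyr", "Hil"), "HPC", theta_amp = 1,
                       coupling = list(c(H = g), c(H = g)),
                       phase_offset = c(0, 1), noise_amp = noise)
  }
  # identical theta source, no noise: coherence 1
  l1 <- gen_lfp(mk2(1, 0), osc, seed = 3)
  c1 <- theta_coherence(l1$samples[1, ], l1$samples[2, ], 500, epochs(0, 120))
  # phase-shifted copies of one source: unit coherence up to roundoff at
  # negligible-power bins inside the band
  expect_gt(c1, 0.98)

  # gamma = 0: independent oscillators
  l0 <- gen_lfp(mk2(0, 0), osc, seed = 4)
  c0 <- theta_coherence(l0$samples[1, ], l0$samples[2, ], 500, epochs(0, 120))
  expect_lt(c0, 0.2)
})

test_that("spike generator matches the Bessel-ratio oracle", {
  osc <- oscillator_params(duration_s = 400, fs = 250, f_jitter = 0.3)
  th <- gen_theta_phase(osc, seed = 5)

  # kappa = 2: r-hat near I1(2)/I0(2), mu recovered
  st <- gen_spikes(5, pi, 2, th, 250, seed = 6)
  ph <- wrap_2pi(approx((seq_along(th) - 1) / 250, th, st)$y)
  cm <- circ_mean_r(ph)
  expect_equal(cm$r, von_mises_r(2), tolerance = 0.03)
  expect_lt(abs(atan2(sin(cm$mu - pi), cos(cm$mu - pi))), 0.1)
  # rate normalization: mean rate independent of kappa
  expect_equal(length(st) / 400, 5, tolerance = 0.15)

  # kappa = 0: uniform phases, homogeneous Poisson
  st0 <- gen_spikes(5, pi, 0, th, 250, seed = 7)
  ph0 <- wrap_2pi(approx((seq_along(th) - 1) / 250, th, st0)$y)
  expect_lt(circ_mean_r(ph0)$r, 0.06)
  expect_equal(length(st0) / 400, 5, tolerance = 0.15)

  expect_identical(gen_spikes(5, 1, 2, th, 250, seed = 8),
                   gen_spikes(5, 1, 2, th, 250, seed = 8))
})

test_that("behavior generator returns ground-truth bouts above 3 s", {
  gb <- gen_behavior(300, seed = 9)
  expect_equal(nrow(gb$behavior), 300 * 50)
  expect_true(all(gb$bouts$end - gb$bouts$start > 3))
  # detected bouts match generated ground truth
  det <- detect_locomotion(gb$behavior, speed_thresh = 2, min_dur = 3)
  expect_equal(nrow(det), nrow(gb$bouts))
  expect_equal(det$start, gb$bouts$start, tolerance = 0.05)
  expect_equal(det$end, gb$bouts$end, tolerance = 0.05)
  expect_identical(gen_behavior(50, seed = 4)$behavior,
                   gen_behavior(50, seed = 4)$behavior)
  # with short-bout parameters, sub-3 s runs exist in the segment stream but
  # are excluded from ground truth
  gb2 <- gen_behavior(600, seed = 10, run_mean_s = 4, run_sdlog = 0.6)
  r <- rle(gb2$behavior$speed > 2)
  durs <- r$lengths[r$values] / 50
  expect_gt(sum(durs <= 3), 0)
  # sampled run lengths are quantized at 20 ms: allow one boundary case
  expect_lte(abs(sum(durs > 3.02) - nrow(gb2$bouts)), 1)
})

test_that("cohort generation validates its spec and writes ground truth", {
  expect_error(cohort_spec(n_animals = c(control = 0, epi3wk = 1, epi8wk = 1)),
               "at least one animal")
  expect_error(cohort_spec(n_animals = c(control = 2)), "all groups")

  spec <- cohort_spec(n_animals = c(control = 1, epi3wk = 1, epi8wk = 1),
                      duration_s = 12, fs = 250,
                      channels = default_channel_params()[c(2, 7), ],
                      units = NULL, seed = 5)
  d <- withr::local_tempdir()
  mf <- gen_cohort(spec, d)
  expect_equal(nrow(mf), 3)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  s <- read_session(file.path(d, "control_01"))
  expect_equal(nrow(s$samples), 2)
  expect_equal(session_duration(s), 12)
})

test_that("group effects rescale the targeted parameters only", {
  spec <- cohort_spec()
  eff <- thetasync:::apply_group_effects(spec, "epi8wk")
  base <- thetasync:::apply_group_effects(spec, "control")
  expect_equal(eff$channels$theta_amp[eff$channels$layer == "LM"],
               0.55 * base$channels$theta_amp[base$channels$layer == "LM"])
  expect_equal(eff$units$kappa_spike[eff$units$pop == "MEC3_trough"],
               0.45 * base$units$kappa_spike[base$units$pop == "MEC3_trough"])
  expect_equal(eff$units$kappa_spike[eff$units$pop == "MEC3_peak"],
               base$units$kappa_spike[base$units$pop == "MEC3_peak"])
  expect_equal(eff$channels$theta_amp[eff$channels$layer == "Pyr"],
               base$channels$theta_amp[base$channels$layer == "Pyr"])
})
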