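test_that("reference channels follow the layer conventions", {
  layers <- c(rep("Or", 5), rep("Pyr", 6), rep("Rad", 10), rep("LM", 9),
              rep("Mol", 10), rep("GC", 0), rep("Hil", 9))
  cm <- map_for_layers(c(rep("Or", 5), rep("Pyr", 6), rep("Rad", 10),
                         rep("LM", 9), rep("Mol", 10), rep("Hil", 9)))
  # Pyr block = channels 5..10 (0-based): CA1 reference is the top channel
  expect_equal(reference_channel(cm, "CA1_theta"), 5)
  # Hil block = channels 40..48: DG reference is the middle channel 44
  expect_equal(reference_channel(cm, "DG_theta"), 44)

  mec <- map_for_layers(c(rep("MEC1", 4), rep("MEC2", 5), rep("MEC3", 6)))
  # combined MEC2+MEC3 block = channels 4..14, middle = 9
  expect_equal(reference_channel(mec, "MEC_theta"), 9)

  expect_error(reference_channel(mec, "CA1_theta"), "absent")
})

test_that("Hilbert phase follows the peak-zero convention", {
  fs <- 1000
  tt <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(cos(2 * pi * 8 * tt))
  mid <- 500:3500
  # at a peak (t multiple of 125 ms) phase ~ 0; at a trough ~ pi
  peaks <- which(abs((tt * 8) %% 1) < 1e-9)
  peaks <- peaks[peaks %in% mid]
  expect_true(all(pmin(ph[peaks], 2 * pi - ph[peaks]) < 0.02))
  troughs <- which(abs((tt * 8) %% 1 - 0.5) < 1e-9)
  troughs <- troughs[troughs %in% mid]
  expect_true(all(abs(ph[troughs] - pi) < 0.02))
  # phase advances 2*pi per cycle
  unw <- ph[mid]
  d <- diff(unw); d[d < -pi] <- d[d < -pi] + 2 * pi
  expect_equal(sum(d), 2 * pi * 8 * (length(mid) - 1) / fs, tolerance = 1e-2)
})

test_that("unit phase locking recovers generator truth and honors epochs", {
  osc <- oscillator_params(duration_s = 300, fs = 250, f_jitter = 0.3)
  th <- gen_theta_phase(osc, seed = 11)
  phase <- wrap_2pi(th)
  st <- gen_spikes(5, pi, 2, th, 250, seed = 12)
  ep <- epochs(0, 300)
  r <- unit_phase_locking(st, phase, 250, ep)
  expect_true(r$significant)
  expect_equal(r$r, von_mises_r(2), tolerance = 0.05)
  expect_lt(abs(atan2(sin(r$mu - pi), cos(r$mu - pi))), 0.15)

  # spikes outside the epochs do not move the estimate
  ep2 <- epochs(0, 150)
  r2 <- unit_phase_locking(st, phase, 250, ep2)
  extra <- sort(c(st, runif(200, 200, 299)))
  r3 <- unit_phase_locking(extra, phase, 250, ep2)
  expect_equal(r3$r, r2$r)
  expect_equal(r3$mu, r2$mu)

  # too few spikes: flagged, not estimated
  r4 <- unit_phase_locking(st[1:10], phase, 250, ep)
  expect_true(r4$insufficient)

  # kappa = 0 units are rarely significant
  set.seed(13)
  sig <- replicate(40, {
    s0 <- gen_spikes(3, 0, 0, th, 250, seed = sample.int(1e6, 1))
    unit_phase_locking(s0, phase, 250, ep)$significant
  })
  expect_lt(mean(sig), 0.2)
})

test_that("population tables gate mu on Rayleigh significance", {
  osc <- oscillator_params(duration_s = 200, fs = 250, f_jitter = 0.3)
  th <- gen_theta_phase(osc, seed = 21)
  phase <- wrap_2pi(th)
  mk_unit <- function(id, kappa, seed) {
    tibble::tibble(unit_id = id, animal_id = "a1", group = "control",
                   region = "HPC", layer = "Hil", cls = "inhibitory",
                   spike_times = list(gen_spikes(4, pi, kappa, th, 250,
                                                 seed = seed)),
                   firing_rate_hz = 4)
  }
  units <- dplyr::bind_rows(mk_unit("locked", 3, 1), mk_unit("flat", 0, 2))
  tb <- population_table(units, list(a1 = phase), 250, list(a1 = epochs(0, 200)),
                         region = "HPC", layer = "Hil", cls = "inhibitory",
                         reference = "CA1_theta")
  expect_equal(nrow(tb), 2)
  locked <- tb[tb$unit_id == "locked", ]
  flat <- tb[tb$unit_id == "flat", ]
  expect_true(locked$significant)
  expect_false(is.na(locked$mu))
  expect_false(flat$significant)
  expect_true(is.na(flat$mu))        # mu reported only when significant
  expect_false(is.na(flat$r))        # r reported for all units

  # preset equals the manual filter
  tb2 <- population_table(units, list(a1 = phase), 250,
                          list(a1 = epochs(0, 200)), preset = "DG_inh_to_CA1")
  expect_equal(tb2$r, tb$r)
  expect_equal(attr(tb2, "counts")$n_units, 2L)

  empty <- population_table(units, list(a1 = phase), 250,
                            list(a1 = epochs(0, 200)),
                            region = "MEC", layer = "MEC2", cls = "excitatory")
  expect_equal(nrow(empty), 0)
})

test_that("MEC3 subclustering separates trough- and peak-locked units", {
  set.seed(31)
  mk <- function(n, mu, kappa) {
    tibble::tibble(unit_id = paste0("u", seq_len(n), "_", round(mu, 1)),
                   mu = rvonmises(n, mu, kappa), r = runif(n, 0.4, 0.8),
                   significant = TRUE)
  }
  res <- dplyr::bind_rows(mk(40, 3.0, 4), mk(40, 0.3, 4))
  cl <- cluster_mec3(res, seed = 3)
  truth <- rep(c("trough_locked", "peak_locked"), each = 40)
  expect_gte(mean(cl$cluster == truth), 0.98)

  # invariant to row order
  perm <- sample(80)
  cl2 <- cluster_mec3(res[perm, ], seed = 3)
  expect_equal(cl2$cluster[order(cl2$unit_id)], cl$cluster[order(cl$unit_id)])

  # a single tight cluster is flagged as low separation
  one <- mk(30, 3.0, 30)
  one$r <- runif(30, 0.58, 0.62)
  cl3 <- cluster_mec3(one, seed = 3)
  expect_true(all(cl3$low_separation))

  expect_warning(cluster_mec3(mk(4, 3, 4), seed = 1), "no clustering")
})
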