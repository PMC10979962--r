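# Synthetic cohort generator.
#
# Signal model: each channel mixes one or more shared narrowband "theta
# sources" (8 Hz carriers with slow frequency drift) with a private oscillator
# of identical spectrum and 1/f background noise,
#   x_i(t) = A_i * [ sum_k sqrt(g_ik * s_k(t)) cos(Theta_k + phi_i)
#                    + sqrt(1 - sum_k g_ik * s_k(t)) cos(Theta_i + phi_i) ]
#            + noise_i(t),
# so the theta-band magnitude coherence between channels i and j sharing
# source k converges to sqrt(g_ik * g_jk) * s_k as noise -> 0: a closed-form
# oracle for every pairwise coherence. The per-source gain s_k(t) is a
# block-wise synchronization state (1 = synchronized, desync_gain during
# desynchronized blocks), which is what makes coherence vary across running
# bouts and lets group deficits be expressed as a larger fraction of
# desynchronized time.

#' Oscillator parameters
#'
#' @param f0 Carrier frequency, Hz (kept inside the 5-12 Hz analysis band).
#' @param f_jitter Standard deviation of the slow frequency drift, Hz.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, Hz.
#' @return A list of oscillator parameters.
#' @export
oscillator_params <- function(f0 = 8, f_jitter = 0.4, duration_s = 300, fs = 1000) {
  assert_that(f0 >= 5 && f0 <= 12, "carrier f0 must lie in the 5-12 Hz theta band")
  assert_that(duration_s > 0 && fs > 0, "duration and fs must be positive")
  list(f0 = f0, f_jitter = f_jitter, duration_s = duration_s, fs = fs)
}

#' Generate an unwrapped theta phase series
#'
#' Instantaneous frequency is `f0` plus a slow AR(1) drift (2 s time constant,
#' stationary s.d. `f_jitter`); the phase is its cumulative integral, so with
#' `f_jitter = 0` the phase is exactly `2*pi*f0*t`.
#'
#' @param osc Oscillator parameters from [oscillator_params()].
#' @param seed Integer seed; the series is bit-reproducible given the seed.
#' @return Unwrapped phase (radians), one value per sample, starting at 0.
#' @export
gen_theta_phase <- function(osc, seed = 1L) {
  n <- round(osc$duration_s * osc$fs)
  if (osc$f_jitter > 0) {
    a <- exp(-1 / (2 * osc$fs))
    drift <- with_seed(seed, as.numeric(
      stats::filter(rnorm(n, 0, osc$f_jitter * sqrt(1 - a^2)),
                    a, method = "recursive")))
    f <- osc$f0 + drift
  } else {
    f <- rep(osc$f0, n)
  }
  2 * pi * cumsum(c(0, f[-n])) / osc$fs
}

#' Spectrally shaped 1/f background noise
#'
#' Gaussian noise shaped to a 1/f amplitude spectrum (power exponent 1),
#' rescaled to the requested RMS.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param rms Target root-mean-square amplitude.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_onef_noise <- function(n, fs, rms, seed = 1L) {
  if (rms <= 0) return(numeric(n))
  W <- fft(with_seed(seed, rnorm(n)))
  fr <- (seq_len(n) - 1) * fs / n
  fr <- pmin(fr, fs - fr)
  fr[1] <- Inf                      # zero out DC
  x <- Re(fft(W / sqrt(fr), inverse = TRUE)) / n
  x / sd(x) * rms
}

#' Channel generation parameters
#'
#' One row per channel. `coupling` is a named list-column: fractions of theta
#' variance drawn from each shared source (remainder is a private oscillator).
#'
#' @param layer,region Laminar label and region per channel.
#' @param theta_amp Theta amplitude, microvolts.
#' @param coupling List of named numeric vectors (per-source variance
#'   fractions, summing to at most 1).
#' @param phase_offset Phase offset, radians.
#' @param noise_amp RMS of the 1/f background, microvolts.
#' @return A channel-parameter tibble.
#' @export
channel_gen_params <- function(layer, region, theta_amp = 150,
                               coupling = list(c(H = 0.8)),
                               phase_offset = 0, noise_amp = 30) {
  bad <- purrr::map_lgl(coupling, function(g) any(g < 0) || sum(g) > 1 + 1e-9)
  assert_that(!any(bad), "coupling fractions must be non-negative and sum to <= 1")
  tibble(layer = layer, region = region, theta_amp = theta_amp,
         coupling = coupling, phase_offset = phase_offset, noise_amp = noise_amp)
}

# block-wise synchronization state series for one source
gen_sync_gain <- function(n, fs, block_s, desync_prob, desync_gain, seed) {
  nb <- ceiling(n / (block_s * fs))
  states <- with_seed(seed,
                      ifelse(runif(nb) < desync_prob, desync_gain, 1))
  rep(states, each = block_s * fs)[seq_len(n)]
}

#' Generate a laminar LFP matrix
#'
#' @param channels Channel-parameter tibble from [channel_gen_params()].
#' @param osc Oscillator parameters (shared by all sources).
#' @param seed Integer seed.
#' @param gains Optional named list of per-sample gain series in `[0, 1]`,
#'   one per source (defaults to constant 1).
#' @return A list with `samples` (channels x samples matrix, microvolts) and
#'   `sources` (named list of unwrapped source phase series -- the generative
#'   ground truth for spike phase locking).
#' @export
gen_lfp <- function(channels, osc, seed = 1L, gains = NULL) {
  assert_that(nrow(channels) >= 1, "need at least one channel")
  n <- round(osc$duration_s * osc$fs)
  src_names <- unique(unlist(purrr::map(channels$coupling, names)))
  sources <- purrr::map(src_names, function(s) {
    gen_theta_phase(osc, derive_seed(seed, "src", s))
  })
  names(sources) <- src_names
  samples <- matrix(0, nrow(channels), n)
  for (i in seq_len(nrow(channels))) {
    g <- channels$coupling[[i]]
    phi <- channels$phase_offset[i]
    shared_var <- numeric(n)
    x <- numeric(n)
    for (s in names(g)) {
      gain <- if (!is.null(gains[[s]])) gains[[s]] else 1
      gs <- g[[s]] * gain
      x <- x + sqrt(gs) * cos(sources[[s]] + phi)
      shared_var <- shared_var + gs
    }
    priv <- gen_theta_phase(osc, derive_seed(seed, "priv", i))
    x <- x + sqrt(pmax(1 - shared_var, 0)) * cos(priv + phi)
    noise <- gen_onef_noise(n, osc$fs, channels$noise_amp[i],
                            derive_seed(seed, "noise", i))
    samples[i, ] <- channels$theta_amp[i] * x + noise
  }
  list(samples = samples, sources = sources)
}

#' Generate a von Mises-modulated Poisson spike train
#'
#' Inhomogeneous Poisson process with rate
#' `lambda(t) = rate_hz * exp(kappa * cos(phase(t) - mu)) / I0(kappa)`,
#' realized by thinning a dominating homogeneous process. The `I0(kappa)`
#' normalization keeps the mean rate equal to `rate_hz` independent of the
#' coupling strength, and the expected spike-phase resultant length is
#' `I1(kappa)/I0(kappa)`.
#'
#' @param rate_hz Mean firing rate, Hz.
#' @param mu Preferred phase, radians.
#' @param kappa von Mises concentration (>= 0).
#' @param phase Unwrapped reference phase series (radians).
#' @param fs Sampling rate of `phase`, Hz.
#' @param seed Integer seed.
#' @return Sorted spike times in seconds.
#' @export
gen_spikes <- function(rate_hz, mu, kappa, phase, fs, seed = 1L) {
  assert_that(rate_hz > 0, "rate must be positive")
  assert_that(kappa >= 0, "kappa must be non-negative")
  dur <- length(phase) / fs
  lam_max <- rate_hz * exp(kappa) / besselI(kappa, 0)
  with_seed(seed, {
    n_cand <- rpois(1, lam_max * dur)
    if (n_cand == 0) {
      numeric(0)
    } else {
      tt <- sort(runif(n_cand, 0, dur))
      ph <- approx(x = (seq_along(phase) - 1) / fs, y = phase, xout = tt,
                   rule = 2)$y
      accept <- runif(n_cand) < exp(kappa * (cos(ph - mu) - 1))
      tt[accept]
    }
  })
}

#' Generate a behavior trace of alternating stillness and running
#'
#' Running-segment durations are log-normal around `run_mean_s` so the
#' generated session contains both sub-3 s and supra-3 s segments; the
#' returned ground-truth bout set keeps only segments longer than
#' `min_bout_s`, matching the locomotion definition used by the analysis.
#'
#' @param duration_s Total duration, seconds.
#' @param seed Integer seed.
#' @param run_mean_s Median running-segment duration, seconds.
#' @param run_sdlog Log-scale s.d. of running-segment durations.
#' @param still_mean_s Mean stillness duration, seconds.
#' @param speed_mean,speed_sd Running speed distribution, cm/s.
#' @param fs_beh Behavior sampling rate, Hz.
#' @param min_bout_s Ground-truth bout threshold (strictly longer than).
#' @return A list with `behavior` (tibble `t`, `position`, `speed`) and
#'   `bouts` (ground-truth epoch tibble of running segments > `min_bout_s`).
#' @export
gen_behavior <- function(duration_s, seed = 1L, run_mean_s = 10, run_sdlog = 0.5,
                         still_mean_s = 4, speed_mean = 15, speed_sd = 3,
                         fs_beh = 50, min_bout_s = 3) {
  with_seed(seed, gen_behavior_impl(duration_s, run_mean_s, run_sdlog,
                                    still_mean_s, speed_mean, speed_sd,
                                    fs_beh, min_bout_s))
}

gen_behavior_impl <- function(duration_s, run_mean_s, run_sdlog, still_mean_s,
                              speed_mean, speed_sd, fs_beh, min_bout_s) {
  t_cursor <- 0; running <- FALSE
  seg_s <- numeric(0); seg_e <- numeric(0); seg_run <- logical(0)
  while (t_cursor < duration_s) {
    d <- if (running) rlnorm(1, log(run_mean_s), run_sdlog) else rexp(1, 1 / still_mean_s) + 0.5
    e <- min(t_cursor + d, duration_s)
    seg_s <- c(seg_s, t_cursor); seg_e <- c(seg_e, e); seg_run <- c(seg_run, running)
    t_cursor <- e
    running <- !running
  }
  tt <- seq(0, duration_s - 1 / fs_beh, by = 1 / fs_beh)
  speed <- abs(rnorm(length(tt), 0, 0.3))
  for (i in which(seg_run)) {
    idx <- tt >= seg_s[i] & tt < seg_e[i]
    speed[idx] <- pmax(rnorm(sum(idx), speed_mean, speed_sd), 5)
  }
  position <- (cumsum(speed / 100) / fs_beh) %% 2   # 2 m circular track
  run_idx <- which(seg_run & (seg_e - seg_s > min_bout_s))
  bouts <- if (length(run_idx) > 0) epochs(seg_s[run_idx], seg_e[run_idx]) else epochs()
  list(behavior = tibble(t = tt, position = position, speed = speed),
       bouts = bouts)
}

#' Default per-layer channel parameters
#'
#' One channel per sublayer. Hippocampal channels load on a shared HPC theta
#' source (`H`), MEC channels on an MEC source (`M`); the DG molecular layer
#' and MEC2 additionally load on a cross-region source (`X`), giving the three
#' anchor pairs (Hil-Pyr, MEC2-MEC3, MEC2-Mol) independent coherence knobs.
#' Theta amplitude peaks at the fissure (LM/Mol) as in laminar recordings, and
#' DG-block channels are phase-inverted relative to CA1.
#'
#' @return A channel-parameter tibble with one row per sublayer.
#' @export
default_channel_params <- function() {
  dplyr::bind_rows(
    channel_gen_params("Or",   "HPC", 80,  list(c(H = 0.80)), 0, 25),
    channel_gen_params("Pyr",  "HPC", 100, list(c(H = 0.80)), 0, 45),
    channel_gen_params("Rad",  "HPC", 140, list(c(H = 0.80)), 0.6, 25),
    channel_gen_params("LM",   "HPC", 220, list(c(H = 0.80)), 1.2, 25),
    channel_gen_params("Mol",  "HPC", 180, list(c(H = 0.35, X = 0.50)), pi, 25),
    channel_gen_params("GC",   "HPC", 120, list(c(H = 0.80)), pi, 30),
    channel_gen_params("Hil",  "HPC", 100, list(c(H = 0.80)), pi, 35),
    channel_gen_params("LB",   "HPC", 110, list(c(H = 0.80)), pi, 30),
    channel_gen_params("MEC1", "MEC", 150, list(c(M = 0.80)), 0, 25),
    channel_gen_params("MEC2", "MEC", 140, list(c(M = 0.35, X = 0.50)), 0.3, 30),
    channel_gen_params("MEC3", "MEC", 130, list(c(M = 0.80)), 0.6, 30)
  )
}

#' Default unit-population parameters
#'
#' Populations mirror the recorded cell groups: DG interneurons locked near
#' the theta trough, CA1 pyramidal cells, MEC2 excitatory cells, and the two
#' MEC3 excitatory subpopulations (trough- and peak-locked). `kappa_pop`
#' controls the across-cell concentration of preferred phases, `kappa_spike`
#' the within-cell locking strength.
#'
#' @return A unit-population tibble.
#' @export
default_unit_params <- function() {
  tibble(
    pop         = c("DG_int", "CA1_pyr", "MEC2_exc", "MEC3_trough", "MEC3_peak",
                    "MEC_int"),
    region      = c("HPC", "HPC", "MEC", "MEC", "MEC", "MEC"),
    layer       = c("Hil", "Pyr", "MEC2", "MEC3", "MEC3", "MEC2"),
    cls         = c("inhibitory", "excitatory", "excitatory", "excitatory",
                    "excitatory", "inhibitory"),
    n_per_animal = c(12L, 10L, 16L, 8L, 10L, 8L),
    rate_hz     = c(15, 1.5, 3, 3, 3, 12),
    ref_source  = c("H", "H", "M", "M", "M", "M"),
    mu_pop      = c(pi, pi, pi, pi, 0.3, pi / 2),
    kappa_pop   = c(8, 4, 3, 6, 6, 2),
    kappa_spike = c(1.5, 1.0, 1.2, 2.0, 1.2, 1.0)
  )
}

#' Cohort specification for the subsampling dissociation scenarios
#'
#' LFP-only cohorts carrying just the anchor-pair layers (Pyr, Hil, Mol,
#' MEC2, MEC3), with either independent per-anchor synchronization states
#' (local and long-range coherence deficits arise from separate mechanisms)
#' or a single shared state driving all anchors (one intact theta generator
#' active in a subset of time bins). Epileptic groups spend a larger fraction
#' of blocks desynchronized.
#'
#' @param mechanism "independent" or "shared".
#' @param n_per_group Animals per group.
#' @param duration_s Session duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
dissociation_cohort_spec <- function(mechanism = c("independent", "shared"),
                                     n_per_group = 6, duration_s = 600,
                                     fs = 250, seed = 1L) {
  mechanism <- match.arg(mechanism)
  ch <- default_channel_params()
  ch <- ch[ch$layer %in% c("Pyr", "Hil", "Mol", "MEC2", "MEC3"), ]
  cohort_spec(
    n_animals = c(control = n_per_group, epi3wk = n_per_group,
                  epi8wk = n_per_group),
    duration_s = duration_s, fs = fs, channels = ch, units = NULL,
    sync = list(block_s = 20, desync_gain = 0.18,
                desync_prob = c(control = 0.05, epi3wk = 0.45, epi8wk = 0.45),
                mechanism = mechanism),
    effects = list(epi3wk = list(), epi8wk = list()),
    seed = seed
  )
}

#' Cohort specification
#'
#' Defines group sizes, signal/unit/behavior parameters, the block-wise
#' synchronization model, and per-group effect multipliers.
#'
#' @param n_animals Named integer vector over `r toString(GROUPS)`.
#' @param duration_s Session duration, seconds.
#' @param fs LFP sampling rate, Hz.
#' @param oscillator `f0`/`f_jitter` for all theta sources.
#' @param channels Channel-parameter tibble.
#' @param units Unit-population tibble (`NULL` for LFP-only cohorts).
#' @param behavior Behavior-generator parameters.
#' @param sync Synchronization-state model: `block_s` (block length, s),
#'   `desync_gain` (coherence multiplier in desynchronized blocks),
#'   `desync_prob` (named per group), `mechanism` ("shared": one state series
#'   drives all sources; "independent": each source has its own).
#' @param effects Per-group effect multipliers: named lists with optional
#'   entries `theta_amp` (named by layer), `kappa_pop` / `kappa_spike` (named
#'   by population), and `seizure_rate_hr`.
#' @param animal_jitter Between-animal heterogeneity: `coupling` (log-normal
#'   s.d. of a per-animal multiplier on all source loadings) and `desync`
#'   (s.d. of additive jitter on the per-animal desynchronized-block
#'   probability). Real cohorts vary at the animal level; without this the
#'   group tests become implausibly sensitive.
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_animals = c(control = 6, epi3wk = 6, epi8wk = 6),
                        duration_s = 300, fs = 1000,
                        oscillator = list(f0 = 8, f_jitter = 0.4),
                        channels = default_channel_params(),
                        units = default_unit_params(),
                        behavior = list(run_mean_s = 10, run_sdlog = 0.5,
                                        still_mean_s = 4, speed_mean = 15,
                                        speed_sd = 3, fs_beh = 50),
                        sync = list(block_s = 20, desync_gain = 0.18,
                                    desync_prob = c(control = 0.05, epi3wk = 0.45,
                                                    epi8wk = 0.45),
                                    mechanism = "shared"),
                        effects = list(
                          epi3wk = list(theta_amp = c(LM = 0.65, Mol = 0.65),
                                        kappa_pop = c(DG_int = 0.35),
                                        seizure_rate_hr = 0.2),
                          epi8wk = list(theta_amp = c(LM = 0.55, Mol = 0.55),
                                        kappa_pop = c(DG_int = 0.35),
                                        kappa_spike = c(MEC3_trough = 0.45),
                                        seizure_rate_hr = 0.2)
                        ),
                        animal_jitter = list(coupling = 0.06, desync = 0.04),
                        seed = 1L) {
  assert_that(all(GROUPS %in% names(n_animals)),
              sprintf("n_animals must name all groups: %s", toString(GROUPS)))
  assert_that(all(n_animals >= 1), "need at least one animal per group")
  assert_that(sync$mechanism %in% c("shared", "independent"),
              "sync$mechanism must be 'shared' or 'independent'")
  structure(list(n_animals = n_animals, duration_s = duration_s, fs = fs,
                 oscillator = oscillator, channels = channels, units = units,
                 behavior = behavior, sync = sync, effects = effects,
                 animal_jitter = animal_jitter, seed = seed),
            class = "cohort_spec")
}

apply_group_effects <- function(spec, group) {
  ch <- spec$channels
  un <- spec$units
  eff <- spec$effects[[group]]
  if (!is.null(eff$theta_amp)) {
    for (ly in names(eff$theta_amp)) {
      ch$theta_amp[ch$layer == ly] <- ch$theta_amp[ch$layer == ly] * eff$theta_amp[[ly]]
    }
  }
  if (!is.null(un)) {
    for (fld in c("kappa_pop", "kappa_spike")) {
      if (!is.null(eff[[fld]])) {
        for (p in names(eff[[fld]])) {
          un[[fld]][un$pop == p] <- un[[fld]][un$pop == p] * eff[[fld]][[p]]
        }
      }
    }
  }
  list(channels = ch, units = un, seizure_rate_hr = eff$seizure_rate_hr %||% 0)
}

# class-conditional waveform/train feature draws
draw_unit_features <- function(cls, n) {
  if (cls == "excitatory") {
    tibble(c_index_ms = rnorm(n, 0.55, 0.06),
           mean_acg = runif(n, 0.03, 0.08),
           csi = runif(n, 0.1, 0.5))
  } else {
    tibble(c_index_ms = rnorm(n, 0.18, 0.03),
           mean_acg = runif(n, 0.12, 0.25),
           csi = runif(n, -0.3, 0))
  }
}

#' Generate one synthetic session with its units and ground truth
#'
#' @param spec A [cohort_spec()].
#' @param group Group label.
#' @param animal_id Animal identifier.
#' @param seed Integer seed for this animal.
#' @return A list with `session` (an `lfp_session`), `units` (tibble including
#'   generative truth columns `true_mu`, `true_kappa`, `pop`), and `truth`
#'   (generator parameters after group effects).
#' @export
gen_session <- function(spec, group, animal_id, seed) {
  eff <- apply_group_effects(spec, group)
  osc <- oscillator_params(spec$oscillator$f0, spec$oscillator$f_jitter,
                           spec$duration_s, spec$fs)
  n <- round(spec$duration_s * spec$fs)
  # between-animal heterogeneity: one coupling multiplier and one
  # desynchronization-probability offset per animal
  jit <- spec$animal_jitter %||% list(coupling = 0, desync = 0)
  aj <- with_seed(derive_seed(seed, "animal"), {
    list(coupling = exp(rnorm(1, 0, jit$coupling %||% 0)),
         desync = rnorm(1, 0, jit$desync %||% 0))
  })
  eff$channels$coupling <- purrr::map(eff$channels$coupling, function(g) {
    g * min(aj$coupling, 1 / max(sum(g), 1e-12))
  })
  p_desync <- min(max(spec$sync$desync_prob[[group]] + aj$desync, 0), 0.95)
  src_names <- unique(unlist(purrr::map(eff$channels$coupling, names)))
  if (spec$sync$mechanism == "shared") {
    g0 <- gen_sync_gain(n, spec$fs, spec$sync$block_s,
                        p_desync, spec$sync$desync_gain,
                        derive_seed(seed, "sync"))
    gains <- purrr::map(src_names, function(s) g0)
  } else {
    gains <- purrr::map(src_names, function(s) {
      gen_sync_gain(n, spec$fs, spec$sync$block_s,
                    p_desync, spec$sync$desync_gain,
                    derive_seed(seed, "sync", s))
    })
  }
  names(gains) <- src_names
  lfp <- gen_lfp(eff$channels, osc, derive_seed(seed, "lfp"), gains = gains)
  beh <- gen_behavior(spec$duration_s, derive_seed(seed, "beh"),
                      run_mean_s = spec$behavior$run_mean_s,
                      run_sdlog = spec$behavior$run_sdlog,
                      still_mean_s = spec$behavior$still_mean_s,
                      speed_mean = spec$behavior$speed_mean,
                      speed_sd = spec$behavior$speed_sd,
                      fs_beh = spec$behavior$fs_beh)
  seiz <- epochs()
  if (eff$seizure_rate_hr > 0) {
    seiz <- with_seed(derive_seed(seed, "seiz"), {
      k <- rpois(1, eff$seizure_rate_hr * spec$duration_s / 3600)
      if (k > 0) {
        st <- sort(runif(k, 0, spec$duration_s - 95))
        epochs(st, pmin(st + runif(k, 30, 90), spec$duration_s))
      } else epochs()
    })
  }
  cm <- channel_map(channel = seq_len(nrow(eff$channels)) - 1L,
                    depth_um = seq_len(nrow(eff$channels)) * 50,
                    region = eff$channels$region, layer = eff$channels$layer)
  session <- lfp_session(lfp$samples, spec$fs, cm, animal_id = animal_id,
                         group = group, behavior = beh$behavior, seizures = seiz)
  units <- NULL
  if (!is.null(eff$units) && nrow(eff$units) > 0) {
    units <- purrr::map_dfr(seq_len(nrow(eff$units)), function(p) {
      up <- eff$units[p, ]
      nn <- up$n_per_animal
      useed <- derive_seed(seed, "units", up$pop)
      draws <- with_seed(useed, list(
        mus = rvonmises(nn, up$mu_pop, up$kappa_pop),
        rates = rlnorm(nn, log(up$rate_hz), 0.4),
        feats = draw_unit_features(up$cls, nn)
      ))
      mus <- draws$mus; rates <- draws$rates; feats <- draws$feats
      st <- purrr::map(seq_len(nn), function(j) {
        gen_spikes(rates[j], mus[j], up$kappa_spike,
                   lfp$sources[[up$ref_source]], spec$fs,
                   derive_seed(useed, "spk", j))
      })
      tibble(unit_id = sprintf("%s_%s_%02d", animal_id, up$pop, seq_len(nn)),
             animal_id = animal_id, group = group,
             region = up$region, layer = up$layer, pop = up$pop,
             spike_times = st,
             firing_rate_hz = purrr::map_dbl(st, ~ length(.x) / spec$duration_s),
             c_index_ms = feats$c_index_ms, mean_acg = feats$mean_acg,
             csi = feats$csi, cls = up$cls,
             true_mu = mus, true_kappa = up$kappa_spike, true_rate = rates)
    })
  }
  list(session = session, units = units,
       truth = list(channels = eff$channels, units = eff$units,
                    sources = names(lfp$sources), seed = seed))
}

#' Generate a full cohort on disk
#'
#' Writes one session directory per animal plus `ground_truth.json` recording
#' every generative parameter (for recovery tests).
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory.
#' @return A tibble manifest (animal_id, group, path), invisibly.
#' @export
gen_cohort <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::map_dfr(GROUPS, function(g) {
    purrr::map_dfr(seq_len(spec$n_animals[[g]]), function(i) {
      aid <- sprintf("%s_%02d", g, i)
      res <- gen_session(spec, g, aid, derive_seed(spec$seed, g, i))
      p <- file.path(out_dir, aid)
      write_session(res$session, p)
      if (!is.null(res$units)) {
        write_units(dplyr::select(res$units, -dplyr::any_of(c("true_mu", "true_kappa",
                                                              "true_rate", "pop"))), p)
      }
      tibble(animal_id = aid, group = g, path = p)
    })
  })
  truth <- list(spec = list(n_animals = as.list(spec$n_animals),
                            duration_s = spec$duration_s, fs = spec$fs,
                            oscillator = spec$oscillator,
                            sync = spec$sync, effects = spec$effects,
                            seed = spec$seed),
                animals = manifest$animal_id)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}
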