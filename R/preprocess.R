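# Signal conditioning and definition of the analysis window: 1 kHz
# downsampling, 60 Hz notch, zero-phase theta bandpass, locomotion bouts
# (> 3 s continuous movement), and seizure + 10 min exclusions.

filt_vec <- function(b, a, x) as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), x))

apply_channels <- function(session, fun) {
  out <- session
  out$samples <- t(apply(session$samples, 1, fun))
  out
}

#' Downsample a session
#'
#' Anti-alias filters (8th-order zero-phase Butterworth at 80% of the target
#' Nyquist) and decimates by the integer factor `fs / target_fs`.
#'
#' @param session An `lfp_session`.
#' @param target_fs Target sampling rate, Hz (default 1000).
#' @return The downsampled session (returned unchanged when already at
#'   `target_fs`).
#' @export
downsample <- function(session, target_fs = 1000) {
  fs <- session$fs
  if (fs == target_fs) return(session)
  assert_that(fs > target_fs, sprintf("cannot downsample from %g to %g Hz", fs, target_fs))
  factor <- fs / target_fs
  assert_that(abs(factor - round(factor)) < 1e-9,
              "fs must be an integer multiple of target_fs")
  factor <- round(factor)
  # decimate in stages of at most 5x so the anti-alias IIR stays well away
  # from numerically fragile ultra-narrow cutoffs
  stages <- integer(0)
  f <- factor
  while (f > 1) {
    st <- if (f %% 5 == 0) 5L else if (f %% 4 == 0) 4L else if (f %% 3 == 0) 3L
          else if (f %% 2 == 0) 2L else f
    stages <- c(stages, st)
    f <- f / st
  }
  out <- session
  out$samples <- t(apply(session$samples, 1, function(x) {
    for (st in stages) {
      bf <- signal::butter(4, 0.8 / st, type = "low")
      x <- filt_vec(bf$b, bf$a, x)[seq(1, length(x), by = st)]
    }
    x
  }))
  out$fs <- target_fs
  out
}

#' Remove 60 Hz line noise
#'
#' Second-order notch (Q = 30) applied forward-backward, giving deep
#' attenuation at 60 Hz and under 1 dB passband ripple at theta frequencies.
#'
#' @param session An `lfp_session` (fs > 120 Hz).
#' @return The notch-filtered session.
#' @export
notch60 <- function(session) {
  fs <- session$fs
  assert_that(fs > 120, "notch60 requires fs > 120 Hz")
  w0 <- 2 * pi * 60 / fs
  alpha <- sin(w0) / (2 * 30)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_channels(session, function(x) filt_vec(b, a, x))
}

#' Zero-phase theta bandpass
#'
#' 4th-order Butterworth bandpass applied forward-backward (no group delay),
#' so downstream Hilbert phases are unbiased.
#'
#' @param session An `lfp_session`.
#' @param band Passband in Hz, default the 5-12 Hz theta band.
#' @return The bandpassed session.
#' @export
bandpass_theta <- function(session, band = c(5, 12)) {
  fs <- session$fs
  assert_that(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2,
              "need 0 < low < high < fs/2")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  apply_channels(session, function(x) filt_vec(bf$b, bf$a, x))
}

# vector versions used where no session container exists
bandpass_vec <- function(x, fs, band = c(5, 12)) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt_vec(bf$b, bf$a, x)
}

#' Detect locomotion bouts
#'
#' Maximal runs of samples with speed above threshold, kept only when longer
#' than `min_dur` ("moving continuously for more than 3 seconds"). Any single
#' sub-threshold sample breaks a bout: no gap bridging.
#'
#' @param behavior Behavior tibble (`t`, `speed`), uniformly sampled.
#' @param speed_thresh Speed threshold, cm/s.
#' @param min_dur Minimum bout duration, seconds (strict).
#' @return An epoch tibble of locomotion bouts.
#' @export
detect_locomotion <- function(behavior, speed_thresh = 2, min_dur = 3) {
  if (nrow(behavior) == 0) return(epochs())
  dt <- median(diff(behavior$t))
  above <- behavior$speed > speed_thresh
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) return(epochs())
  s <- behavior$t[starts[keep]]
  e <- behavior$t[ends[keep]] + dt
  ep <- tibble(start = s, end = e)
  epochs_filter_min(ep, min_dur)
}

#' Expand seizures into exclusion windows
#'
#' Each seizure `[s, e)` becomes `[s, e + post_s)` -- the seizing period plus
#' the 10 minutes after it -- and overlaps are merged.
#'
#' @param seizures Epoch tibble of seizure intervals.
#' @param post_s Post-seizure exclusion, seconds (default 600).
#' @return A normalized exclusion epoch tibble.
#' @export
seizure_exclusion <- function(seizures, post_s = 600) {
  if (nrow(seizures) == 0) return(epochs())
  epochs_normalize(tibble(start = seizures$start, end = seizures$end + post_s))
}

#' Final analysis epochs: locomotion minus exclusions
#'
#' Set-difference of locomotion bouts and exclusion windows; fragments created
#' by the subtraction must still exceed `min_dur` (the locomotion rule is
#' re-applied).
#'
#' @param locomotion Locomotion epoch tibble.
#' @param exclusions Exclusion epoch tibble.
#' @param min_dur Minimum fragment duration, seconds (strict).
#' @return An epoch tibble of analyzable time.
#' @export
analysis_epochs <- function(locomotion, exclusions, min_dur = 3) {
  epochs_filter_min(epochs_setdiff(locomotion, exclusions), min_dur)
}

#' All preprocessing in one step
#'
#' Downsamples, notch-filters, and derives the analysis epochs for a session.
#'
#' @param session An `lfp_session`.
#' @param target_fs Target sampling rate, Hz.
#' @param speed_thresh,min_bout_s Locomotion parameters.
#' @param seizure_post_s Post-seizure exclusion, seconds.
#' @return A list with `session` (conditioned) and `epochs` (analysis epochs).
#' @export
preprocess_session <- function(session, target_fs = 1000, speed_thresh = 2,
                               min_bout_s = 3, seizure_post_s = 600) {
  s <- downsample(session, target_fs)
  s <- notch60(s)
  loco <- detect_locomotion(s$behavior, speed_thresh, min_bout_s)
  excl <- seizure_exclusion(s$seizures, seizure_post_s)
  list(session = s, epochs = analysis_epochs(loco, excl, min_bout_s))
}
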