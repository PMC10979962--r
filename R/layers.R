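# Electrophysiological layer assignment for sessions without a curated map.
# Deliberately minimal: theta power peak anchors the fissure (LM), spike-band
# RMS above the fissure anchors the pyramidal layer, and a ~180 degree theta
# phase reversal separates the CA1 and DG blocks. Always overridable by an
# explicit channel map.

#' Per-channel layer features
#'
#' Theta power, theta phase offset relative to the topmost channel (circular
#' mean of the Hilbert phase difference), and spike-band RMS (high-frequency
#' proxy for spike density).
#'
#' @param session An `lfp_session`.
#' @param epochs_tbl Analysis epochs (defaults to the whole recording).
#' @param band Theta band, Hz.
#' @param spike_band High-frequency band for the spike-density proxy, Hz.
#' @return A tibble: `channel`, `theta_power`, `phase_offset` (radians,
#'   `(-pi, pi]`), `spike_rms`.
#' @export
layer_features <- function(session, epochs_tbl = NULL, band = c(5, 12),
                           spike_band = c(100, 400)) {
  fs <- session$fs
  n <- ncol(session$samples)
  if (is.null(epochs_tbl)) epochs_tbl <- epochs(0, n / fs)
  nch <- nrow(session$samples)
  pw <- purrr::map_dbl(seq_len(nch), function(i) {
    theta_power(session$samples[i, ], fs, epochs_tbl, band = band)
  })
  spike_band <- c(spike_band[1], min(spike_band[2], 0.45 * fs))
  srms <- purrr::map_dbl(seq_len(nch), function(i) {
    sd(bandpass_vec(session$samples[i, ], fs, spike_band))
  })
  ref_phase <- instantaneous_phase(bandpass_vec(session$samples[1, ], fs, band))
  poff <- purrr::map_dbl(seq_len(nch), function(i) {
    ph <- instantaneous_phase(bandpass_vec(session$samples[i, ], fs, band))
    d <- circ_mean_r(wrap_2pi(ph - ref_phase))$mu
    atan2(sin(d), cos(d))
  })
  tibble(channel = session$channel_map$channel, theta_power = pw,
         phase_offset = poff, spike_rms = srms)
}

#' Propose a layer map from electrophysiological features
#'
#' HPC heuristic: the theta-power maximum marks the fissure (LM); the
#' spike-band RMS maximum above the fissure marks the pyramidal layer; the
#' first ~180 degree theta phase reversal below the fissure marks the CA1/DG
#' boundary; remaining channels are filled by laminar order (Or above Pyr,
#' Rad between Pyr and LM, Mol/GC/Hil below the reversal). A flat power
#' profile (no clear maximum) leaves every channel UNASSIGNED with a warning.
#'
#' @param features Feature tibble from [layer_features()] (channels ordered
#'   superficial to deep; >= 8 channels).
#' @param region Currently "HPC" (MEC sessions should carry explicit maps).
#' @param flatness_thresh Peak-to-median power ratio below which the profile
#'   is declared flat.
#' @return A tibble: `channel`, `layer` (or "UNASSIGNED"), and attribute
#'   `confidence` (named numeric: power-peak prominence, phase-reversal size).
#' @export
propose_layers <- function(features, region = "HPC", flatness_thresh = 2) {
  nch <- nrow(features)
  assert_that(nch >= 8, "need at least 8 channels on the shank")
  lay <- rep("UNASSIGNED", nch)
  peak <- which.max(features$theta_power)
  prominence <- features$theta_power[peak] / median(features$theta_power)
  if (!is.finite(prominence) || prominence < flatness_thresh) {
    warn("flat theta power profile: all channels left UNASSIGNED")
    return(structure(tibble(channel = features$channel, layer = lay),
                     confidence = c(power_peak = prominence, phase_reversal = NA)))
  }
  lay[peak] <- "LM"
  # pyramidal layer: spike-band RMS maximum above the fissure
  above <- seq_len(max(peak - 1, 1))
  pyr <- above[which.max(features$spike_rms[above])]
  lay[pyr] <- "Pyr"
  if (pyr > 1) lay[1:(pyr - 1)] <- "Or"
  if (peak - pyr > 1) lay[(pyr + 1):(peak - 1)] <- "Rad"
  # CA1/DG boundary: first large phase flip below the fissure
  rev_size <- NA_real_
  if (peak < nch) {
    below <- peak:(nch - 1)
    dphi <- purrr::map_dbl(below, function(i) {
      d <- features$phase_offset[i + 1] - features$phase_offset[i]
      abs(atan2(sin(d), cos(d)))
    })
    flip <- which(dphi > pi / 2)
    if (length(flip) > 0) {
      b <- below[flip[1]]        # boundary between b and b+1
      rev_size <- dphi[flip[1]]
      if (b > peak) lay[(peak + 1):b] <- "LM"
      dg <- (b + 1):nch
      # DG block by order: Mol, then GC, then Hil
      k <- length(dg)
      n_mol <- max(1, round(k / 3)); n_gc <- max(1, round(k / 3))
      lay[dg[seq_len(n_mol)]] <- "Mol"
      if (k > n_mol) lay[dg[(n_mol + 1):min(n_mol + n_gc, k)]] <- "GC"
      if (k > n_mol + n_gc) lay[dg[(n_mol + n_gc + 1):k]] <- "Hil"
    }
  }
  structure(tibble(channel = features$channel, layer = lay),
            confidence = c(power_peak = prominence, phase_reversal = rev_size))
}
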