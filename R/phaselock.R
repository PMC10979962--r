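# Spike-theta phase locking: reference oscillations, Hilbert phase,
# per-unit (mu, r, Rayleigh p), population tables, and the MEC3
# trough/peak subclustering.

#' Reference channel for a named theta oscillation
#'
#' CA1 theta = topmost pyramidal-layer channel; DG theta = middle hilus
#' channel; MEC theta = middle channel of the combined MEC2+MEC3 block.
#'
#' @param cm Channel-map tibble.
#' @param reference One of "CA1_theta", "DG_theta", "MEC_theta".
#' @return 0-based channel index.
#' @export
reference_channel <- function(cm, reference = c("CA1_theta", "DG_theta", "MEC_theta")) {
  reference <- match.arg(reference)
  if (reference == "CA1_theta") {
    representative_channel(cm, "Pyr", which = "top")
  } else if (reference == "DG_theta") {
    representative_channel(cm, "Hil", which = "middle")
  } else {
    idx <- sort(c(layer_channels(cm, "MEC2"), layer_channels(cm, "MEC3")))
    assert_that(length(idx) > 0,
                sprintf("MEC2/MEC3 absent; available: %s", toString(unique(cm$layer))))
    idx[ceiling(length(idx) / 2)]
  }
}

#' Instantaneous theta phase via the Hilbert transform
#'
#' Analytic-signal angle of an already theta-bandpassed trace, wrapped to
#' `[0, 2*pi)`. Convention: phase 0 at the waveform peak, pi at the trough.
#'
#' @param x Theta-bandpassed signal vector.
#' @return Phase series in `[0, 2*pi)`.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(X * h, inverse = TRUE) / n
  wrap_2pi(Arg(analytic))
}

#' Phase-lock one unit to a reference phase series
#'
#' Samples the reference phase at spike times inside the analysis epochs,
#' computes the circular mean direction (mu) and resultant length (r), and
#' tests non-uniformity with the Rayleigh test. `mu` is reported only for
#' significantly locked units.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param phase Reference phase series in `[0, 2*pi)`.
#' @param fs Sampling rate of `phase`, Hz.
#' @param epochs_tbl Analysis epoch tibble.
#' @param min_spikes Minimum in-epoch spikes for a usable estimate.
#' @param alpha Rayleigh significance level.
#' @return A one-row tibble: `n_spikes`, `mu`, `r`, `rayleigh_p`,
#'   `significant`, `insufficient`.
#' @export
unit_phase_locking <- function(spike_times, phase, fs, epochs_tbl,
                               min_spikes = 20, alpha = 0.05) {
  st <- spike_times[in_epochs(spike_times, epochs_tbl)]
  st <- st[st < length(phase) / fs]
  n <- length(st)
  if (n < max(min_spikes, 5)) {
    return(tibble(n_spikes = n, mu = NA_real_, r = NA_real_,
                  rayleigh_p = NA_real_, significant = FALSE,
                  insufficient = TRUE))
  }
  # nearest-sample phase lookup (flooring would lag by half a sample,
  # biasing mu by pi * f_theta / fs)
  ph <- phase[pmin(round(st * fs) + 1, length(phase))]
  cm <- circ_mean_r(ph)
  rt <- rayleigh_test(ph)
  sig <- rt$p < alpha
  tibble(n_spikes = n, mu = ifelse(sig, cm$mu, NA_real_), r = cm$r,
         rayleigh_p = rt$p, significant = sig, insufficient = FALSE)
}

#' Built-in population/reference pairings
#'
#' The three standard pairings: DG inhibitory cells to CA1 theta, MEC2
#' excitatory cells to DG theta, MEC3 excitatory cells to CA1 theta.
#' @export
PHASE_LOCKING_PRESETS <- tibble::tibble(
  preset = c("DG_inh_to_CA1", "MEC2_exc_to_DG", "MEC3_exc_to_CA1"),
  region = c("HPC", "MEC", "MEC"),
  layer = c("Hil", "MEC2", "MEC3"),
  cls = c("inhibitory", "excitatory", "excitatory"),
  reference = c("CA1_theta", "DG_theta", "CA1_theta")
)

#' Phase-locking table for a selected population
#'
#' Filters classified units by region/layer/class (or a named preset), locks
#' each to the requested reference oscillation of its session, and returns
#' one row per unit. The `r`, firing-rate and count columns include every
#' unit with enough spikes; `mu` is populated only for significantly locked
#' units (Rayleigh gate).
#'
#' @param units Classified unit tibble (with `spike_times` list-column,
#'   `animal_id`, `region`, `layer`, `cls`).
#' @param phase_by_animal Named list: per animal, the reference phase series.
#' @param fs Sampling rate of the phase series, Hz.
#' @param epochs_by_animal Named list of analysis epoch tibbles per animal.
#' @param preset Optional preset name from [PHASE_LOCKING_PRESETS].
#' @param region,layer,cls Manual filters (ignored when `preset` given).
#' @param reference Reference label recorded in the output.
#' @param min_spikes Minimum in-epoch spike count.
#' @param alpha Rayleigh significance level for the mu gate.
#' @return A tibble of per-unit phase-locking results (insufficient-spike
#'   units are excluded), plus per-animal unit counts as attribute `counts`.
#' @export
population_table <- function(units, phase_by_animal, fs, epochs_by_animal,
                             preset = NULL, region = NULL, layer = NULL,
                             cls = NULL, reference = NA_character_,
                             min_spikes = 20, alpha = 0.05) {
  if (!is.null(preset)) {
    p <- dplyr::filter(PHASE_LOCKING_PRESETS, .data$preset == !!preset)
    assert_that(nrow(p) == 1, sprintf("unknown preset '%s'", preset))
    region <- p$region; layer <- p$layer; cls <- p$cls; reference <- p$reference
  }
  sel <- units
  if (!is.null(region)) sel <- dplyr::filter(sel, .data$region == !!region)
  if (!is.null(layer)) sel <- dplyr::filter(sel, .data$layer == !!layer)
  if (!is.null(cls)) sel <- dplyr::filter(sel, .data$cls == !!cls)
  if (nrow(sel) == 0) {
    return(tibble(unit_id = character(), animal_id = character(),
                  reference = character(), n_spikes = integer(),
                  mu = double(), r = double(), rayleigh_p = double(),
                  significant = logical(), firing_rate_hz = double()))
  }
  res <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    aid <- sel$animal_id[i]
    pl <- unit_phase_locking(sel$spike_times[[i]], phase_by_animal[[aid]],
                             fs, epochs_by_animal[[aid]],
                             min_spikes = min_spikes, alpha = alpha)
    dplyr::mutate(pl, unit_id = sel$unit_id[i], animal_id = aid,
                  group = sel$group[i], reference = reference,
                  firing_rate_hz = sel$firing_rate_hz[i], .before = 1)
  })
  res <- dplyr::filter(res, !.data$insufficient)
  counts <- dplyr::count(res, .data$animal_id, name = "n_units")
  attr(res, "counts") <- counts
  res
}

#' Cluster MEC3 excitatory units into trough- and peak-locked subpopulations
#'
#' K-means (k = 2, 50 seeded restarts) on the circularity-safe embedding
#' `(r*cos(mu), r*sin(mu))` of each unit's locking to local MEC theta.
#' The cluster whose circular mean preferred phase is nearer the theta trough
#' (pi) is labelled "trough_locked"; the other "peak_locked". Requires at
#' least `min_units` significantly locked units; low separation is flagged.
#'
#' @param local_results Phase-locking tibble (to local MEC theta) with `mu`,
#'   `r`, `significant` columns; only significant units are clustered.
#' @param min_units Minimum clusterable units.
#' @param seed Seed for the k-means restarts.
#' @param min_sep_rad Minimum angular separation of the two clusters' mean
#'   preferred phases; below it the split is flagged `low_separation` (a
#'   single phase cluster forced into two).
#' @return Input rows of clustered units with `cluster` and `low_separation`
#'   columns; zero rows (with a warning) when too few units.
#' @export
cluster_mec3 <- function(local_results, min_units = 6, seed = 1L,
                         min_sep_rad = pi / 3) {
  sig <- dplyr::filter(local_results, .data$significant & !is.na(.data$mu))
  if (nrow(sig) < min_units) {
    warn(sprintf("only %d significantly locked units (< %d): no clustering",
                 nrow(sig), min_units))
    return(dplyr::mutate(sig[0, ], cluster = character(),
                         low_separation = logical()))
  }
  emb <- cbind(sig$r * cos(sig$mu), sig$r * sin(sig$mu))
  km <- with_seed(derive_seed(seed, "mec3-cluster"),
                  kmeans(emb, centers = 2, nstart = 50))
  # trough cluster: circular mean of mu nearest pi
  dist_to_trough <- purrr::map_dbl(1:2, function(k) {
    mu_k <- circ_mean_r(sig$mu[km$cluster == k])$mu
    abs(atan2(sin(mu_k - pi), cos(mu_k - pi)))   # circular distance to pi
  })
  trough_k <- which.min(dist_to_trough)
  lab <- ifelse(km$cluster == trough_k, "trough_locked", "peak_locked")
  # separation check: angular distance between the clusters' mean phases
  mu1 <- circ_mean_r(sig$mu[km$cluster == 1])$mu
  mu2 <- circ_mean_r(sig$mu[km$cluster == 2])$mu
  sep <- abs(atan2(sin(mu1 - mu2), cos(mu1 - mu2)))
  dplyr::mutate(sig, cluster = lab, low_separation = sep < min_sep_rad)
}
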