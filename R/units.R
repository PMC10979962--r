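# Spike-train features and cell-class rules.
#
# HPC rule (from the recording literature this pipeline targets): excitatory
# iff rate < 8 Hz AND complex spike index > 0 AND mean autocorrelogram < 0.1
# AND trough-to-peak latency (c index) > 0.26; inhibitory iff rate > 0.2 Hz
# AND mean autocorrelogram > 0.1. MEC units are split by 1-D k-means on the
# c index (narrow waveform cluster = inhibitory).

#' Spike-train autocorrelogram
#'
#' Counts of spike-pair lags in `(0, window]` ms, mirrored to negative lags,
#' normalized by the number of spikes (so each bin is the expected number of
#' follower spikes per reference spike). The zero-lag bin is excluded.
#'
#' @param spike_times Sorted spike times, seconds (>= 50 spikes).
#' @param bin_ms Bin width, ms.
#' @param window_ms Half-window, ms.
#' @return A tibble with `lag_ms` (bin centers) and `value`.
#' @export
autocorrelogram <- function(spike_times, bin_ms = 1, window_ms = 50) {
  n <- length(spike_times)
  assert_that(n >= 50, "autocorrelogram requires >= 50 spikes")
  w <- window_ms / 1000
  # forward pairs within the window (spike times are sorted); lag order
  # widens until no spike pair at that order fits in the window
  lags <- numeric(0)
  ord <- 1L
  repeat {
    if (ord >= n) break
    d <- spike_times[(1 + ord):n] - spike_times[1:(n - ord)]
    d <- d[d <= w]
    if (length(d) == 0) break
    lags <- c(lags, d)
    ord <- ord + 1L
  }
  nb <- window_ms / bin_ms
  idx <- pmin(ceiling(lags * 1000 / bin_ms), nb)
  cnt <- tabulate(idx, nbins = nb)
  centers <- (seq_len(nb) - 0.5) * bin_ms
  tibble(lag_ms = c(-rev(centers), centers),
         value = c(rev(cnt), cnt) / n)
}

#' Mean of the autocorrelogram values
#' @inheritParams autocorrelogram
#' @return Mean bin value (dimensionless).
#' @export
mean_acg <- function(spike_times, bin_ms = 1, window_ms = 50) {
  mean(autocorrelogram(spike_times, bin_ms, window_ms)$value)
}

#' Complex spike index
#'
#' Burst amplitude-attenuation measure: over consecutive spike pairs with
#' inter-spike interval in `(3, 15]` ms,
#' `(n_decreasing - n_increasing) / n_pairs`. Positive values indicate the
#' amplitude-decrementing bursts typical of pyramidal cells.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param amplitudes Spike amplitudes (arbitrary units), same length.
#' @return A list with `csi` in `[-1, 1]` and `n_pairs`; `csi = 0` with
#'   `n_pairs = 0` when no pairs fall in the window.
#' @export
complex_spike_index <- function(spike_times, amplitudes) {
  assert_that(length(spike_times) == length(amplitudes),
              "amplitudes must match spike times")
  isi <- diff(spike_times)
  sel <- which(isi > 0.003 & isi <= 0.015)
  if (length(sel) == 0) return(list(csi = 0, n_pairs = 0L))
  d <- amplitudes[sel + 1] - amplitudes[sel]
  list(csi = (sum(d < 0) - sum(d > 0)) / length(sel),
       n_pairs = length(sel))
}

#' Classify HPC units as excitatory or inhibitory
#'
#' Applies the fixed HPC rule to a unit feature table. Units satisfying
#' neither rule, or both, are "unclassified" (the latter with a conflict
#' flag); units with missing csi cannot satisfy the excitatory rule.
#'
#' @param units Tibble with `firing_rate_hz`, `csi`, `mean_acg`, `c_index_ms`.
#' @param rate_max_exc,rate_min_inh,acg_thresh,c_index_thresh Rule thresholds.
#' @return The tibble with `cls` and `cls_conflict` columns replaced/added.
#' @export
classify_hpc <- function(units, rate_max_exc = 8, rate_min_inh = 0.2,
                         acg_thresh = 0.1, c_index_thresh = 0.26) {
  csi <- if ("csi" %in% names(units)) units$csi else rep(NA_real_, nrow(units))
  exc <- units$firing_rate_hz < rate_max_exc &
    !is.na(csi) & csi > 0 &
    units$mean_acg < acg_thresh &
    units$c_index_ms > c_index_thresh
  inh <- units$firing_rate_hz > rate_min_inh & units$mean_acg > acg_thresh
  cls <- dplyr::case_when(exc & !inh ~ "excitatory",
                          inh & !exc ~ "inhibitory",
                          TRUE ~ "unclassified")
  dplyr::mutate(units, cls = cls, cls_conflict = exc & inh)
}

#' Classify MEC units by k-means on trough-to-peak latency
#'
#' 1-D k-means (k = 2, 50 seeded restarts) on the c index; the cluster with
#' the smaller mean latency (narrow waveforms) is labelled inhibitory.
#' Degenerate inputs (< 4 units, or all identical latencies) leave all units
#' unclassified with a warning.
#'
#' @param units Tibble with a `c_index_ms` column.
#' @param seed Seed for the k-means restarts.
#' @return The tibble with a `cls` column replaced/added.
#' @export
classify_mec <- function(units, seed = 1L) {
  n <- nrow(units)
  if (n < 4 || length(unique(units$c_index_ms)) < 2) {
    if (n > 0) warn("too few or degenerate MEC units: all left unclassified")
    return(dplyr::mutate(units, cls = rep("unclassified", n)))
  }
  km <- with_seed(derive_seed(seed, "mec-kmeans"),
                  kmeans(matrix(units$c_index_ms, ncol = 1), centers = 2,
                         nstart = 50))
  inh_cluster <- which.min(km$centers)
  dplyr::mutate(units,
                cls = ifelse(km$cluster == inh_cluster, "inhibitory", "excitatory"))
}

#' Classify a mixed-region unit table
#'
#' Routes HPC units through the threshold rule and MEC units through k-means.
#'
#' @param units Unit tibble with `region` plus the feature columns.
#' @param seed Seed for the MEC k-means.
#' @param ... Thresholds forwarded to [classify_hpc()].
#' @return The tibble with a `cls` column.
#' @export
classify_units <- function(units, seed = 1L, ...) {
  hpc <- dplyr::filter(units, .data$region == "HPC")
  mec <- dplyr::filter(units, .data$region == "MEC")
  out <- dplyr::bind_rows(
    if (nrow(hpc) > 0) classify_hpc(hpc, ...) else hpc,
    if (nrow(mec) > 0) classify_mec(mec, seed = seed) else mec
  )
  out[match(units$unit_id, out$unit_id), ]
}
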