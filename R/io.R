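# Session and unit containers plus the on-disk layout:
#   <session>/lfp.bin      raw float32, little-endian, row-major [channels x samples]
#   <session>/session.json sampling rate, channel map, group, seizure epochs
#   <session>/behavior.csv t, position, speed
#   units.csv + spikes.json for sorted units

#' Recognized laminar labels
#'
#' Hippocampal sublayers run CA1 stratum oriens (Or) to the dentate lower
#' blade (LB); MEC layers 1-3 are labelled MEC1-MEC3.
#' @export
HPC_LAYERS <- c("Or", "Pyr", "Rad", "LM", "Mol", "GC", "Hil", "LB")

#' @rdname HPC_LAYERS
#' @export
MEC_LAYERS <- c("MEC1", "MEC2", "MEC3")

#' Canonical layer ordering used for sub-region matrices
#' @export
LAYER_ORDER <- c(HPC_LAYERS, MEC_LAYERS)

#' Experimental groups
#' @export
GROUPS <- c("control", "epi3wk", "epi8wk")

UNIT_CLASSES <- c("excitatory", "inhibitory", "unclassified")

validate_layer <- function(region, layer) {
  ok <- (is.na(layer) | layer == "UNASSIGNED") |
    (region == "HPC" & layer %in% HPC_LAYERS) |
    (region == "MEC" & layer %in% MEC_LAYERS)
  assert_that(all(ok), "layer labels must match their region (HPC: Or..LB; MEC: MEC1..MEC3)")
  invisible(TRUE)
}

#' Build a channel map
#'
#' @param channel 0-based channel indices (unique).
#' @param depth_um Depth along the shank, non-decreasing with index per shank.
#' @param region "HPC" or "MEC" per channel.
#' @param layer Laminar label per channel (or "UNASSIGNED").
#' @param shank Shank id per channel.
#' @return A tibble channel map.
#' @export
channel_map <- function(channel, depth_um, region, layer, shank = 0L) {
  assert_that(!anyDuplicated(channel), "channel indices must be unique")
  validate_layer(region, layer)
  tibble(channel = as.integer(channel), depth_um = as.double(depth_um),
         region = as.character(region), layer = as.character(layer),
         shank = as.integer(shank))
}

#' Construct an LFP session
#'
#' Bundles a laminar LFP matrix with its channel map, behavior trace and
#' seizure epochs for one recording.
#'
#' @param samples Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_map Tibble from [channel_map()].
#' @param animal_id Animal identifier.
#' @param group One of `r toString(GROUPS)`.
#' @param behavior Tibble with `t` (s, strictly increasing), `position` (m),
#'   `speed` (cm/s, non-negative).
#' @param seizures Epoch tibble of seizure intervals.
#' @return An object of class `lfp_session`.
#' @export
lfp_session <- function(samples, fs, channel_map, animal_id = "a1",
                        group = "control",
                        behavior = tibble(t = double(), position = double(), speed = double()),
                        seizures = epochs()) {
  assert_that(is.matrix(samples), "samples must be a channels x samples matrix")
  assert_that(fs > 0, "fs must be positive")
  assert_that(nrow(samples) == nrow(channel_map),
              "channel count mismatch between samples and channel map")
  assert_that(group %in% GROUPS, sprintf("group must be one of: %s", toString(GROUPS)))
  dur <- ncol(samples) / fs
  if (nrow(seizures) > 0) {
    assert_that(all(seizures$start >= 0) && all(seizures$end <= dur + 1e-9),
                "seizure epochs must lie within the recording")
  }
  if (nrow(behavior) > 0) {
    assert_that(all(diff(behavior$t) > 0), "behavior time must be strictly increasing")
    assert_that(all(behavior$speed >= 0), "speed must be non-negative")
  }
  structure(list(samples = samples, fs = as.double(fs), channel_map = channel_map,
                 animal_id = animal_id, group = group, behavior = behavior,
                 seizures = epochs_normalize(seizures)),
            class = "lfp_session")
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("<lfp_session> %s (%s): %d channels x %.1f s @ %g Hz, %d seizure epoch(s)\n",
              x$animal_id, x$group, nrow(x$samples), ncol(x$samples) / x$fs,
              x$fs, nrow(x$seizures)))
  invisible(x)
}

#' Session duration in seconds
#' @param session An `lfp_session`.
#' @export
session_duration <- function(session) ncol(session$samples) / session$fs

#' Write a session directory
#'
#' @param session An `lfp_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "lfp.bin"), "wb")
  on.exit(close(con), add = TRUE)
  # row-major: all samples of channel 1, then channel 2, ...
  writeBin(as.vector(t(session$samples)), con, size = 4, endian = "little")
  sidecar <- list(
    fs = session$fs,
    n_channels = nrow(session$samples),
    n_samples = ncol(session$samples),
    animal_id = session$animal_id,
    group = session$group,
    channel_map = session$channel_map,
    seizures = as.data.frame(session$seizures)
  )
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(session$behavior, file.path(path, "behavior.csv"), progress = FALSE)
  invisible(path)
}

#' Read a session directory
#'
#' @param path Directory written by [write_session()] (or following the same
#'   layout). Round-trips float32 payloads bit-exactly.
#' @return An `lfp_session`.
#' @export
read_session <- function(path) {
  for (f in c("lfp.bin", "session.json", "behavior.csv")) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("session file missing: %s", file.path(path, f)))
    }
  }
  sidecar <- jsonlite::read_json(file.path(path, "session.json"), simplifyVector = TRUE)
  for (f in c("fs", "n_channels", "channel_map")) {
    if (is.null(sidecar[[f]])) abort(sprintf("session.json is missing required field '%s'", f))
  }
  nch <- as.integer(sidecar$n_channels)
  nbytes <- file.size(file.path(path, "lfp.bin"))
  nfloat <- nbytes / 4
  if (nfloat %% nch != 0) {
    abort(sprintf("format error: lfp.bin holds %d floats, not divisible by %d channels",
                  nfloat, nch))
  }
  if (!is.null(sidecar$n_samples) && nfloat != nch * sidecar$n_samples) {
    abort("format error: lfp.bin size disagrees with session.json n_samples")
  }
  con <- file(file.path(path, "lfp.bin"), "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, "double", n = nfloat, size = 4, endian = "little")
  samples <- matrix(raw, nrow = nch, byrow = TRUE)
  cm <- as_tibble(sidecar$channel_map)
  cm$channel <- as.integer(cm$channel); cm$shank <- as.integer(cm$shank)
  sz <- sidecar$seizures
  seiz <- if (is.null(sz) || NROW(sz) == 0) epochs() else epochs(sz$start, sz$end)
  beh <- readr::read_csv(file.path(path, "behavior.csv"),
                         show_col_types = FALSE, progress = FALSE)
  lfp_session(samples, sidecar$fs, cm,
              animal_id = sidecar$animal_id %||% basename(path),
              group = sidecar$group %||% "control",
              behavior = beh, seizures = seiz)
}

#' Write unit records
#'
#' Scalar features go to `units.csv`; spike-time arrays to a companion
#' `spikes.json` keyed by `unit_id`.
#'
#' @param units Tibble with columns `unit_id`, `region`, `layer`,
#'   `spike_times` (list-column of sorted numeric vectors), optional
#'   `amplitudes` (list-column), `c_index_ms`, `mean_acg`, `csi`,
#'   `firing_rate_hz`, `cls`.
#' @param path Directory to write into.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path) {
  validate_units(units)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scalar <- dplyr::select(units, -dplyr::any_of(c("spike_times", "amplitudes")))
  readr::write_csv(scalar, file.path(path, "units.csv"), progress = FALSE)
  arr <- purrr::map(seq_len(nrow(units)), function(i) {
    list(spike_times = units$spike_times[[i]],
         amplitudes = if ("amplitudes" %in% names(units)) units$amplitudes[[i]] else NULL)
  })
  names(arr) <- units$unit_id
  jsonlite::write_json(arr, file.path(path, "spikes.json"), digits = 9, null = "null")
  invisible(path)
}

#' Read unit records
#' @param path Directory containing `units.csv` and `spikes.json`.
#' @return A units tibble (see [write_units()]); spike times preserved to
#'   better than 1e-6 s.
#' @export
read_units <- function(path) {
  fu <- file.path(path, "units.csv"); fj <- file.path(path, "spikes.json")
  if (!file.exists(fu)) abort(sprintf("units file missing: %s", fu))
  scalar <- readr::read_csv(fu, show_col_types = FALSE, progress = FALSE)
  if (nrow(scalar) == 0) {
    out <- as_tibble(scalar)
    out$spike_times <- list()
    return(out)
  }
  arr <- jsonlite::read_json(fj, simplifyVector = TRUE)
  scalar$unit_id <- as.character(scalar$unit_id)
  scalar$spike_times <- purrr::map(scalar$unit_id, function(id) {
    as.double(arr[[id]]$spike_times %||% numeric(0))
  })
  has_amp <- any(purrr::map_lgl(scalar$unit_id, function(id) !is.null(arr[[id]]$amplitudes)))
  if (has_amp) {
    scalar$amplitudes <- purrr::map(scalar$unit_id, function(id) {
      a <- arr[[id]]$amplitudes
      if (is.null(a)) NULL else as.double(a)
    })
  }
  out <- as_tibble(scalar)
  validate_units(out)
  out
}

validate_units <- function(units) {
  if (nrow(units) == 0) return(invisible(TRUE))
  if ("cls" %in% names(units)) {
    bad <- setdiff(unique(units$cls), UNIT_CLASSES)
    assert_that(length(bad) == 0,
                sprintf("unknown unit class: %s", toString(bad)))
  }
  sorted <- purrr::map_lgl(units$spike_times, function(st) !is.unsorted(st))
  assert_that(all(sorted), "spike times must be sorted for every unit")
  if (all(c("region", "layer") %in% names(units))) validate_layer(units$region, units$layer)
  invisible(TRUE)
}
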