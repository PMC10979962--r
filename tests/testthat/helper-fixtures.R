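# Small programmatic fixtures shared across test files.

# a channel map with one channel per requested layer
map_for_layers <- function(layers, regions = NULL) {
  if (is.null(regions)) {
    regions <- ifelse(layers %in% MEC_LAYERS, "MEC", "HPC")
  }
  channel_map(channel = seq_along(layers) - 1L,
              depth_um = seq_along(layers) * 50,
              region = regions, layer = layers)
}

# session whose channels are pure tones (or custom signals)
signal_session <- function(signals, fs, layers = NULL, group = "control",
                           behavior = NULL, seizures = epochs()) {
  m <- do.call(rbind, signals)
  if (is.null(layers)) layers <- HPC_LAYERS[seq_len(nrow(m))]
  beh <- behavior %||% tibble::tibble(t = numeric(), position = numeric(),
                                      speed = numeric())
  lfp_session(m, fs, map_for_layers(layers), animal_id = "test",
              group = group, behavior = beh, seizures = seizures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant-speed behavior trace
flat_behavior <- function(duration, speed, fs = 50) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  tibble::tibble(t = tt, position = (tt * speed / 100) %% 2,
                 speed = rep(speed, length(tt)))
}

whole_epochs <- function(duration) epochs(0, duration)

# three-unit fixture table for io round-trips
fixture_units <- function() {
  tibble::tibble(
    unit_id = c("u1", "u2", "u3"),
    region = c("HPC", "HPC", "MEC"),
    layer = c("Pyr", "Hil", "MEC2"),
    spike_times = list(c(0.1, 0.5, 1.25), c(0.2, 0.4), sort(runif(20, 0, 10))),
    firing_rate_hz = c(3, 2, 2),
    c_index_ms = c(0.5, 0.15, 0.6),
    mean_acg = c(0.05, 0.2, 0.04),
    csi = c(0.3, -0.1, 0.2),
    cls = c("excitatory", "inhibitory", "unclassified")
  )
}
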