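# Cohort-level orchestration: preprocessing -> spectral -> units ->
# phase locking -> subsampling, with tidy CSV outputs and a resolved-config
# record beside them. Deterministic given (data, config, seed).

#' Pipeline configuration with documented defaults
#'
#' Defaults equal the analysis constants used throughout the package: 1 kHz
#' target rate, 5-12 Hz theta band, 2 cm/s speed threshold, 3 s bouts,
#' 600 s post-seizure exclusion, Welch alpha 0.017 across three groups,
#' Rayleigh alpha 0.05, circular alpha ladder 0.017/0.003/0.0003, 20-spike
#' minimum, and the three anchor pairs with 5 retained-bin minimum.
#'
#' @param ... Overrides for any default field.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(fs_target = 1000, theta_band = c(5, 12), speed_thresh_cm_s = 2,
              min_bout_s = 3, seizure_post_s = 600, win_s = 2, nw = 3, k = 5,
              welch_alpha = 0.017, rayleigh_alpha = 0.05,
              circ_alphas = c(0.017, 0.003, 0.0003), min_spikes = 20,
              min_bins = 5, match_anchor = "MEC_HPC", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              sprintf("unknown config fields: %s", toString(unknown)))
  cfg[names(over)] <- over
  assert_that(cfg$theta_band[1] > 0 && cfg$theta_band[1] < cfg$theta_band[2],
              "invalid theta band")
  assert_that(all(diff(cfg$circ_alphas) < 0), "circ_alphas must decrease")
  structure(cfg, class = "pipeline_config")
}

read_cohort <- function(cohort_dir) {
  mf <- file.path(cohort_dir, "manifest.csv")
  paths <- if (file.exists(mf)) {
    readr::read_csv(mf, show_col_types = FALSE, progress = FALSE)$path
  } else {
    dirs <- list.dirs(cohort_dir, recursive = FALSE)
    dirs[file.exists(file.path(dirs, "session.json"))]
  }
  assert_that(length(paths) > 0, "cohort directory contains no sessions")
  sessions <- purrr::map(paths, read_session)
  names(sessions) <- purrr::map_chr(sessions, "animal_id")
  sessions
}

#' Run the full cohort analysis pipeline
#'
#' Executes preprocessing, spectral analysis (power profiles, sub-region
#' coherence matrices, cross-group Welch p-matrices), unit classification,
#' phase locking (the three preset populations, sequential circular group
#' comparisons, MEC3 subclustering), and the coherence-matched subsampling
#' dissociation, writing tidy CSVs to `out_dir`.
#'
#' @param cohort_dir Directory of session subdirectories (as written by
#'   [gen_cohort()]).
#' @param out_dir Output directory for result tables.
#' @param config A [pipeline_config()].
#' @return A list of the in-memory results (`power`, `coherence`,
#'   `pmatrix`, `units`, `phase_locking`, `mec3`, `dissociation`),
#'   invisibly; CSVs and `config.json` in `out_dir` are the on-disk record.
#' @export
run_pipeline <- function(cohort_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- read_cohort(cohort_dir)
  groups <- purrr::map_chr(sessions, "group")
  missing_groups <- setdiff(GROUPS, unique(groups))
  assert_that(length(missing_groups) == 0,
              sprintf("cohort lacks group(s): %s", toString(missing_groups)))
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  pre <- purrr::map(sessions, function(s) {
    preprocess_session(s, target_fs = min(config$fs_target, s$fs),
                       speed_thresh = config$speed_thresh_cm_s,
                       min_bout_s = config$min_bout_s,
                       seizure_post_s = config$seizure_post_s)
  })
  sess <- purrr::map(pre, "session")
  eps <- purrr::map(pre, "epochs")

  # per-layer theta power
  power <- purrr::map_dfr(names(sess), function(aid) {
    s <- sess[[aid]]
    layers <- unique(s$channel_map$layer)
    layers <- layers[layers %in% LAYER_ORDER]
    purrr::map_dfr(layers, function(ly) {
      ch <- representative_channel(s$channel_map, ly)
      tibble(animal_id = aid, group = s$group, layer = ly,
             theta_power = theta_power(s$samples[ch + 1, ], s$fs, eps[[aid]],
                                       band = config$theta_band,
                                       win_s = config$win_s,
                                       nw = config$nw, k = config$k))
    })
  })
  readr::write_csv(power, file.path(out_dir, "power_profile.csv"), progress = FALSE)

  # sub-region coherence matrices and p-matrices
  mats <- purrr::map(names(sess), function(aid) {
    subregion_matrix(sess[[aid]], eps[[aid]], band = config$theta_band,
                     win_s = config$win_s, nw = config$nw, k = config$k)
  })
  names(mats) <- names(sess)
  coh_long <- purrr::map_dfr(mats, tidy)
  readr::write_csv(coh_long, file.path(out_dir, "coherence_matrix.csv"),
                   progress = FALSE)
  pm <- purrr::map_dfr(c("epi3wk", "epi8wk"), function(g) {
    dplyr::mutate(
      group_pvalue_matrix(mats[groups == "control"], mats[groups == g],
                          alpha = config$welch_alpha),
      comparison = paste0("control_vs_", g), .before = 1)
  })
  readr::write_csv(pm, file.path(out_dir, "pmatrix.csv"), progress = FALSE)

  # units and phase locking (skipped for LFP-only cohorts)
  results <- list(power = power, coherence = coh_long, pmatrix = pm)
  unit_paths <- names(sess)[file.exists(file.path(cohort_dir, names(sess), "units.csv"))]
  if (length(unit_paths) > 0) {
    units <- purrr::map_dfr(unit_paths, function(aid) {
      u <- read_units(file.path(cohort_dir, aid))
      dplyr::mutate(u, animal_id = aid, group = groups[[aid]])
    })
    units <- classify_units(units, seed = config$seed)
    readr::write_csv(dplyr::select(units, -dplyr::any_of(c("spike_times", "amplitudes"))),
                     file.path(out_dir, "units_classified.csv"), progress = FALSE)

    refs <- c("CA1_theta", "DG_theta", "MEC_theta")
    phases <- purrr::map(refs, function(rf) {
      purrr::map(sess, function(s) {
        ch <- reference_channel(s$channel_map, rf)
        instantaneous_phase(bandpass_vec(s$samples[ch + 1, ], s$fs,
                                         config$theta_band))
      })
    })
    names(phases) <- refs
    pl <- purrr::map_dfr(PHASE_LOCKING_PRESETS$preset, function(ps) {
      rf <- PHASE_LOCKING_PRESETS$reference[PHASE_LOCKING_PRESETS$preset == ps]
      tb <- population_table(units, phases[[rf]], sess[[1]]$fs, eps,
                             preset = ps, min_spikes = config$min_spikes,
                             alpha = config$rayleigh_alpha)
      dplyr::mutate(tb, preset = ps, .before = 1)
    })
    pl_out <- dplyr::mutate(pl, mu_deg = rad2deg(.data$mu))
    readr::write_csv(pl_out, file.path(out_dir, "phase_locking.csv"),
                     progress = FALSE)
    results$units <- units
    results$phase_locking <- pl

    # sequential circular group comparisons on gated preferred phases
    circ <- purrr::map_dfr(unique(pl$preset), function(ps) {
      sub <- dplyr::filter(pl, .data$preset == ps, .data$significant,
                           !is.na(.data$mu))
      grps <- split(sub$mu, sub$group)
      grps <- grps[purrr::map_int(grps, length) >= 8]
      if (length(grps) < 2) return(NULL)
      dplyr::mutate(sequential_circular_comparison(grps,
                                                   alphas = config$circ_alphas,
                                                   seed = config$seed),
                    preset = ps, .before = 1)
    })
    if (nrow(circ) > 0) {
      readr::write_csv(circ, file.path(out_dir, "circ_comparisons.csv"),
                       progress = FALSE)
      results$circ_comparisons <- circ
    }

    # MEC3 trough/peak clustering on local MEC theta, per group
    mec3_units <- dplyr::filter(units, .data$layer == "MEC3",
                                .data$cls == "excitatory")
    if (nrow(mec3_units) > 0) {
      local_pl <- population_table(mec3_units, phases$MEC_theta, sess[[1]]$fs,
                                   eps, region = "MEC", layer = "MEC3",
                                   cls = "excitatory", reference = "MEC_theta",
                                   min_spikes = config$min_spikes)
      mec3 <- purrr::map_dfr(unique(local_pl$group), function(g) {
        sub <- dplyr::filter(local_pl, .data$group == g)
        cl <- tryCatch(cluster_mec3(sub, seed = config$seed),
                       warning = function(w) sub[0, ])
        if (nrow(cl) > 0) cl else NULL
      })
      if (nrow(mec3) > 0) {
        readr::write_csv(dplyr::mutate(mec3, mu_deg = rad2deg(.data$mu)),
                         file.path(out_dir, "mec3_clusters.csv"),
                         progress = FALSE)
        results$mec3 <- mec3
      }
    }
  }

  # subsampling dissociation (needs all anchor layers in every session)
  anchors_ok <- all(purrr::map_lgl(sess, function(s) {
    all(unique(unlist(anchor_pairs()[, c("layer_a", "layer_b")])) %in%
          s$channel_map$layer)
  }))
  if (anchors_ok) {
    diss <- dissociation_analysis(sess, eps, match_anchor = config$match_anchor,
                                  min_bins = config$min_bins,
                                  band = config$theta_band,
                                  win_s = config$win_s, nw = config$nw,
                                  k = config$k)
    readr::write_csv(diss$animal_table, file.path(out_dir, "subsample_report.csv"),
                     progress = FALSE)
    results$dissociation <- diss
  }
  invisible(results)
}
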