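# Coherence-matched subsampling: break each session into running-bout bins,
# compute anchor-pair theta coherence per bout, retain epileptic bouts within
# one standard deviation of the control group's pooled bout coherence, and
# re-test the remaining anchors on the retained bouts.

#' The three anchor layer pairs
#'
#' Cross-region MEC-HPC (MEC2 to the DG molecular layer), within-HPC (DG hilus
#' to CA1 pyramidal layer) and within-MEC (MEC2 to MEC3).
#'
#' @return A tibble with `anchor`, `layer_a`, `layer_b`.
#' @export
anchor_pairs <- function() {
  tibble(anchor = c("MEC_HPC", "within_HPC", "within_MEC"),
         layer_a = c("MEC2", "Hil", "MEC2"),
         layer_b = c("Mol", "Pyr", "MEC3"))
}

#' Per-bout theta coherence for one layer pair
#'
#' One multitaper coherence value per running bout between the pair's
#' representative channels; bouts shorter than one analysis window are
#' skipped and flagged.
#'
#' @param session An `lfp_session`.
#' @param layer_a,layer_b Layer labels of the pair.
#' @param bouts Epoch tibble of running bouts.
#' @param band,win_s,nw,k Spectral parameters (see [theta_coherence()]).
#' @return A tibble: `bout` (index), `start`, `end`, `coherence` (`NA` for
#'   skipped bouts), `skipped`.
#' @export
per_bout_coherence <- function(session, layer_a, layer_b, bouts,
                               band = c(5, 12), win_s = 2, nw = 3, k = 5) {
  ca <- representative_channel(session$channel_map, layer_a)
  cb <- representative_channel(session$channel_map, layer_b)
  x <- session$samples[ca + 1, ]; y <- session$samples[cb + 1, ]
  fs <- session$fs
  nb <- nrow(bouts)
  coh <- rep(NA_real_, nb)
  skipped <- rep(TRUE, nb)
  for (i in seq_len(nb)) {
    if (bouts$end[i] - bouts$start[i] < win_s) next
    wins <- epoch_windows(bouts[i, ], fs, length(x), win_s)
    if (length(wins$starts) == 0) next
    sp <- mt_spectra(x, y, fs, wins$starts, wins$n, nw, k, band = band)
    coh[i] <- mean(pmin(Mod(sp$Sxy) / sqrt(sp$Sxx * sp$Syy), 1))
    skipped[i] <- FALSE
  }
  tibble(bout = seq_len(nb), start = bouts$start, end = bouts$end,
         coherence = coh, skipped = skipped)
}

#' Control-group anchor statistics
#'
#' Mean and standard deviation of the pooled per-bout coherence values across
#' all control animals (matching operates on bouts, so bouts are pooled).
#'
#' @param control_bouts List (one element per control animal) of per-bout
#'   coherence tibbles from [per_bout_coherence()].
#' @return A list with `mean`, `sd`, `n_bouts`.
#' @export
control_anchor_stats <- function(control_bouts) {
  assert_that(length(control_bouts) >= 2, "need at least 2 control animals")
  v <- unlist(purrr::map(control_bouts, function(b) b$coherence[!b$skipped]))
  v <- v[!is.na(v)]
  assert_that(length(v) >= 2, "need at least 2 usable control bouts")
  list(mean = mean(v), sd = sd(v), n_bouts = length(v))
}

#' Retain bouts within one control standard deviation
#'
#' Bout `i` is retained iff `|c_i - mean_ctrl| <= sd_ctrl`. The retention
#' rule is monotone in `sd_ctrl`.
#'
#' @param bout_values Per-bout coherence values (skipped bouts `NA`).
#' @param control_stats List with `mean` and `sd` from
#'   [control_anchor_stats()].
#' @param min_bins Minimum retained bouts for the animal to stay in the
#'   subsampled dataset.
#' @return A list with `retained` (indices), `n_retained`, `fraction`
#'   (of usable bouts), `excluded` (too few retained).
#' @export
subsample_bins <- function(bout_values, control_stats, min_bins = 5) {
  assert_that(control_stats$sd >= 0, "control sd must be non-negative")
  usable <- which(!is.na(bout_values))
  keep <- usable[abs(bout_values[usable] - control_stats$mean) <= control_stats$sd]
  list(retained = keep, n_retained = length(keep),
       fraction = if (length(usable) > 0) length(keep) / length(usable) else NA_real_,
       excluded = length(keep) < min_bins)
}

anchor_anova <- function(df) {
  # one-way ANOVA on per-animal mean coherence across groups
  df <- dplyr::filter(df, !is.na(.data$coherence))
  sizes <- table(df$group)
  if (length(sizes) < 2 || sum(sizes) <= length(sizes)) return(NA_real_)
  tryCatch(unname(oneway.test(coherence ~ group, data = df,
                              var.equal = TRUE)$p.value),
           error = function(e) NA_real_)
}

#' Coherence-matched subsampling dissociation analysis
#'
#' For every animal, computes per-bout theta coherence on all three anchor
#' pairs; pools the control group's bouts on the matching anchor to get the
#' (mean, SD) band; retains epileptic bouts inside the band (control animals
#' keep all bouts); drops animals with fewer than `min_bins` retained bouts
#' from all subsampled comparisons; and runs one-way ANOVAs across groups on
#' per-animal mean coherence for each anchor, in the original and subsampled
#' datasets. Matching is verified by requiring the matched anchor to be
#' non-significant after subsampling; failure is reported but downstream
#' tests are still emitted.
#'
#' @param sessions Named list of `lfp_session` objects (all groups).
#' @param bouts_by_animal Named list of running-bout epoch tibbles.
#' @param match_anchor Anchor to match on ("MEC_HPC", "within_HPC",
#'   "within_MEC").
#' @param min_bins Minimum retained bouts per epileptic animal.
#' @param alpha Significance level for the group ANOVAs.
#' @param subsampled_estimate "mean_of_bouts" (default) averages retained
#'   per-bout values; "concatenated" re-estimates coherence over the retained
#'   bouts jointly.
#' @param band,win_s,nw,k Spectral parameters.
#' @return A `dissociation_result` list: `bout_table` (per animal x anchor x
#'   bout), `animal_table` (per animal x anchor: original and subsampled
#'   coherence, retention), `anova` (per anchor x dataset p-values),
#'   `matching_ok`, `excluded_animals`, `retained` (per-animal indices).
#' @export
dissociation_analysis <- function(sessions, bouts_by_animal,
                                  match_anchor = "MEC_HPC", min_bins = 5,
                                  alpha = 0.05,
                                  subsampled_estimate = c("mean_of_bouts", "concatenated"),
                                  band = c(5, 12), win_s = 2, nw = 3, k = 5) {
  subsampled_estimate <- match.arg(subsampled_estimate)
  anchors <- anchor_pairs()
  assert_that(match_anchor %in% anchors$anchor, "unknown match anchor")
  aids <- names(sessions)
  groups <- purrr::map_chr(sessions, "group")

  bout_table <- purrr::map_dfr(aids, function(aid) {
    purrr::map_dfr(seq_len(nrow(anchors)), function(j) {
      bt <- per_bout_coherence(sessions[[aid]], anchors$layer_a[j],
                               anchors$layer_b[j], bouts_by_animal[[aid]],
                               band = band, win_s = win_s, nw = nw, k = k)
      dplyr::mutate(bt, animal_id = aid, group = groups[[aid]],
                    anchor = anchors$anchor[j], .before = 1)
    })
  })

  ctrl_ids <- aids[groups == "control"]
  ctrl_bouts <- purrr::map(ctrl_ids, function(aid) {
    dplyr::filter(bout_table, .data$animal_id == aid,
                  .data$anchor == match_anchor)
  })
  stats <- control_anchor_stats(ctrl_bouts)

  retained <- purrr::map(aids, function(aid) {
    mv <- dplyr::filter(bout_table, .data$animal_id == aid,
                        .data$anchor == match_anchor)
    if (groups[[aid]] == "control") {
      list(retained = mv$bout[!is.na(mv$coherence)],
           n_retained = sum(!is.na(mv$coherence)), fraction = 1,
           excluded = FALSE)
    } else {
      subsample_bins(mv$coherence, stats, min_bins = min_bins)
    }
  })
  names(retained) <- aids
  excluded <- aids[purrr::map_lgl(retained, "excluded")]

  animal_table <- purrr::map_dfr(aids, function(aid) {
    purrr::map_dfr(anchors$anchor, function(an) {
      bv <- dplyr::filter(bout_table, .data$animal_id == aid, .data$anchor == an)
      orig <- mean(bv$coherence, na.rm = TRUE)
      keep <- retained[[aid]]$retained
      sub <- if (aid %in% excluded) {
        NA_real_
      } else if (subsampled_estimate == "mean_of_bouts") {
        mean(bv$coherence[bv$bout %in% keep], na.rm = TRUE)
      } else {
        kb <- bv[bv$bout %in% keep & !bv$skipped, c("start", "end")]
        anch <- anchors[anchors$anchor == an, ]
        if (nrow(kb) == 0) NA_real_ else {
          s <- sessions[[aid]]
          ca <- representative_channel(s$channel_map, anch$layer_a)
          cb <- representative_channel(s$channel_map, anch$layer_b)
          theta_coherence(s$samples[ca + 1, ], s$samples[cb + 1, ], s$fs,
                          kb, band = band, win_s = win_s, nw = nw, k = k)
        }
      }
      tibble(animal_id = aid, group = groups[[aid]], anchor = an,
             n_bouts = sum(!is.na(bv$coherence)),
             n_retained = retained[[aid]]$n_retained,
             retained_fraction = retained[[aid]]$fraction,
             coherence_original = orig, coherence_subsampled = sub,
             excluded = aid %in% excluded)
    })
  })

  anova_tbl <- purrr::map_dfr(anchors$anchor, function(an) {
    at <- dplyr::filter(animal_table, .data$anchor == an)
    p_orig <- anchor_anova(dplyr::transmute(at, group = .data$group,
                                            coherence = .data$coherence_original))
    p_sub <- anchor_anova(dplyr::transmute(
      dplyr::filter(at, !.data$excluded), group = .data$group,
      coherence = .data$coherence_subsampled))
    tibble(anchor = an,
           p_original = p_orig, p_subsampled = p_sub,
           significant_original = !is.na(p_orig) & p_orig < alpha,
           significant_subsampled = !is.na(p_sub) & p_sub < alpha)
  })

  matching_ok <- !anova_tbl$significant_subsampled[anova_tbl$anchor == match_anchor]
  if (!matching_ok) {
    warn(sprintf("matching on %s failed: matched anchor still significant in subsample",
                 match_anchor))
  }
  structure(list(match_anchor = match_anchor, control_stats = stats,
                 bout_table = bout_table, animal_table = animal_table,
                 anova = anova_tbl, matching_ok = matching_ok,
                 excluded_animals = excluded,
                 retained = purrr::map(retained, "retained")),
            class = "dissociation_result")
}

#' @export
print.dissociation_result <- function(x, ...) {
  cat(sprintf("<dissociation_result> matched on %s (matching %s)\n",
              x$match_anchor, if (x$matching_ok) "succeeded" else "FAILED"))
  print(as.data.frame(x$anova))
  if (length(x$excluded_animals) > 0) {
    cat("excluded (insufficient retained bins):",
        toString(x$excluded_animals), "\n")
  }
  invisible(x)
}

#' Tidy a dissociation result
#' @param x A `dissociation_result`.
#' @param ... Unused.
#' @return The per-animal/anchor tibble.
#' @export
tidy.dissociation_result <- function(x, ...) x$animal_table

#' One-line summary of a dissociation result
#' @param x A `dissociation_result`.
#' @param ... Unused.
#' @return A one-row tibble: match anchor, matching success, number of
#'   excluded animals, and per-anchor subsampled significance.
#' @export
glance.dissociation_result <- function(x, ...) {
  sig <- x$anova$significant_subsampled
  names(sig) <- paste0("sig_sub_", x$anova$anchor)
  dplyr::bind_cols(tibble(match_anchor = x$match_anchor,
                          matching_ok = x$matching_ok,
                          n_excluded = length(x$excluded_animals)),
                   as_tibble(as.list(sig)))
}

#' Generate a scenario cohort in memory and run the dissociation analysis
#'
#' Convenience wrapper: builds a [dissociation_cohort_spec()] cohort (in
#' memory, no disk I/O), detects running bouts, and runs
#' [dissociation_analysis()] matched on the requested anchor.
#'
#' @param mechanism "independent" or "shared" (see
#'   [dissociation_cohort_spec()]).
#' @param match_anchor Anchor to match on.
#' @param seed Integer seed for the whole replicate.
#' @param n_per_group,duration_s,fs Cohort size parameters.
#' @param ... Passed to [dissociation_analysis()].
#' @return A `dissociation_result`.
#' @export
run_dissociation_replicate <- function(mechanism, match_anchor, seed,
                                       n_per_group = 6, duration_s = 600,
                                       fs = 250, ...) {
  spec <- dissociation_cohort_spec(mechanism, n_per_group = n_per_group,
                                   duration_s = duration_s, fs = fs,
                                   seed = seed)
  sessions <- list(); bouts <- list()
  for (g in GROUPS) {
    for (i in seq_len(spec$n_animals[[g]])) {
      aid <- sprintf("%s_%02d", g, i)
      res <- gen_session(spec, g, aid, derive_seed(seed, g, i))
      sessions[[aid]] <- res$session
      bouts[[aid]] <- detect_locomotion(res$session$behavior)
    }
  }
  dissociation_analysis(sessions, bouts, match_anchor = match_anchor, ...)
}

#' Overlap of retained bouts between subsampling runs
#'
#' Jaccard fraction of retained bout indices, per animal and pooled, for two
#' dissociation results computed on the same sessions.
#'
#' @param res_a,res_b `dissociation_result` objects on identical session sets.
#' @return A tibble with per-animal rows plus a pooled row
#'   (`animal_id = "(pooled)"`).
#' @export
subsample_overlap <- function(res_a, res_b) {
  ids <- intersect(names(res_a$retained), names(res_b$retained))
  assert_that(length(ids) > 0, "results share no sessions")
  assert_that(setequal(names(res_a$retained), names(res_b$retained)),
              "results must cover the same session set")
  per <- purrr::map_dfr(ids, function(aid) {
    a <- res_a$retained[[aid]]; b <- res_b$retained[[aid]]
    u <- length(union(a, b))
    tibble(animal_id = aid,
           jaccard = if (u == 0) NA_real_ else length(intersect(a, b)) / u)
  })
  ai <- sum(purrr::map_int(ids, function(aid) {
    length(intersect(res_a$retained[[aid]], res_b$retained[[aid]]))
  }))
  au <- sum(purrr::map_int(ids, function(aid) {
    length(union(res_a$retained[[aid]], res_b$retained[[aid]]))
  }))
  dplyr::bind_rows(per, tibble(animal_id = "(pooled)",
                               jaccard = if (au == 0) NA_real_ else ai / au))
}
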