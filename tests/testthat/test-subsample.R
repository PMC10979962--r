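test_that("anchor pairs carry the fixed layer definitions", {
  ap <- anchor_pairs()
  expect_equal(ap$layer_a[ap$anchor == "MEC_HPC"], "MEC2")
  expect_equal(ap$layer_b[ap$anchor == "MEC_HPC"], "Mol")
  expect_equal(unlist(ap[ap$anchor == "within_HPC", 2:3], use.names = FALSE),
               c("Hil", "Pyr"))
  expect_equal(unlist(ap[ap$anchor == "within_MEC", 2:3], use.names = FALSE),
               c("MEC2", "MEC3"))
})

test_that("per-bout coherence yields one value per usable bout", {
  spec <- dissociation_cohort_spec("shared", n_per_group = 1, duration_s = 120,
                                   fs = 250, seed = 3)
  res <- gen_session(spec, "control", "c1", seed = 7)
  s <- res$session
  bouts <- detect_locomotion(s$behavior)
  bt <- per_bout_coherence(s, "Hil", "Pyr", bouts)
  expect_equal(nrow(bt), nrow(bouts))
  ok <- bt$coherence[!bt$skipped]
  expect_true(all(ok >= 0 & ok <= 1))
  expect_true(all(bt$skipped == (bouts$end - bouts$start < 2)))
  # deterministic
  bt2 <- per_bout_coherence(s, "Hil", "Pyr", bouts)
  expect_identical(bt, bt2)
  # bout-wise mean approximates the whole-bout-set estimate
  whole <- theta_coherence(
    s$samples[representative_channel(s$channel_map, "Hil") + 1, ],
    s$samples[representative_channel(s$channel_map, "Pyr") + 1, ],
    s$fs, bouts)
  expect_equal(mean(ok), whole, tolerance = 0.06)
})

test_that("control stats pool bouts and subsampling retains the +/-1 SD band", {
  b1 <- tibble::tibble(coherence = rep(0.6, 10), skipped = FALSE)
  b2 <- tibble::tibble(coherence = rep(0.6, 5), skipped = FALSE)
  st <- control_anchor_stats(list(b1, b2))
  expect_equal(st$mean, 0.6)
  expect_equal(st$sd, 0)
  expect_error(control_anchor_stats(list(b1)), "2 control")

  set.seed(4)
  vals <- rnorm(400, 0.6, 0.1)
  stn <- control_anchor_stats(list(tibble::tibble(coherence = vals,
                                                  skipped = FALSE),
                                   tibble::tibble(coherence = numeric(),
                                                  skipped = logical())))
  expect_lt(abs(stn$mean - 0.6), 0.02)
  expect_lt(abs(stn$sd - 0.1), 0.02)

  # exact-match retention at sd = 0
  sb <- subsample_bins(c(0.6, 0.7, 0.6), list(mean = 0.6, sd = 0))
  expect_equal(sb$retained, c(1L, 3L))
  expect_true(sb$excluded)  # fewer than 5 bins

  # all bouts below the band: excluded with none retained
  sb2 <- subsample_bins(rep(0.3, 20), list(mean = 0.8, sd = 0.1))
  expect_equal(sb2$n_retained, 0)
  expect_true(sb2$excluded)

  # retention is monotone in the control SD
  v <- rnorm(50, 0.5, 0.2)
  r1 <- subsample_bins(v, list(mean = 0.5, sd = 0.05))$retained
  r2 <- subsample_bins(v, list(mean = 0.5, sd = 0.15))$retained
  expect_true(all(r1 %in% r2))
})

test_that("subsample overlap is Jaccard per animal and pooled", {
  fake <- function(lst) structure(list(retained = lst), class = "dissociation_result")
  a <- fake(list(x = 1:4, y = 1:2))
  b <- fake(list(x = 1:4, y = 3:4))
  ov <- subsample_overlap(a, b)
  expect_equal(ov$jaccard[ov$animal_id == "x"], 1)
  expect_equal(ov$jaccard[ov$animal_id == "y"], 0)
  expect_equal(ov$jaccard[ov$animal_id == "(pooled)"], 4 / 8)
  expect_error(subsample_overlap(a, fake(list(z = 1:2))), "share no sessions")
})

test_that("an all-control cohort is barely changed by subsampling", {
  spec <- dissociation_cohort_spec("shared", n_per_group = 2, duration_s = 420,
                                   fs = 250, seed = 11)
  sessions <- list(); bouts <- list()
  for (g in GROUPS) {
    for (i in 1:2) {
      aid <- sprintf("%s_%d", g, i)
      # identical desync statistics for every group: a null cohort
      res <- gen_session(spec, "control", aid, seed = derive_seed(99, aid))
      res$session$group <- g
      sessions[[aid]] <- res$session
      bouts[[aid]] <- detect_locomotion(res$session$behavior)
    }
  }
  d <- dissociation_analysis(sessions, bouts, match_anchor = "within_HPC",
                             min_bins = 3)
  expect_true(d$matching_ok)
  at <- d$animal_table
  # per-anchor group means move by < 0.02 under the null
  for (an in anchor_pairs()$anchor) {
    sub <- at[at$anchor == an & !at$excluded, ]
    expect_lt(abs(mean(sub$coherence_subsampled, na.rm = TRUE) -
                    mean(sub$coherence_original, na.rm = TRUE)), 0.02)
  }
  # epileptic-labelled animals drawn from the control distribution retain
  # most of their bouts
  epi <- at[at$group != "control" & at$anchor == "within_HPC", ]
  expect_true(all(epi$retained_fraction >= 0.6))
})
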