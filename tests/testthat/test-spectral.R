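test_that("dpss tapers are orthonormal at both exact and interpolated lengths", {
  for (n in c(200, 1000)) {
    v <- dpss_tapers(n, 3, 5)
    expect_equal(dim(v), c(n, 5))
    expect_equal(crossprod(v), diag(5), tolerance = 1e-3)
  }
})

test_that("theta power scales quadratically and ranks signals", {
  fs <- 500
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 8 * tt)
  ep <- epochs(0, 30)
  p1 <- theta_power(x, fs, ep)
  p2 <- theta_power(2 * x, fs, ep)
  expect_equal(p2 / p1, 4, tolerance = 1e-9)

  set.seed(2)
  wn <- rnorm(length(tt))
  expect_gt(theta_power(wn + x, fs, ep), theta_power(wn, fs, ep))

  # stationarity: concatenating identical epochs leaves the estimate unchanged
  pa <- theta_power(x, fs, epochs(0, 10))
  pb <- theta_power(x, fs, epochs(c(0, 10), c(10, 20)))
  expect_equal(pa, pb, tolerance = 1e-6)

  expect_error(theta_power(x, fs, epochs(0, 1)), "insufficient")
})

test_that("coherence: self-unity, scale invariance, null level", {
  fs <- 500
  set.seed(3)
  n <- 150 * fs
  x <- rnorm(n); y <- rnorm(n)
  ep <- epochs(0, 150)
  expect_equal(theta_coherence(x, x, fs, ep), 1, tolerance = 1e-9)
  expect_lt(theta_coherence(x, y, fs, ep), 0.15)
  c1 <- theta_coherence(x, x + y, fs, ep)
  expect_equal(theta_coherence(3.7 * x, -0.4 * (x + y), fs, ep), c1,
               tolerance = 1e-9)
})

test_that("power and coherence ignore out-of-epoch samples", {
  fs <- 500
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  set.seed(4)
  x <- cos(2 * pi * 8 * tt) + rnorm(length(tt), 0, 0.3)
  y <- cos(2 * pi * 8 * tt + 1) + rnorm(length(tt), 0, 0.3)
  ep <- epochs(c(2, 20), c(10, 30))
  p0 <- theta_power(x, fs, ep)
  c0 <- theta_coherence(x, y, fs, ep)
  corrupt <- !in_epochs(tt, ep)
  x[corrupt] <- 1e6; y[corrupt] <- -1e6
  expect_equal(theta_power(x, fs, ep), p0)
  expect_equal(theta_coherence(x, y, fs, ep), c0)
})

test_that("sub-region matrices are symmetric with unit diagonal and NA gaps", {
  osc <- oscillator_params(duration_s = 40, fs = 250)
  ch <- channel_gen_params(c("Pyr", "LM", "Hil"), "HPC", theta_amp = 100,
                           coupling = list(c(H = 0.9), c(H = 0.9), c(H = 0.9)),
                           phase_offset = c(0, 1, pi), noise_amp = 10)
  l <- gen_lfp(ch, osc, seed = 6)
  s <- signal_session(asplit(l$samples, 1), 250, layers = c("Pyr", "LM", "Hil"))
  m <- subregion_matrix(s, epochs(0, 40))
  mm <- unclass(m)
  expect_equal(mm["Pyr", "Pyr"], 1)
  expect_equal(mm["Pyr", "Hil"], mm["Hil", "Pyr"])
  expect_true(all(is.na(mm["Or", ])))
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_true(all(td$coherence >= 0 & td$coherence <= 1))

  one <- signal_session(list(rnorm(1000)), 250, layers = "Pyr")
  expect_error(subregion_matrix(one, epochs(0, 4)), "two labelled layers")
})

test_that("group p-matrix signs follow the mean difference", {
  mk <- function(vals, id) {
    m <- matrix(NA_real_, length(LAYER_ORDER), length(LAYER_ORDER),
                dimnames = list(LAYER_ORDER, LAYER_ORDER))
    m["Pyr", "Hil"] <- m["Hil", "Pyr"] <- vals[1]
    m["Pyr", "LM"] <- m["LM", "Pyr"] <- vals[2]
    diag(m)[c("Pyr", "Hil", "LM")] <- 1
    structure(m, class = c("coherence_matrix", "matrix"), animal_id = id,
              group = "x")
  }
  set.seed(7)
  A <- lapply(1:6, function(i) mk(c(0.8, 0.5) + rnorm(2, 0, 0.02), i))
  B <- lapply(1:6, function(i) mk(c(0.4, 0.8) + rnorm(2, 0, 0.02), i))
  pm <- group_pvalue_matrix(A, B, alpha = 0.017)
  expect_equal(pm$sign[pm$layer_a == "Pyr" & pm$layer_b == "Hil"], "decrease")
  expect_equal(pm$sign[pm$layer_a == "Pyr" & pm$layer_b == "LM"], "increase")

  # a layer missing from one group yields a flagged n.s. cell
  A2 <- lapply(A, function(m) { m["LM", ] <- NA; m[, "LM"] <- NA; m })
  A2 <- lapply(seq_along(A2), function(i) {
    structure(A2[[i]], class = c("coherence_matrix", "matrix"),
              animal_id = i, group = "x")
  })
  pm2 <- group_pvalue_matrix(A2[1:6], B, alpha = 0.017)
  cell <- pm2[pm2$layer_a == "Pyr" & pm2$layer_b == "LM", ]
  expect_true(cell$missing)
  expect_equal(cell$sign, "n.s.")
})

test_that("identical groups reject at about the nominal alpha", {
  set.seed(8)
  mkv <- function() {
    m <- matrix(NA_real_, length(LAYER_ORDER), length(LAYER_ORDER),
                dimnames = list(LAYER_ORDER, LAYER_ORDER))
    m["Pyr", "Hil"] <- m["Hil", "Pyr"] <- 0.6 + rnorm(1, 0, 0.05)
    structure(m, class = c("coherence_matrix", "matrix"), animal_id = "a",
              group = "x")
  }
  hits <- replicate(400, {
    pm <- group_pvalue_matrix(replicate(6, mkv(), simplify = FALSE),
                              replicate(6, mkv(), simplify = FALSE),
                              alpha = 0.05)
    pm$sign[1] != "n.s."
  })
  expect_gt(mean(hits), 0.02); expect_lt(mean(hits), 0.09)
})

test_that("seizure correlation handles exact, null and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  r <- metric_vs_seizure_correlation(x, x)
  expect_equal(r$r, 1)
  expect_error(metric_vs_seizure_correlation(c(1, 2), c(1, 2)), "at least 3")
  z <- metric_vs_seizure_correlation(rep(1, 5), x)
  expect_true(is.na(z$r))
  set.seed(9)
  rr <- replicate(300, metric_vs_seizure_correlation(rnorm(20), rnorm(20))$p < 0.05)
  expect_lt(mean(rr), 0.1)
})
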