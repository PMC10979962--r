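test_that("circular mean and resultant length match closed forms", {
  cm <- circ_mean_r(rep(pi / 2, 10))
  expect_equal(cm$mu, pi / 2)
  expect_equal(cm$r, 1)

  anti <- circ_mean_r(c(0, pi))
  expect_equal(anti$r, 0, tolerance = 1e-12)
  expect_true(is.na(anti$mu))

  # von Mises sample recovers the Bessel-ratio resultant
  set.seed(21)
  x <- rvonmises(5000, 1, 4)
  cm <- circ_mean_r(x)
  expect_equal(cm$r, von_mises_r(4), tolerance = 0.02)
  expect_equal(cm$mu, 1, tolerance = 0.05)
})

test_that("r is order-invariant and all statistics rotation-invariant", {
  set.seed(2)
  x <- rvonmises(60, 2, 1.5)
  y <- rvonmises(60, 2.5, 1.5)
  expect_equal(circ_mean_r(sample(x))$r, circ_mean_r(x)$r)
  for (rot in c(0.7, 3.1, 5.5)) {
    expect_equal(rayleigh_test(wrap_2pi(x + rot))$p, rayleigh_test(x)$p)
    k1 <- kuiper_two_sample(x, y, seed = 9)
    k2 <- kuiper_two_sample(wrap_2pi(x + rot), wrap_2pi(y + rot), seed = 9)
    expect_equal(k2$V, k1$V, tolerance = 1e-12)
    expect_equal(concentration_k_test(wrap_2pi(x + rot), wrap_2pi(y + rot))$p,
                 concentration_k_test(x, y)$p, tolerance = 1e-10)
  }
})

test_that("Rayleigh test is extreme under concentration, monotone in R", {
  expect_lt(rayleigh_test(rep(1.3, 100))$p, 1e-10)
  expect_error(rayleigh_test(runif(4, 0, 2 * pi)), "n >= 5")

  # p decreases as concentration grows at fixed n
  n <- 80
  ps <- sapply(c(0.05, 0.15, 0.3, 0.5), function(R) {
    # construct a sample with exact resultant R: two antipodal groups
    k <- round(n * (1 + R) / 2)
    rayleigh_test(c(rep(0, k), rep(pi, n - k)))$p
  })
  expect_true(all(diff(ps) < 0))
})

test_that("Kuiper test: identity, asymptotic/permutation agreement, power", {
  set.seed(31)
  x <- rvonmises(100, 0, 2)
  same <- kuiper_two_sample(x, x)
  expect_gt(same$p, 0.95)

  # asymptotic vs permutation p within 0.02 at n = 100
  for (i in 1:4) {
    a <- rvonmises(100, 0, 1)
    b <- rvonmises(100, 0.45, 1)
    pa <- kuiper_two_sample(a, b)$p
    pp <- kuiper_two_sample(a, b, perm_threshold = 200, n_perm = 2000,
                            seed = i)$p
    expect_lt(abs(pa - pp), 0.02)
  }

  # opposite preferred phases: decisively rejected
  pw <- replicate(30, kuiper_two_sample(rvonmises(100, 0, 2),
                                        rvonmises(100, pi, 2))$p)
  expect_true(all(pw < 0.001))
})

test_that("concentration test: identity, regimes, power", {
  set.seed(41)
  x <- rvonmises(150, 1, 2)
  expect_gt(concentration_k_test(x, x)$p, 0.9)

  # regime selection by pooled resultant length
  expect_equal(concentration_k_test(rvonmises(100, 0, 0.5),
                                    rvonmises(100, 0, 0.5))$regime, "low")
  expect_equal(concentration_k_test(rvonmises(100, 0, 4),
                                    rvonmises(100, 0, 4))$regime, "high")

  # kappa 4 vs 0.5 detected at the ** alpha in nearly all runs
  det <- replicate(40, concentration_k_test(rvonmises(120, 0, 4),
                                            rvonmises(120, 0, 0.5))$p < 0.003)
  expect_gte(mean(det), 0.95)
})

test_that("sequential comparison gates on Kuiper and stars on the ladder", {
  set.seed(51)
  g <- list(control = rvonmises(150, pi, 4),
            epi3wk = rvonmises(150, pi, 1),
            epi8wk = rvonmises(150, pi, 4))
  res <- sequential_circular_comparison(g)
  r_c3 <- res[res$group_a == "control" & res$group_b == "epi3wk", ]
  expect_true(r_c3$gated)
  expect_gte(r_c3$stars, 1)
  # identical-kappa pair: concentration stars require passing the gate first
  r_c8 <- res[res$group_a == "control" & res$group_b == "epi8wk", ]
  expect_true(!r_c8$gated || r_c8$k_p > 0.017)

  # star ladder boundary is strict
  fake <- res[1, ]
  expect_equal(sum(0.0169 < c(0.017, 0.003, 0.0003)), 1)
  expect_equal(sum(0.0171 < c(0.017, 0.003, 0.0003)), 0)
})

test_that("three identical groups rarely pass the Kuiper gate", {
  set.seed(61)
  gates <- replicate(60, {
    g <- list(a = rvonmises(80, 2, 2), b = rvonmises(80, 2, 2),
              c = rvonmises(80, 2, 2))
    any(sequential_circular_comparison(g)$gated)
  })
  # 3 pairwise gates at alpha 0.017: expected family rate ~5%
  expect_lt(mean(gates), 0.2)
})
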