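# Self-contained circular statistics for spike-theta phase analyses.
# All angles are radians; inputs are wrapped to [0, 2*pi) internally.

#' Circular mean direction and resultant length
#'
#' The first trigonometric moment: `R = |sum(exp(i*theta))| / n`, `mu` its
#' argument. For a von Mises sample with concentration kappa, `r` estimates
#' `I1(kappa)/I0(kappa)`.
#'
#' @param phases Numeric vector of angles (radians).
#' @return A list with `mu` (in `[0, 2*pi)`, `NA` when `r == 0`), `r` in
#'   `[0, 1]`, and `n`.
#' @examples
#' circ_mean_r(rep(pi / 2, 10))
#' @export
circ_mean_r <- function(phases) {
  assert_that(length(phases) >= 1, "need at least one phase")
  z <- mean(exp(1i * wrap_2pi(phases)))
  r <- Mod(z)
  mu <- if (r < .Machine$double.eps^0.5) NA_real_ else wrap_2pi(Arg(z))
  list(mu = mu, r = r, n = length(phases))
}

#' Expected resultant length of a von Mises distribution
#'
#' `A(kappa) = I1(kappa)/I0(kappa)`, the population value that the sample
#' resultant length estimates.
#'
#' @param kappa Concentration parameter (>= 0).
#' @return Expected resultant length in `[0, 1)`.
#' @export
von_mises_r <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampling; reduces to the circular uniform at
#' `kappa = 0`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  assert_that(kappa >= 0, "kappa must be non-negative")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    m <- n - i
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    ns <- sum(ok)
    if (ns > 0) {
      out[(i + 1):(i + ns)] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      i <- i + ns
    }
  }
  wrap_2pi(out + mu)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform circular distribution against a unimodal
#' alternative via `Z = n * R^2`, with the standard small-sample corrected
#' p-value approximation.
#'
#' @param phases Numeric vector of angles (radians), `n >= 5`.
#' @return A list with `p`, `z` and `n`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  assert_that(n >= 5, "Rayleigh test requires n >= 5")
  R <- circ_mean_r(phases)$r
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(p = min(max(p, .Machine$double.xmin), 1), z = z, n = n)
}

kuiper_stat <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  o <- order(c(x1, x2))
  d <- cumsum(c(rep(1 / n1, n1), rep(-1 / n2, n2))[o])
  max(d, 0) - min(d, 0)
}

kuiper_p_asym <- function(V, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  j <- 1:100
  p <- 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  min(max(p, 0), 1)
}

#' Two-sample Kuiper test
#'
#' Rotation-invariant circular analogue of the two-sample Kolmogorov-Smirnov
#' test: `V = max(F1 - F2) + max(F2 - F1)` over the circle. The p-value uses
#' the asymptotic Kuiper series at effective sample size
#' `n1 * n2 / (n1 + n2)`; below `min(n1, n2) < 50` a seeded permutation
#' p-value (`n_perm` shuffles) is used instead.
#'
#' @param x1,x2 Angle vectors (radians), each of length >= 8.
#' @param n_perm Number of permutations for the small-sample fallback.
#' @param perm_threshold Per-sample size below which the permutation p-value
#'   is used.
#' @param seed Seed for the permutation fallback.
#' @return A list with `V`, `p`, `method` ("asymptotic" or "permutation").
#' @export
kuiper_two_sample <- function(x1, x2, n_perm = 2000, perm_threshold = 50,
                              seed = 1L) {
  n1 <- length(x1); n2 <- length(x2)
  assert_that(n1 >= 8 && n2 >= 8, "Kuiper test requires n >= 8 per sample")
  x1 <- wrap_2pi(x1); x2 <- wrap_2pi(x2)
  V <- kuiper_stat(x1, x2)
  if (min(n1, n2) < perm_threshold) {
    pool <- c(x1, x2)
    cnt <- with_seed(derive_seed(seed, "kuiper-perm", n1, n2), {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        s <- sample.int(n1 + n2)
        if (kuiper_stat(pool[s[1:n1]], pool[s[-(1:n1)]]) >= V - 1e-12) {
          hits <- hits + 1L
        }
      }
      hits
    })
    list(V = V, p = (cnt + 1) / (n_perm + 1), method = "permutation")
  } else {
    list(V = V, p = kuiper_p_asym(V, n1, n2), method = "asymptotic")
  }
}

#' Test for equality of circular concentration parameters
#'
#' Fisher's two-sample test of a common von Mises concentration, with the
#' standard regime-dependent forms: variance-stabilized angular transforms for
#' mean resultant length below 0.45 and between 0.45 and 0.70, and a
#' two-tailed variance-ratio F test (on `n - R`) above 0.70.
#'
#' @param x1,x2 Angle vectors (radians).
#' @return A list with `p`, `statistic`, `regime` ("low", "mid", "high"),
#'   `rbar` (pooled mean resultant length) and `low_power` flag set when both
#'   samples are nearly uniform.
#' @export
concentration_k_test <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  assert_that(n1 >= 5 && n2 >= 5, "concentration test requires n >= 5 per sample")
  r1 <- circ_mean_r(x1)$r; r2 <- circ_mean_r(x2)$r
  rbar <- (n1 * r1 + n2 * r2) / (n1 + n2)
  low_power <- r1 < 0.05 && r2 < 0.05
  if (rbar < 0.45) {
    g <- function(r) 2 * asin(pmin(r * sqrt(3 / 8), 1))
    w1 <- 4 * (n1 - 4) / 3; w2 <- 4 * (n2 - 4) / 3
    stat <- (g(r1) - g(r2))^2 / (1 / w1 + 1 / w2)
    p <- 1 - pchisq(stat, 1)
    regime <- "low"
  } else if (rbar <= 0.70) {
    g <- function(r) asinh((r - 1.089) / 0.258)
    w1 <- (n1 - 3) / 0.798; w2 <- (n2 - 3) / 0.798
    stat <- (g(r1) - g(r2))^2 / (1 / w1 + 1 / w2)
    p <- 1 - pchisq(stat, 1)
    regime <- "mid"
  } else {
    R1 <- n1 * r1; R2 <- n2 * r2
    stat <- ((n2 - 1) * (n1 - R1)) / ((n1 - 1) * (n2 - R2))
    p <- if (stat > 1) 2 * (1 - pf(stat, n1 - 1, n2 - 1)) else 2 * pf(stat, n1 - 1, n2 - 1)
    regime <- "high"
  }
  list(p = min(p, 1), statistic = stat, regime = regime, rbar = rbar,
       low_power = low_power)
}

#' Sequential circular comparison across groups
#'
#' For every pair of groups, a two-sample Kuiper test gates the comparison:
#' only pairs whose distributions differ at the first alpha are additionally
#' tested for equality of concentration, and star levels are assigned from the
#' concentration test p-value against the alpha ladder (default
#' 0.017 / 0.003 / 0.0003, the multiple-comparison-corrected levels for three
#' groups).
#'
#' @param groups Named list of angle vectors (radians).
#' @param alphas Decreasing alpha ladder; `alphas[1]` is also the Kuiper gate.
#' @param seed Seed forwarded to the Kuiper permutation fallback.
#' @return A tibble with one row per group pair: `group_a`, `group_b`,
#'   `kuiper_V`, `kuiper_p`, `gated`, `k_p`, `stars`.
#' @export
sequential_circular_comparison <- function(groups,
                                           alphas = c(0.017, 0.003, 0.0003),
                                           seed = 1L) {
  assert_that(length(groups) >= 2, "need at least two groups")
  assert_that(all(diff(alphas) < 0), "alphas must be strictly decreasing")
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    kt <- kuiper_two_sample(groups[[a]], groups[[b]],
                            seed = derive_seed(seed, a, b))
    gated <- kt$p < alphas[1]
    if (gated) {
      kk <- concentration_k_test(groups[[a]], groups[[b]])
      stars <- sum(kk$p < alphas)
      kp <- kk$p
    } else {
      stars <- 0L; kp <- NA_real_
    }
    tibble(group_a = a, group_b = b, kuiper_V = kt$V, kuiper_p = kt$p,
           gated = gated, k_p = kp, stars = as.integer(stars))
  })
}
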