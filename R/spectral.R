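# Multitaper theta power and coherence. Windows of 2 s are cut from the
# analysis epochs and tapered with K = 5 Slepian (DPSS) tapers at
# time-bandwidth NW = 3 (Chronux-comparable resolution for a 5-12 Hz band);
# the band summary is the mean of magnitude coherence (or PSD) over 5-12 Hz.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal formulation; for long windows the
#' tapers are computed at a reduced length and spline-interpolated, then
#' re-orthonormalized (the approach used by standard multitaper toolboxes).
#' Results are cached per `(n, nw, k)`.
#'
#' @param n Window length in samples.
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @return An `n x k` matrix with orthonormal columns.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  base_n <- 384L
  exact <- function(nn) {
    w <- nw / nn
    i <- 0:(nn - 1)
    d <- ((nn - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
    e <- (1:(nn - 1)) * (nn - (1:(nn - 1))) / 2
    A <- matrix(0, nn, nn)
    diag(A) <- d
    A[cbind(1:(nn - 1), 2:nn)] <- e
    A[cbind(2:nn, 1:(nn - 1))] <- e
    v <- eigen(A, symmetric = TRUE)$vectors[, 1:k, drop = FALSE]
    for (j in 1:k) {       # sign convention: leading lobe positive
      if (j %% 2 == 1 && sum(v[, j]) < 0) v[, j] <- -v[, j]
      if (j %% 2 == 0 && (v[2, j] - v[1, j]) < 0) v[, j] <- -v[, j]
    }
    v
  }
  if (n <= base_n) {
    v <- exact(n)
  } else {
    vb <- exact(base_n)
    xb <- seq(0, 1, length.out = base_n)
    xn <- seq(0, 1, length.out = n)
    v <- apply(vb, 2, function(col) spline(xb, col, xout = xn)$y)
    v <- qr.Q(qr(v)) * sign(sum(v[, 1]))   # re-orthonormalize
    for (j in 1:k) {
      if (j %% 2 == 1 && sum(v[, j]) < 0) v[, j] <- -v[, j]
      if (j %% 2 == 0 && (v[2, j] - v[1, j]) < 0) v[, j] <- -v[, j]
    }
  }
  .dpss_cache[[key]] <- v
  v
}

# indices of full analysis windows cut from epochs
epoch_windows <- function(epochs_tbl, fs, n_samples, win_s) {
  nwin_samp <- round(win_s * fs)
  starts <- integer(0)
  ep <- epochs_normalize(epochs_tbl)
  for (i in seq_len(nrow(ep))) {
    i0 <- floor(ep$start[i] * fs) + 1
    i1 <- min(floor(ep$end[i] * fs), n_samples)
    k <- floor((i1 - i0 + 1) / nwin_samp)
    if (k > 0) starts <- c(starts, i0 + (0:(k - 1)) * nwin_samp)
  }
  list(starts = starts, n = nwin_samp)
}

# multitaper auto/cross spectra accumulated over windows; restricted to the
# frequency bins inside `band` when given (all auto/cross products are only
# needed there)
mt_spectra <- function(x, y, fs, starts, nwin, nw, k, band = NULL) {
  tap <- dpss_tapers(nwin, nw, k)
  freq <- (0:(nwin - 1)) * fs / nwin
  sel <- if (is.null(band)) seq_along(freq) else
    which(freq >= band[1] & freq <= band[2])
  nb <- length(sel)
  Sxx <- Syy <- numeric(nb)
  Sxy <- complex(nb)
  for (s in starts) {
    xi <- x[s:(s + nwin - 1)]
    yi <- if (!is.null(y)) y[s:(s + nwin - 1)] else NULL
    for (j in seq_len(k)) {
      X <- fft(xi * tap[, j])[sel]
      Sxx <- Sxx + Mod(X)^2
      if (!is.null(yi)) {
        Y <- fft(yi * tap[, j])[sel]
        Syy <- Syy + Mod(Y)^2
        Sxy <- Sxy + X * Conj(Y)
      }
    }
  }
  m <- length(starts) * k
  list(freq = freq[sel], Sxx = Sxx / m, Syy = Syy / m, Sxy = Sxy / m, m = m)
}

#' Theta-band multitaper power of one channel
#'
#' Mean multitaper power spectral density over the theta band, restricted to
#' the analysis epochs.
#'
#' @param x Numeric signal vector (microvolts).
#' @param fs Sampling rate, Hz.
#' @param epochs_tbl Epoch tibble; at least 2 s of coverage required.
#' @param band Frequency band, Hz.
#' @param win_s Window length, seconds.
#' @param nw,k Multitaper parameters.
#' @return Band-mean power (microvolts^2 per Hz scale of the raw periodogram).
#' @export
theta_power <- function(x, fs, epochs_tbl, band = c(5, 12), win_s = 2,
                        nw = 3, k = 5) {
  wins <- epoch_windows(epochs_tbl, fs, length(x), win_s)
  assert_that(length(wins$starts) >= 1,
              "insufficient epoch time: need at least one full analysis window")
  sp <- mt_spectra(x, NULL, fs, wins$starts, wins$n, nw, k, band = band)
  mean(sp$Sxx) / fs
}

#' Theta-band multitaper coherence between two channels
#'
#' Magnitude of the multitaper coherency averaged over the theta band, using
#' only windows cut from the analysis epochs. Invariant to per-channel
#' scaling; equals 1 for identical signals.
#'
#' @param x,y Numeric signal vectors of equal length.
#' @param fs Sampling rate, Hz.
#' @param epochs_tbl Epoch tibble.
#' @param band Frequency band, Hz.
#' @param win_s Window length, seconds.
#' @param nw,k Multitaper parameters.
#' @return Coherence in `[0, 1]`.
#' @export
theta_coherence <- function(x, y, fs, epochs_tbl, band = c(5, 12), win_s = 2,
                            nw = 3, k = 5) {
  assert_that(length(x) == length(y), "signals must have equal length")
  wins <- epoch_windows(epochs_tbl, fs, length(x), win_s)
  assert_that(length(wins$starts) >= 1,
              "insufficient epoch time: need at least one full analysis window")
  sp <- mt_spectra(x, y, fs, wins$starts, wins$n, nw, k, band = band)
  C <- Mod(sp$Sxy) / sqrt(sp$Sxx * sp$Syy)
  mean(pmin(C, 1))
}

# contiguous channel block of one layer; representative = middle (default)
layer_channels <- function(cm, layer) {
  idx <- cm$channel[cm$layer == layer]
  sort(idx)
}

#' Representative channel of a layer
#'
#' @param cm Channel-map tibble.
#' @param layer Layer label.
#' @param which "middle" (default) or "top" (shallowest).
#' @return 0-based channel index.
#' @export
representative_channel <- function(cm, layer, which = "middle") {
  idx <- layer_channels(cm, layer)
  assert_that(length(idx) > 0,
              sprintf("layer '%s' absent; available: %s", layer,
                      toString(unique(cm$layer))))
  if (which == "top") idx[1] else idx[ceiling(length(idx) / 2)]
}

#' Per-animal uniform sub-region coherence matrix
#'
#' One theta-coherence value per ordered layer pair, on the canonical layer
#' grid, using each layer's representative channel. Layers absent from the
#' session are reported as `NA` (missing, not zero).
#'
#' @param session An `lfp_session`.
#' @param epochs_tbl Analysis epoch tibble.
#' @param band Frequency band, Hz.
#' @param aggregate "middle" representative channel (default) or "mean" over
#'   member channels.
#' @param ... Passed to [theta_coherence()].
#' @return A `coherence_matrix` object: symmetric matrix with unit diagonal,
#'   layer-labelled dimnames, and `animal_id` / `group` attributes.
#' @export
subregion_matrix <- function(session, epochs_tbl, band = c(5, 12),
                             aggregate = c("middle", "mean"), ...) {
  aggregate <- match.arg(aggregate)
  cm <- session$channel_map
  present <- LAYER_ORDER[LAYER_ORDER %in% cm$layer]
  assert_that(length(present) >= 2, "need at least two labelled layers")
  vals <- matrix(NA_real_, length(LAYER_ORDER), length(LAYER_ORDER),
                 dimnames = list(LAYER_ORDER, LAYER_ORDER))
  pair_coh <- function(la, lb) {
    if (aggregate == "middle") {
      ca <- representative_channel(cm, la); cb <- representative_channel(cm, lb)
      theta_coherence(session$samples[ca + 1, ], session$samples[cb + 1, ],
                      session$fs, epochs_tbl, band = band, ...)
    } else {
      cas <- layer_channels(cm, la); cbs <- layer_channels(cm, lb)
      mean(purrr::map_dbl(cas, function(ca) {
        mean(purrr::map_dbl(cbs, function(cb) {
          theta_coherence(session$samples[ca + 1, ], session$samples[cb + 1, ],
                          session$fs, epochs_tbl, band = band, ...)
        }))
      }))
    }
  }
  for (a in seq_along(present)) {
    vals[present[a], present[a]] <- 1
    if (a < length(present)) {
      for (b in (a + 1):length(present)) {
        v <- pair_coh(present[a], present[b])
        vals[present[a], present[b]] <- v
        vals[present[b], present[a]] <- v
      }
    }
  }
  structure(vals, class = c("coherence_matrix", "matrix"),
            animal_id = session$animal_id, group = session$group)
}

#' @export
print.coherence_matrix <- function(x, ...) {
  cat(sprintf("<coherence_matrix> animal %s (%s)\n",
              attr(x, "animal_id"), attr(x, "group")))
  keep <- !apply(is.na(unclass(x)), 1, all)
  print(round(unclass(x)[keep, keep], 3))
  invisible(x)
}

#' Tidy a coherence matrix into long format
#' @param x A `coherence_matrix`.
#' @param ... Unused.
#' @return A tibble: `animal_id`, `group`, `layer_a`, `layer_b`, `coherence`
#'   (upper triangle, present layers only).
#' @export
tidy.coherence_matrix <- function(x, ...) {
  m <- unclass(x)
  present <- rownames(m)[!apply(is.na(m), 1, all)]
  out <- purrr::map_dfr(seq_along(present), function(a) {
    if (a >= length(present)) return(NULL)
    purrr::map_dfr((a + 1):length(present), function(b) {
      tibble(layer_a = present[a], layer_b = present[b],
             coherence = m[present[a], present[b]])
    })
  })
  dplyr::mutate(out, animal_id = attr(x, "animal_id"),
                group = attr(x, "group"), .before = 1)
}

#' Cross-group Welch p-value matrix for layer-pair coherence
#'
#' Welch's two-sample t-test per layer pair on per-animal coherence values.
#' Cells significant at `alpha` are signed: "decrease" when the second group's
#' mean is lower, "increase" when higher; cells with fewer than two animals in
#' either group are "n.s." with a missing-data flag.
#'
#' @param matrices_a,matrices_b Lists of `coherence_matrix` objects (one per
#'   animal) for the reference and comparison groups.
#' @param alpha Significance threshold (0.05, or 0.017 when correcting across
#'   three groups).
#' @return A `group_comparison` tibble: `layer_a`, `layer_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `p`, `sign`, `missing`.
#' @export
group_pvalue_matrix <- function(matrices_a, matrices_b, alpha = 0.017) {
  pull_cell <- function(ms, la, lb) {
    v <- purrr::map_dbl(ms, function(m) unclass(m)[la, lb])
    v[!is.na(v)]
  }
  layers_used <- LAYER_ORDER[purrr::map_lgl(LAYER_ORDER, function(l) {
    any(purrr::map_lgl(c(matrices_a, matrices_b),
                       function(m) !all(is.na(unclass(m)[l, ]))))
  })]
  out <- purrr::map_dfr(seq_along(layers_used), function(a) {
    if (a >= length(layers_used)) return(NULL)
    purrr::map_dfr((a + 1):length(layers_used), function(b) {
      la <- layers_used[a]; lb <- layers_used[b]
      va <- pull_cell(matrices_a, la, lb)
      vb <- pull_cell(matrices_b, la, lb)
      if (length(va) < 2 || length(vb) < 2) {
        return(tibble(layer_a = la, layer_b = lb, n_a = length(va),
                      n_b = length(vb), mean_a = mean(va), mean_b = mean(vb),
                      p = NA_real_, sign = "n.s.", missing = TRUE))
      }
      p <- tryCatch(t.test(va, vb, var.equal = FALSE)$p.value,
                    error = function(e) NA_real_)
      sgn <- if (!is.na(p) && p < alpha) {
        if (mean(vb) < mean(va)) "decrease" else "increase"
      } else "n.s."
      tibble(layer_a = la, layer_b = lb, n_a = length(va), n_b = length(vb),
             mean_a = mean(va), mean_b = mean(vb), p = p, sign = sgn,
             missing = FALSE)
    })
  })
  structure(out, class = c("group_comparison", class(out)), alpha = alpha)
}

#' Correlate an LFP metric with seizure burden across animals
#'
#' Pearson correlation (two-tailed) of a per-animal metric against seizure
#' frequency or recency.
#'
#' @param values Per-animal metric values (length >= 3).
#' @param covariate Per-animal seizure frequency or recency.
#' @return A tibble with `r`, `p`, `n`; `r`/`p` are `NA` with a note when a
#'   variable has zero variance.
#' @export
metric_vs_seizure_correlation <- function(values, covariate) {
  assert_that(length(values) == length(covariate), "lengths must match")
  assert_that(length(values) >= 3, "need at least 3 animals")
  if (sd(values) == 0 || sd(covariate) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = length(values),
                  note = "zero variance: correlation undefined"))
  }
  ct <- cor.test(values, covariate, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(values),
         note = NA_character_)
}
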