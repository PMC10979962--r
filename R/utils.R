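# internal helpers shared across modules

#' Derive a reproducible child seed
#'
#' Deterministically mixes a master seed with string/integer context labels so
#' each animal, channel, or unit receives an independent, reproducible stream.
#' Result is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Character or integer context labels.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    for (cp in utf8ToInt(p)) {
      h <- (h * 31 + cp) %% 2147483647
    }
  }
  as.integer(h)
}

#' Wrap angles to the canonical circular domain
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to `[0, 2*pi)`.
#' @export
wrap_2pi <- function(x) {
  y <- x %% (2 * pi)
  y[which(y < 0)] <- y[which(y < 0)] + 2 * pi
  # `%%` can return 2*pi for tiny negative inputs via rounding
  y[which(y >= 2 * pi)] <- 0
  y
}

#' Convert radians to degrees on [0, 360)
#' @param x Angles in radians.
#' @return Angles in degrees wrapped to `[0, 360)`.
#' @export
rad2deg <- function(x) wrap_2pi(x) * 180 / pi

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
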