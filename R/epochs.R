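# Interval ("epoch") algebra over half-open [start, end) windows in seconds.
# All epoch sets are tibbles with numeric `start`/`end` columns; every public
# operation normalizes its result (sorted, non-overlapping, start < end).

#' Construct an epoch set
#'
#' An epoch set is a tibble of half-open `[start, end)` intervals in seconds.
#'
#' @param start,end Numeric vectors of equal length; `start < end` pairwise.
#' @param label Optional label attached as an attribute.
#' @return A normalized epoch tibble with columns `start`, `end`.
#' @examples
#' epochs(c(0, 5), c(3, 9))
#' @export
epochs <- function(start = numeric(), end = numeric(), label = NULL) {
  assert_that(length(start) == length(end), "start and end must have equal length")
  assert_that(all(start < end), "every epoch must satisfy start < end")
  out <- epochs_normalize(tibble(start = as.double(start), end = as.double(end)))
  attr(out, "label") <- label
  out
}

#' Normalize an epoch set
#'
#' Sorts intervals and merges overlapping or touching intervals. Idempotent and
#' duration-preserving on already-disjoint input.
#'
#' @param ep Epoch tibble with `start`, `end` columns.
#' @return Normalized epoch tibble.
#' @export
epochs_normalize <- function(ep) {
  if (nrow(ep) == 0) return(tibble(start = double(), end = double()))
  assert_that(all(ep$end > ep$start), "every epoch must satisfy start < end")
  o <- order(ep$start, ep$end)
  s <- ep$start[o]; e <- ep$end[o]
  ks <- numeric(0); ke <- numeric(0)
  cs <- s[1]; ce <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= ce) {
        ce <- max(ce, e[i])
      } else {
        ks <- c(ks, cs); ke <- c(ke, ce)
        cs <- s[i]; ce <- e[i]
      }
    }
  }
  tibble(start = c(ks, cs), end = c(ke, ce))
}

#' Total covered duration of an epoch set
#' @param ep Epoch tibble.
#' @return Total seconds covered (overlaps counted once).
#' @export
epochs_duration <- function(ep) {
  ep <- epochs_normalize(ep)
  sum(ep$end - ep$start)
}

#' Union of two epoch sets
#' @param a,b Epoch tibbles.
#' @return Normalized union.
#' @export
epochs_union <- function(a, b) {
  epochs_normalize(tibble(start = c(a$start, b$start), end = c(a$end, b$end)))
}

#' Intersection of two epoch sets
#' @param a,b Epoch tibbles.
#' @return Normalized intersection.
#' @export
epochs_intersect <- function(a, b) {
  a <- epochs_normalize(a); b <- epochs_normalize(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(epochs())
  s <- numeric(0); e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    keep <- lo < hi
    s <- c(s, lo[keep]); e <- c(e, hi[keep])
  }
  if (length(s) == 0) return(epochs())
  epochs_normalize(tibble(start = s, end = e))
}

#' Set difference of two epoch sets
#'
#' Removes every part of `a` covered by `b`.
#'
#' @param a,b Epoch tibbles.
#' @return Normalized `a \\ b`.
#' @export
epochs_setdiff <- function(a, b) {
  a <- epochs_normalize(a); b <- epochs_normalize(b)
  if (nrow(a) == 0) return(epochs())
  if (nrow(b) == 0) return(a)
  s <- numeric(0); e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    cs <- a$start[i]; ce <- a$end[i]
    cut <- b[b$end > cs & b$start < ce, , drop = FALSE]
    pos <- cs
    if (nrow(cut) > 0) {
      for (j in seq_len(nrow(cut))) {
        if (cut$start[j] > pos) { s <- c(s, pos); e <- c(e, cut$start[j]) }
        pos <- max(pos, cut$end[j])
      }
    }
    if (pos < ce) { s <- c(s, pos); e <- c(e, ce) }
  }
  if (length(s) == 0) return(epochs())
  epochs_normalize(tibble(start = s, end = e))
}

#' Keep only epochs at least a minimum duration
#' @param ep Epoch tibble.
#' @param min_dur Minimum duration in seconds (strictly greater-than).
#' @return Filtered epoch tibble.
#' @export
epochs_filter_min <- function(ep, min_dur) {
  ep <- epochs_normalize(ep)
  ep[ep$end - ep$start > min_dur, , drop = FALSE]
}

# membership of time points in an epoch set
in_epochs <- function(t, ep) {
  ep <- epochs_normalize(ep)
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ep))) {
    out <- out | (t >= ep$start[i] & t < ep$end[i])
  }
  out
}
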