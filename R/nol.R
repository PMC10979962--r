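# Novel object location (NOL) scoring: discrimination index, training
# exclusion rules, and the group-level preference test.

#' NOL interaction events
#'
#' @param object Character vector, "moved" or "unmoved" per event.
#' @param start_s,end_s Event times in seconds (`end > start`).
#' @return A tibble of interaction events.
#' @export
nol_events <- function(object, start_s, end_s) {
  assert_that(all(object %in% c("moved", "unmoved")),
              "object must be 'moved' or 'unmoved'")
  assert_that(all(end_s > start_s), "every event needs end > start")
  tibble(object = object, start_s = start_s, end_s = end_s)
}

nol_times <- function(events) {
  dplyr::summarise(dplyr::group_by(events, .data$object),
                   t = sum(.data$end_s - .data$start_s), .groups = "drop")
}

#' Discrimination index
#'
#' `DI = 100 * (T_moved - T_unmoved) / (T_moved + T_unmoved)`: positive when
#' the animal preferentially investigates the moved object.
#'
#' @param events Event tibble from [nol_events()].
#' @return A list with `di` in `[-100, 100]`, `t_moved`, `t_unmoved`;
#'   `di = NA` with a flag when the total interaction time is zero.
#' @export
discrimination_index <- function(events) {
  tt <- nol_times(events)
  tm <- sum(tt$t[tt$object == "moved"])
  tu <- sum(tt$t[tt$object == "unmoved"])
  if (tm + tu <= 0) {
    return(list(di = NA_real_, t_moved = tm, t_unmoved = tu,
                undefined = TRUE))
  }
  list(di = 100 * (tm - tu) / (tm + tu), t_moved = tm, t_unmoved = tu,
       undefined = FALSE)
}

#' Training-session exclusion rule
#'
#' Excludes an animal when its training DI exceeds 30 (strict), or when it
#' explored either object for less than 3 s during training. Training
#' exposures are pooled before scoring.
#'
#' @param training_events Pooled training event tibble.
#' @param di_max Training DI bound (strict inequality).
#' @param min_time_s Per-object minimum exploration, seconds.
#' @return A list with `include` and `reason` (`NA` when included).
#' @export
apply_exclusions <- function(training_events, di_max = 30, min_time_s = 3) {
  sc <- discrimination_index(training_events)
  if (isTRUE(sc$undefined)) {
    return(list(include = FALSE, reason = "no interaction time in training"))
  }
  if (sc$di > di_max) {
    return(list(include = FALSE,
                reason = sprintf("training DI %.1f > %g", sc$di, di_max)))
  }
  if (min(sc$t_moved, sc$t_unmoved) < min_time_s) {
    return(list(include = FALSE,
                reason = sprintf("object explored < %g s in training", min_time_s)))
  }
  list(include = TRUE, reason = NA_character_)
}

#' Group preference test on test-session DIs
#'
#' Two-tailed one-sample t-test of the group's DIs against 0 (no preference).
#'
#' @param dis Numeric vector of per-animal test DIs (>= 3 animals).
#' @return A tibble with `mean`, `sem`, `p`, `n`; `p` is `NA` with a note
#'   when the DIs have zero variance.
#' @export
group_preference_test <- function(dis) {
  assert_that(length(dis) >= 3, "need at least 3 animals")
  if (sd(dis) == 0) {
    return(tibble(mean = mean(dis), sem = 0, p = NA_real_, n = length(dis),
                  note = "zero variance: t-test undefined"))
  }
  tt <- t.test(dis, mu = 0)
  tibble(mean = mean(dis), sem = sd(dis) / sqrt(length(dis)),
         p = tt$p.value, n = length(dis), note = NA_character_)
}

#' Read NOL events from a Chronotate-style CSV
#'
#' Expects columns naming the object and press-in / press-out times; column
#' names are matched case-insensitively to (`object`, `start`/`press_in`,
#' `end`/`press_out`).
#'
#' @param path CSV file path.
#' @return An event tibble as from [nol_events()].
#' @export
read_nol_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(df))
  pick <- function(alts) {
    i <- which(nm %in% alts)[1]
    assert_that(!is.na(i), sprintf("no column matching: %s", toString(alts)))
    df[[i]]
  }
  nol_events(object = tolower(pick(c("object", "label"))),
             start_s = as.numeric(pick(c("start", "start_s", "press_in", "in"))),
             end_s = as.numeric(pick(c("end", "end_s", "press_out", "out"))))
}
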