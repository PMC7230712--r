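# Shift classification, main-sleep resolution and wake-to-wake day windows.
#
# A "day window" runs from the wake time of the main sleep preceding a
# shift/rest day until the wake time of the following main sleep; its day
# type (rest/morning/evening/night) comes from the work period it encloses.

SHIFT_CLASSES <- c("morning", "evening", "night", "excluded", "unclassified")
DAY_TYPES <- c("rest", "morning", "evening", "night")

#' Classify a work period into a shift type
#'
#' Duration bounds are applied first: shifts longer than `max_h` (default
#' 13.5 h) or shorter than `min_h` (default 4.5 h) are `"excluded"`.
#' Otherwise, a shift is `"night"` if the work interval contains the entire
#' 0100-0500 h span, else `"evening"` if work ends between 2200 h and
#' 0200 h, else `"morning"` if work starts between 0500 h and 0900 h, else
#' `"unclassified"`. Precedence night > evening > morning makes overlapping
#' rules deterministic.
#'
#' @param start,end POSIXct work start/end (vectorized).
#' @param min_h,max_h duration exclusion bounds in hours.
#' @return character vector of shift classes.
#' @examples
#' d <- as.POSIXct("2024-01-01", tz = "UTC")
#' classify_shift(d + 7 * 3600, d + 16 * 3600)    # morning
#' classify_shift(d + 22.5 * 3600, d + 31.5 * 3600) # night
#' @export
classify_shift <- function(start, end, min_h = 4.5, max_h = 13.5) {
  start <- parse_timestamp(start); end <- parse_timestamp(end)
  dur <- hours_between(start, end)
  if (any(dur <= 0)) stop("shift end must be after start")
  if (any(dur >= 48)) stop("shift duration must be < 48 h")
  n <- length(start)
  out <- rep("unclassified", n)
  start_clock <- clock_hours(start)
  end_clock <- clock_hours(end)
  # night: interval contains the whole 0100-0500 span. The span containing
  # 0100 on some calendar day must start at/before 0100 and end at/after
  # 0500 of that day.
  covers_night_core <- vapply(seq_len(n), function(i) {
    d0 <- calendar_date(start[i])
    for (add in 0:2) {
      a <- at_clock(d0 + add, 1)
      b <- at_clock(d0 + add, 5)
      if (start[i] <= a && end[i] >= b) return(TRUE)
      if (a > end[i]) break
    }
    FALSE
  }, logical(1))
  is_evening <- end_clock >= 22 | end_clock <= 2
  is_morning <- start_clock >= 5 & start_clock <= 9
  out[is_morning] <- "morning"
  out[is_evening] <- "evening"
  out[covers_night_core] <- "night"
  out[dur > max_h | dur < min_h] <- "excluded"
  out
}

#' Resolve main sleep vs naps
#'
#' Within each calendar day (attributed by the wake date by default; see
#' Details) the longest sleep episode is flagged as the main sleep and all
#' others as naps; ties are broken in favour of the earlier onset.
#'
#' @details Attribution by wake (offset) date keeps exactly one main sleep
#' per day on rotating rosters where a post-evening-shift sleep (onset
#' ~0100 h) and the next night's sleep (onset ~2300 h) would otherwise
#' share an onset date. `attribute = "onset"` restores onset-date grouping.
#'
#' @param episodes data.frame with `subject_id`, `onset`, `wake` (POSIXct).
#' @param attribute `"wake"` (default) or `"onset"`.
#' @return `episodes` with a logical `is_main` column.
#' @export
resolve_main_sleep <- function(episodes, attribute = c("wake", "onset")) {
  attribute <- match.arg(attribute)
  episodes$onset <- parse_timestamp(episodes$onset)
  episodes$wake <- parse_timestamp(episodes$wake)
  if (any(episodes$wake <= episodes$onset)) stop("sleep wake must follow onset")
  check_no_overlap(episodes)
  key <- calendar_date(if (attribute == "wake") episodes$wake else episodes$onset)
  dur <- hours_between(episodes$onset, episodes$wake)
  episodes$is_main <- FALSE
  for (s in unique(episodes$subject_id)) {
    si <- which(episodes$subject_id == s)
    for (d in unique(key[si])) {
      di <- si[key[si] == d]
      best <- di[order(-dur[di], episodes$onset[di])][1]
      episodes$is_main[best] <- TRUE
    }
  }
  episodes
}

check_no_overlap <- function(episodes) {
  for (s in unique(episodes$subject_id)) {
    e <- episodes[episodes$subject_id == s, , drop = FALSE]
    e <- e[order(e$onset), , drop = FALSE]
    if (nrow(e) > 1 && any(e$onset[-1] < e$wake[-nrow(e)]))
      stop("overlapping sleep episodes for subject ", s)
  }
  invisible(TRUE)
}

#' Build wake-to-wake day windows
#'
#' For each subject, consecutive main-sleep wake times delimit analysis
#' days. Each window is labelled with the class of the shift starting
#' inside it (rest if none); windows containing an excluded or
#' unclassified shift, or with implausible length (outside
#' `(12, 36)` h), are dropped with a diagnostic attribute.
#'
#' @param shifts data.frame `subject_id`, `start`, `end` (POSIXct); a
#'   `shift_class` column is added if absent.
#' @param episodes sleep data.frame with `is_main` resolved (see
#'   [resolve_main_sleep()]).
#' @return data.frame of windows: `subject_id`, `date`, `day_type`,
#'   `window_start`, `window_end`, `day_length_h`, `sleep_h`,
#'   `work_start`, `work_end`; attribute `"dropped"` holds diagnostics.
#' @export
build_day_windows <- function(shifts, episodes) {
  episodes$onset <- parse_timestamp(episodes$onset)
  episodes$wake <- parse_timestamp(episodes$wake)
  if (is.null(episodes$is_main)) stop("resolve main sleep first")
  if (nrow(shifts) > 0) {
    shifts$start <- parse_timestamp(shifts$start)
    shifts$end <- parse_timestamp(shifts$end)
    if (is.null(shifts$shift_class))
      shifts$shift_class <- classify_shift(shifts$start, shifts$end)
  }
  rows <- list(); dropped <- list()
  for (s in unique(episodes$subject_id)) {
    mains <- episodes[episodes$subject_id == s & episodes$is_main, , drop = FALSE]
    mains <- mains[order(mains$wake), , drop = FALSE]
    if (nrow(mains) < 2) {
      dropped[[length(dropped) + 1]] <- data.frame(
        subject_id = s, date = NA, reason = "fewer than two main sleeps")
      next
    }
    subj_sleep <- episodes[episodes$subject_id == s, , drop = FALSE]
    subj_shift <- if (nrow(shifts)) shifts[shifts$subject_id == s, , drop = FALSE]
                  else shifts
    for (i in seq_len(nrow(mains) - 1)) {
      w_start <- mains$wake[i]
      w_end <- mains$wake[i + 1]
      len <- hours_between(w_start, w_end)
      date <- calendar_date(w_start)
      inside <- if (nrow(subj_shift))
        which(subj_shift$start >= w_start & subj_shift$start < w_end)
      else integer(0)
      if (len <= 12 || len >= 36) {
        dropped[[length(dropped) + 1]] <- data.frame(
          subject_id = s, date = date,
          reason = sprintf("day length %.1f h outside (12, 36)", len))
        next
      }
      if (length(inside) > 1) {
        dropped[[length(dropped) + 1]] <- data.frame(
          subject_id = s, date = date, reason = "multiple shifts in window")
        next
      }
      if (length(inside) == 1) {
        cls <- subj_shift$shift_class[inside]
        if (cls %in% c("excluded", "unclassified")) {
          dropped[[length(dropped) + 1]] <- data.frame(
            subject_id = s, date = date,
            reason = paste("shift", cls))
          next
        }
        day_type <- cls
        work_start <- subj_shift$start[inside]
        work_end <- subj_shift$end[inside]
      } else {
        day_type <- "rest"
        work_start <- as.POSIXct(NA)
        work_end <- as.POSIXct(NA)
      }
      sleep_h <- interval_overlap_hours(w_start, w_end,
                                        subj_sleep$onset, subj_sleep$wake)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, date = date, day_type = day_type,
        window_start = w_start, window_end = w_end,
        day_length_h = len, sleep_h = sleep_h,
        work_start = work_start, work_end = work_end)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), date = as.Date(character(0)),
               day_type = character(0),
               window_start = as.POSIXct(character(0), tz = "UTC"),
               window_end = as.POSIXct(character(0), tz = "UTC"),
               day_length_h = numeric(0), sleep_h = numeric(0),
               work_start = as.POSIXct(character(0), tz = "UTC"),
               work_end = as.POSIXct(character(0), tz = "UTC"))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  out
}

#' Fraction of the day window spent asleep
#'
#' @param windows data.frame from [build_day_windows()].
#' @return numeric vector `sleep_h / day_length_h` in `[0, 1]`.
#' @export
sleep_fraction <- function(windows) {
  frac <- windows$sleep_h / windows$day_length_h
  if (any(frac > 1 + 1e-9 | frac < 0)) stop("invalid sleep fraction")
  pmin(frac, 1)
}
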