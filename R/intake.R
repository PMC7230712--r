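# Intake events: merge photographic meal records into eating occasions
# (same meal type within 15 minutes, chained, timestamp of the last member)
# and assign events to day windows with nap-adjusted time awake.

MACRO_COLS <- c("carb_kcal", "sugar_kcal", "fat_kcal", "satfat_kcal",
                "protein_kcal", "alcohol_kcal")
MEAL_TYPES <- c("breakfast", "lunch", "dinner", "snack", "beverage_only")

validate_meal_records <- function(records) {
  need <- c("subject_id", "timestamp", "meal_type", "kcal", MACRO_COLS)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("meal log missing columns: ", paste(miss, collapse = ", "))
  records$timestamp <- parse_timestamp(records$timestamp)
  if (any(records$kcal < 0) || any(as.matrix(records[MACRO_COLS]) < 0))
    stop("negative kcal values in meal log")
  if (any(records$sugar_kcal > records$carb_kcal + 1e-6))
    stop("sugar kcal exceeds carbohydrate kcal")
  if (any(records$satfat_kcal > records$fat_kcal + 1e-6))
    stop("saturated-fat kcal exceeds fat kcal")
  records
}

#' Merge meal records into intake events
#'
#' Successive records of the same meal type logged by the same subject
#' within `gap_min` minutes of each other (default 15, chained pairwise in
#' time order) are combined into a single intake event carrying the
#' timestamp of the last member and the summed kcal and macronutrient kcal.
#' Records of different types never merge. Merging conserves total kcal and
#' every macronutrient exactly and is idempotent.
#'
#' @param records data.frame with `subject_id`, `timestamp`, `meal_type`,
#'   `kcal` and macro kcal columns (`carb_kcal`, `sugar_kcal`, `fat_kcal`,
#'   `satfat_kcal`, `protein_kcal`, `alcohol_kcal`).
#' @param gap_min merge threshold in minutes.
#' @return data.frame of intake events with an `n_merged` count.
#' @examples
#' d <- as.POSIXct("2024-01-01 10:00", tz = "UTC")
#' x <- data.frame(subject_id = "s1", timestamp = c(d, d + 600),
#'                 meal_type = "snack", kcal = c(100, 50),
#'                 carb_kcal = c(50, 25), sugar_kcal = c(10, 5),
#'                 fat_kcal = c(30, 15), satfat_kcal = c(10, 5),
#'                 protein_kcal = c(20, 10), alcohol_kcal = 0)
#' merge_intakes(x) # one event at 10:10 with 150 kcal
#' @export
merge_intakes <- function(records, gap_min = 15) {
  records <- validate_meal_records(records)
  records <- records[order(records$subject_id, records$meal_type,
                           records$timestamp), , drop = FALSE]
  n <- nrow(records)
  if (n == 0) {
    records$n_merged <- integer(0)
    return(records)
  }
  # within each (subject, type) series a new event starts where the gap to
  # the previous record exceeds the threshold; chained merging follows from
  # cumulative grouping. Records of other types in between do not break a
  # chain.
  gap_ok <- c(FALSE, diff(as.numeric(records$timestamp)) <= gap_min * 60 + 1e-9)
  same <- c(FALSE, records$subject_id[-1] == records$subject_id[-n] &
                   records$meal_type[-1] == records$meal_type[-n])
  grp <- cumsum(!(gap_ok & same))
  idx_last <- tapply(seq_len(n), grp, function(i) i[length(i)])
  out <- records[unlist(idx_last), , drop = FALSE]
  agg <- function(col) as.numeric(tapply(records[[col]], grp, sum))
  out$kcal <- agg("kcal")
  for (col in MACRO_COLS) out[[col]] <- agg(col)
  out$n_merged <- as.integer(tapply(rep(1L, n), grp, sum))
  out <- out[order(out$subject_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign intake events to day windows
#'
#' Each event is mapped to the (unique) day window containing its timestamp
#' (`window_start <= t < window_end`) for the same subject. Within a
#' window, `time_awake` is the elapsed time since window start minus any
#' intervening sleep (naps and, for events during a sleep episode, the
#' portion already slept). `clock_time_h` is the event clock time in hours.
#'
#' @param events intake events from [merge_intakes()].
#' @param windows day windows from [build_day_windows()].
#' @param episodes sleep episodes (for nap adjustment); main sleeps outside
#'   the window are ignored automatically.
#' @return events with `window_id`, `day_type`, `time_awake_h`,
#'   `clock_time_h`; unassigned events carry `NA` window ids.
#' @export
assign_to_window <- function(events, windows, episodes = NULL) {
  events$timestamp <- parse_timestamp(events$timestamp)
  if (nrow(windows) == 0) {
    events$window_id <- NA_integer_
    events$day_type <- NA_character_
    events$time_awake_h <- NA_real_
    events$clock_time_h <- clock_hours(events$timestamp)
    return(events)
  }
  windows$window_start <- parse_timestamp(windows$window_start)
  windows$window_end <- parse_timestamp(windows$window_end)
  if (!is.null(episodes)) {
    episodes$onset <- parse_timestamp(episodes$onset)
    episodes$wake <- parse_timestamp(episodes$wake)
  }
  check_windows_disjoint(windows)
  events$window_id <- NA_integer_
  events$day_type <- NA_character_
  events$time_awake_h <- NA_real_
  events$clock_time_h <- clock_hours(events$timestamp)
  for (i in seq_len(nrow(events))) {
    t <- events$timestamp[i]
    j <- which(windows$subject_id == events$subject_id[i] &
               windows$window_start <= t & t < windows$window_end)
    if (length(j) != 1) next
    events$window_id[i] <- j
    events$day_type[i] <- windows$day_type[j]
    elapsed <- hours_between(windows$window_start[j], t)
    slept <- 0
    if (!is.null(episodes)) {
      k <- episodes$subject_id == events$subject_id[i]
      slept <- interval_overlap_hours(windows$window_start[j], t,
                                      episodes$onset[k], episodes$wake[k])
    }
    events$time_awake_h[i] <- max(elapsed - slept, 0)
  }
  events
}

check_windows_disjoint <- function(windows) {
  for (s in unique(windows$subject_id)) {
    w <- windows[windows$subject_id == s, , drop = FALSE]
    w <- w[order(w$window_start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$window_start[-1] < w$window_end[-nrow(w)] - 1e-9))
      stop("overlapping day windows for subject ", s)
  }
  invisible(TRUE)
}

#' Filter events to caloric intakes
#'
#' Keeps events with strictly more than `min_kcal` (default 5) kcal. Used
#' only for timing metrics (first/last meal, eating window, circular
#' statistics); caloric totals always use all events.
#'
#' @param events intake events.
#' @param min_kcal strict lower bound in kcal.
#' @return filtered events.
#' @export
filter_caloric <- function(events, min_kcal = 5) {
  events[events$kcal > min_kcal, , drop = FALSE]
}
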