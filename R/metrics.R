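# Per-(subject, day-window) chrononutrition metrics: BMR standardization,
# timing latencies, eating window, weighted circular summaries, night/work
# caloric fractions, and binned caloric distributions.

#' Mifflin-St Jeor basal metabolic rate
#'
#' `10 * weight_kg + 6.25 * height_cm - 5 * age_years + 5` for males and
#' `- 161` for females, in kcal/day. `coefficients = "unrounded"` uses the
#' original regression coefficients (9.99, 6.25, 4.92, +5.4/-161.3).
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param age_years,height_cm,weight_kg positive numerics.
#' @param coefficients `"rounded"` (default) or `"unrounded"`.
#' @return kcal/day.
#' @examples
#' mifflin_st_jeor("male", 32, 180, 80)    # 1770
#' mifflin_st_jeor("female", 32, 165, 60)  # 1310.25
#' @export
mifflin_st_jeor <- function(sex, age_years, height_cm, weight_kg,
                            coefficients = c("rounded", "unrounded")) {
  coefficients <- match.arg(coefficients)
  if (any(is.na(age_years) | is.na(height_cm) | is.na(weight_kg)))
    stop("missing anthropometrics")
  if (any(age_years <= 0 | height_cm <= 0 | weight_kg <= 0))
    stop("anthropometrics must be positive")
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  k <- if (coefficients == "rounded") c(10, 6.25, 5, 5, -161)
       else c(9.99, 6.25, 4.92, 5.4, -161.3)
  bmr <- k[1] * weight_kg + k[2] * height_cm - k[3] * age_years +
    ifelse(sex == "male", k[4], k[5])
  if (any(bmr < 800 | bmr > 4000))
    warning("BMR outside the 800-4000 kcal plausibility band")
  bmr
}

#' Caloric intake as a percentage of day-length-weighted BMR
#'
#' `100 * total_kcal / (bmr_24h * day_length_h / 24)`: the 24-h BMR is
#' weighted by the wake-to-wake day length so long and short days are
#' comparable.
#'
#' @param total_kcal intake in kcal (>= 0).
#' @param bmr_24h 24-h basal metabolic rate in kcal.
#' @param day_length_h wake-to-wake day length in hours.
#' @return percent of BMR.
#' @examples
#' pct_bmr(3200, 1700, 24.6) # 183.6
#' @export
pct_bmr <- function(total_kcal, bmr_24h, day_length_h) {
  if (any(day_length_h <= 0)) stop("day length must be positive")
  if (any(bmr_24h <= 0)) stop("BMR must be positive")
  if (any(total_kcal < 0)) stop("kcal must be nonnegative")
  100 * total_kcal / (bmr_24h * day_length_h / 24)
}

#' Meal-timing latencies and eating window
#'
#' From the qualifying (>5 kcal) events of one day window: elapsed
#' (nap-adjusted) time awake at the first meal, interval from the last meal
#' to the following main-sleep onset, and the clock duration between first
#' and last meals (the eating window).
#'
#' @param events events of one window, already filtered with
#'   [filter_caloric()] and carrying `time_awake_h`.
#' @param next_sleep_onset POSIXct onset of the following main sleep (or
#'   `NA`).
#' @return list `first_meal_latency_h`, `last_meal_to_sleep_h`,
#'   `eating_window_h`; all `NA` when no qualifying events.
#' @export
eating_window <- function(events, next_sleep_onset = NA) {
  if (nrow(events) == 0)
    return(list(first_meal_latency_h = NA_real_,
                last_meal_to_sleep_h = NA_real_,
                eating_window_h = NA_real_))
  events <- events[order(events$timestamp), , drop = FALSE]
  first <- events[1, ]
  last <- events[nrow(events), ]
  list(
    first_meal_latency_h = first$time_awake_h,
    last_meal_to_sleep_h = if (is.na(next_sleep_onset)) NA_real_
      else hours_between(last$timestamp, next_sleep_onset),
    eating_window_h = hours_between(first$timestamp, last$timestamp))
}

#' Percent of calories consumed at night
#'
#' Fraction of total kcal whose event clock time falls in the half-open
#' night window (default 2300-0600 h). Days with intake but none at night
#' score an explicit 0.
#'
#' @param events intake events with `clock_time_h` and `kcal`.
#' @param night_start,night_end clock hours bounding the night window.
#' @return percent in `[0, 100]`; 0 when there are no events.
#' @export
fraction_at_night <- function(events, night_start = 23, night_end = 6) {
  if (nrow(events) == 0 || sum(events$kcal) <= 0) return(0)
  at_night <- clock_in_interval(events$clock_time_h, night_start, night_end)
  min(100 * sum(events$kcal[at_night]) / sum(events$kcal), 100)
}

#' Percent of calories consumed at work
#'
#' Fraction of total kcal with timestamps inside the closed work interval.
#' Undefined (`NA`) for rest days.
#'
#' @param events intake events with `timestamp`, `kcal`.
#' @param work_start,work_end POSIXct shift bounds (either `NA` for rest
#'   days).
#' @return percent in `[0, 100]`, or `NA` without a work interval.
#' @export
fraction_at_work <- function(events, work_start, work_end) {
  if (is.na(work_start) || is.na(work_end)) return(NA_real_)
  if (nrow(events) == 0 || sum(events$kcal) <= 0) return(0)
  at_work <- events$timestamp >= work_start & events$timestamp <= work_end
  min(100 * sum(events$kcal[at_work]) / sum(events$kcal), 100)
}

#' Caloric distribution over 4-h bins
#'
#' Percent of the day's total kcal per half-open 4-h bin, either by clock
#' time (six bins, 00-04 ... 20-24) or by nap-adjusted time awake (bins up
#' to the window length). Zero-filled; sums to 100 whenever there is any
#' intake.
#'
#' @param events intake events with `clock_time_h`, `time_awake_h`, `kcal`.
#' @param mode `"clock"` or `"awake"`.
#' @param day_length_h window length (caps the number of awake bins).
#' @param bin_h bin width in hours.
#' @return named numeric vector of percentages.
#' @export
bin_distribution <- function(events, mode = c("clock", "awake"),
                             day_length_h = 24, bin_h = 4) {
  mode <- match.arg(mode)
  if (mode == "clock") {
    edges <- seq(0, 24, by = bin_h)
    x <- events$clock_time_h
  } else {
    edges <- seq(0, bin_h * ceiling(max(day_length_h, bin_h) / bin_h), by = bin_h)
    x <- events$time_awake_h
  }
  nb <- length(edges) - 1
  labels <- sprintf("%02d-%02d", edges[-length(edges)], edges[-1])
  out <- stats::setNames(numeric(nb), labels)
  total <- sum(events$kcal)
  if (nrow(events) == 0 || total <= 0) return(out)
  idx <- pmin(findInterval(x, edges, rightmost.closed = FALSE), nb)
  for (b in seq_len(nb)) out[b] <- 100 * sum(events$kcal[idx == b]) / total
  out
}

#' Compute all day-level chrononutrition metrics
#'
#' One row per day window: meal count, total and per-macronutrient %BMR,
#' timing latencies and eating window, weighted circular summary (mean
#' intake time, rho, circular SD), night and at-work caloric percentages,
#' and flattened 4-h clock and time-awake bin percentages. Timing metrics
#' use only qualifying events (> `min_kcal`, default 5 kcal) and are `NA`
#' when fewer than `min_events` (default 2) qualify; totals always use all
#' events.
#'
#' @param events assigned intake events (see [assign_to_window()]).
#' @param windows day windows.
#' @param subjects subject table with `subject_id`, `sex`, `age_years`,
#'   `height_cm`, `weight_kg`.
#' @param episodes sleep episodes (to locate the following main-sleep
#'   onset).
#' @param min_kcal strict kcal threshold for timing metrics.
#' @param min_events minimum qualifying events for timing metrics.
#' @param night_start,night_end night window clock hours.
#' @return data.frame of day metrics (one row per window).
#' @export
compute_day_metrics <- function(events, windows, subjects, episodes = NULL,
                                min_kcal = 5, min_events = 2,
                                night_start = 23, night_end = 6) {
  stopifnot(all(c("subject_id", "sex", "age_years", "height_cm",
                  "weight_kg") %in% names(subjects)))
  subjects$bmr_24h <- mifflin_st_jeor(subjects$sex, subjects$age_years,
                                      subjects$height_cm, subjects$weight_kg)
  if (!is.null(episodes)) {
    episodes$onset <- parse_timestamp(episodes$onset)
    episodes$wake <- parse_timestamp(episodes$wake)
  }
  windows$window_start <- parse_timestamp(windows$window_start)
  windows$window_end <- parse_timestamp(windows$window_end)
  macro_pct_cols <- paste0(sub("_kcal$", "", MACRO_COLS), "_pct_bmr")
  rows <- vector("list", nrow(windows))
  for (j in seq_len(nrow(windows))) {
    w <- windows[j, ]
    bmr <- subjects$bmr_24h[match(w$subject_id, subjects$subject_id)]
    ev <- events[!is.na(events$window_id) & events$window_id == j, , drop = FALSE]
    total <- sum(ev$kcal)
    m <- list(subject_id = w$subject_id, date = w$date,
              day_type = w$day_type, day_length_h = w$day_length_h,
              bmr_24h = bmr, meal_count = nrow(ev), total_kcal = total,
              total_pct_bmr = pct_bmr(total, bmr, w$day_length_h))
    for (i in seq_along(MACRO_COLS))
      m[[macro_pct_cols[i]]] <- pct_bmr(sum(ev[[MACRO_COLS[i]]]), bmr,
                                        w$day_length_h)
    qual <- filter_caloric(ev, min_kcal)
    if (nrow(qual) >= min_events) {
      onset_next <- if (!is.null(episodes)) {
        k <- which(episodes$subject_id == w$subject_id & episodes$is_main &
                   abs(hours_between(w$window_end, episodes$wake)) < 1e-6)
        if (length(k) == 1) episodes$onset[k] else NA
      } else NA
      tw <- eating_window(qual, onset_next)
      cs <- circular_summary(qual$clock_time_h, qual$kcal)
      m$first_meal_latency_h <- tw$first_meal_latency_h
      m$last_meal_to_sleep_h <- tw$last_meal_to_sleep_h
      m$eating_window_h <- tw$eating_window_h
      m$circ_mean_h <- cs$mean_time
      m$circ_rho <- cs$rho
      m$circ_sd_h <- cs$circ_sd_h
    } else {
      m[c("first_meal_latency_h", "last_meal_to_sleep_h", "eating_window_h",
          "circ_mean_h", "circ_rho", "circ_sd_h")] <- NA_real_
    }
    m$pct_at_night <- fraction_at_night(ev, night_start, night_end)
    m$pct_at_work <- fraction_at_work(ev, w$work_start, w$work_end)
    cb <- bin_distribution(ev, "clock")
    names(cb) <- paste0("clock_", names(cb))
    ab <- bin_distribution(ev, "awake", day_length_h = 36)
    names(ab) <- paste0("awake_", names(ab))
    rows[[j]] <- c(m, as.list(cb), as.list(ab))
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
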