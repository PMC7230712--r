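# Synthetic shift-worker data with known ground truth. The stated world
# mirrors the study roster: 35-day cycles mixing 9- and 12-h morning
# (0700-1600, 0700-1900), evening (1500-2400) and night (2230-0730,
# 2300-0800, 1900-0700) shifts separated by rest days, and 28-day cycles of
# 12-h day (0700-1900) and night (1900-0700) shifts; day-type-conditional
# sleep timing; meal times from von Mises mixtures dominated by a
# 1600-2000 h component, with a nocturnal component on night-shift days;
# lognormal meal calories and Dirichlet macronutrient composition.

SHIFT_CATALOGUE <- list(
  cycle35 = list(
    morning = list(c(7, 16), c(7, 19)),
    evening = list(c(15, 24)),
    night = list(c(22.5, 31.5), c(23, 32), c(19, 31))),
  cycle28 = list(
    morning = list(c(7, 19)),
    night = list(c(19, 31))))

# 35-day template: runs of >= 3 consecutive shifts of each type (so that
# second-in-sequence collection days are interior), rest days after night
# runs, never night -> morning.
ROSTER_35 <- c("rest", "rest", "rest",
               "morning", "morning", "morning",
               "rest", "rest",
               "evening", "evening", "evening",
               "rest", "rest", "rest",
               "night", "night", "night",
               "rest", "rest",
               "morning", "morning", "morning",
               "evening", "evening", "evening",
               "rest", "rest",
               "night", "night", "night",
               "rest", "rest", "rest",
               "morning", "morning")
ROSTER_28 <- rep(c("morning", "morning", "rest", "rest",
                   "night", "night", "rest", "rest"), length.out = 28)

#' Meal-timing parameters for one day type
#'
#' @param components data.frame with `mu` (clock hours), `kappa` (>= 0) and
#'   `weight` columns; weights must sum to 1.
#' @param n_meals_mean Poisson mean; meal count is `Poisson(mean) + 1`.
#' @param kcal_log_mu,kcal_log_sigma lognormal meal-size parameters.
#' @param macro_alpha Dirichlet concentrations for (carb, fat, protein)
#'   kcal shares.
#' @param sugar_frac,satfat_frac Beta shape pairs for the sugar share of
#'   carbohydrate and saturated share of fat.
#' @param pair_prob probability a meal is emitted as two same-type records
#'   a few minutes apart (exercises the 15-min merge).
#' @param beverage_prob probability a meal is downgraded to a small
#'   beverage-only record (exercises the >5 kcal filter).
#' @return a `meal_timing_params` list.
#' @export
meal_timing_params <- function(components, n_meals_mean,
                               kcal_log_mu = 5.9, kcal_log_sigma = 0.6,
                               macro_alpha = c(8.8, 7.2, 3.6),
                               sugar_frac = c(7.4, 12.6),
                               satfat_frac = c(6.6, 13.4),
                               pair_prob = 0.15, beverage_prob = 0.10) {
  components <- as.data.frame(components)
  stopifnot(all(c("mu", "kappa", "weight") %in% names(components)),
            all(components$kappa >= 0),
            abs(sum(components$weight) - 1) < 1e-8,
            n_meals_mean > 0, all(macro_alpha > 0))
  structure(list(components = components, n_meals_mean = n_meals_mean,
                 kcal_log_mu = kcal_log_mu, kcal_log_sigma = kcal_log_sigma,
                 macro_alpha = macro_alpha, sugar_frac = sugar_frac,
                 satfat_frac = satfat_frac, pair_prob = pair_prob,
                 beverage_prob = beverage_prob),
            class = "meal_timing_params")
}

#' Default day-type meal-timing parameters
#'
#' Mixtures peak at 1600-2000 h on every day type; night-shift days add a
#' nocturnal (0200 h) component of weight 0.30. Meal counts follow the
#' cohort's per-day-type means (7.5, 6.3, 5.0, 5.9 via Poisson + 1) and
#' lognormal sizes put total intake at the observed %BMR scale.
#'
#' @return named list of [meal_timing_params()] per day type.
#' @export
default_day_type_params <- function() {
  comp <- function(mu, kappa, weight) data.frame(mu = mu, kappa = kappa,
                                                 weight = weight)
  list(
    rest = meal_timing_params(
      comp(c(8.5, 12.5, 18, 20.5), c(4, 5, 5, 3), c(0.20, 0.25, 0.35, 0.20)),
      n_meals_mean = 6.5, kcal_log_mu = 5.86),
    morning = meal_timing_params(
      comp(c(6.2, 11.5, 18, 20.5), c(5, 5, 5, 3), c(0.20, 0.20, 0.40, 0.20)),
      n_meals_mean = 5.3, kcal_log_mu = 5.97),
    evening = meal_timing_params(
      comp(c(9.5, 13, 18, 21.5), c(4, 5, 5, 4), c(0.20, 0.20, 0.40, 0.20)),
      n_meals_mean = 4.0, kcal_log_mu = 5.92),
    night = meal_timing_params(
      comp(c(17, 20, 2, 7.5), c(4, 5, 3, 4), c(0.25, 0.30, 0.30, 0.15)),
      n_meals_mean = 4.9, kcal_log_mu = 5.83))
}

#' Default day-type sleep-timing parameters
#'
#' Wake/onset clock means per day type (onset hours > 24 denote the next
#' calendar day), with dispersions treated as between-day SDs in minutes:
#' rest 0800 +/- 24 / 2256 +/- 18; morning 0532 +/- 7 / 2215 +/- 15;
#' evening 0834 +/- 26 / 0111(+1d) +/- 9; night 1558 +/- 39 /
#' 0914(+1d) +/- 17.
#'
#' @return named list per day type:
#'   `list(wake_mean, wake_sd, onset_mean, onset_sd)` (hours, minutes).
#' @export
default_sleep_params <- function() {
  list(
    rest = list(wake_mean = 8, wake_sd = 24,
                onset_mean = 22 + 56 / 60, onset_sd = 18),
    morning = list(wake_mean = 5 + 32 / 60, wake_sd = 7,
                   onset_mean = 22 + 15 / 60, onset_sd = 15),
    evening = list(wake_mean = 8 + 34 / 60, wake_sd = 26,
                   onset_mean = 24 + 1 + 11 / 60, onset_sd = 9),
    night = list(wake_mean = 15 + 58 / 60, wake_sd = 39,
                 onset_mean = 24 + 9 + 14 / 60, onset_sd = 17))
}

#' Generator configuration
#'
#' @param n_subjects number of subjects (default 30).
#' @param roster_kind `"mixed"` (default; subjects split between cycles in
#'   the cohort's 27:4 proportion), `"cycle35"` or `"cycle28"`.
#' @param day_type_params named list of [meal_timing_params()] per day
#'   type; defaults to [default_day_type_params()].
#' @param sleep_params named list per day type; defaults to
#'   [default_sleep_params()].
#' @param nap_prob probability of a nap before a 2230/2300-start night
#'   shift.
#' @param start_date roster start date.
#' @param seed integer RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 30,
                             roster_kind = c("mixed", "cycle35", "cycle28"),
                             day_type_params = default_day_type_params(),
                             sleep_params = default_sleep_params(),
                             nap_prob = 0.25,
                             start_date = as.Date("2024-01-08"),
                             seed = 1L) {
  roster_kind <- match.arg(roster_kind)
  stopifnot(n_subjects >= 1)
  for (p in sleep_params)
    if (p$wake_sd <= 0 || p$onset_sd <= 0)
      stop("sleep timing SDs must be positive")
  types_needed <- unique(c(ROSTER_35, ROSTER_28))
  if (!all(types_needed %in% names(sleep_params)) ||
      !all(types_needed %in% names(day_type_params)))
    stop("every day type in the roster needs sleep and meal parameters")
  structure(list(n_subjects = n_subjects, roster_kind = roster_kind,
                 day_type_params = day_type_params,
                 sleep_params = sleep_params, nap_prob = nap_prob,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate one subject's shift roster
#'
#' Produces the day-type sequence of the requested cycle with shift
#' start/end times drawn from the catalogue (constant within a run of
#' consecutive shifts), plus the position of each day within its run
#' (`in_seq`; the cohort's collection days are the second in a sequence).
#'
#' @param config a [generator_config()].
#' @param subject_id subject identifier.
#' @param kind `"cycle35"` or `"cycle28"`.
#' @return data.frame: `subject_id`, `date`, `day_type`, `start`, `end`
#'   (POSIXct, `NA` on rest days), `in_seq`.
#' @export
generate_roster <- function(config, subject_id, kind = config$roster_kind) {
  if (!kind %in% c("cycle35", "cycle28"))
    stop("unknown roster_kind: ", kind)
  types <- if (kind == "cycle35") ROSTER_35 else ROSTER_28
  catalogue <- SHIFT_CATALOGUE[[kind]]
  n <- length(types)
  dates <- config$start_date + seq_len(n) - 1
  start <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  end <- start
  run_id <- cumsum(c(TRUE, types[-1] != types[-n]))
  in_seq <- stats::ave(seq_len(n), run_id, FUN = seq_along)
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    ty <- types[idx[1]]
    if (ty == "rest") next
    opts <- catalogue[[ty]]
    tm <- opts[[sample.int(length(opts), 1)]]
    start[idx] <- at_clock(dates[idx], tm[1])
    end[idx] <- at_clock(dates[idx], tm[2])
  }
  data.frame(subject_id = subject_id, date = dates, day_type = types,
             start = start, end = end, in_seq = in_seq)
}

#' Generate sleep episodes for a roster
#'
#' One main sleep per day boundary with day-type-conditional onset (from
#' the ending day's type) and wake (from the starting day's type), plus
#' occasional naps before late-start night shifts. Implied durations
#' outside 2.5-16 h (which occur at rest-to-night and night-to-rest
#' transitions) fall back to 7 h (after too-short) or 9 h (after too-long)
#' sleeps. A main sleep never overlaps the shift it precedes (bounded
#' retries, then error).
#'
#' @param roster from [generate_roster()].
#' @param config a [generator_config()].
#' @return data.frame `subject_id`, `onset`, `wake`, `is_main`.
#' @export
generate_sleep <- function(roster, config) {
  if (nrow(roster) == 0) stop("empty roster")
  sp <- config$sleep_params
  n <- nrow(roster)
  types <- c("rest", roster$day_type, "rest")
  d0 <- roster$date[1] - 1
  onset <- wake <- as.POSIXct(rep(NA_real_, n + 1), origin = "1970-01-01",
                              tz = "UTC")
  for (i in 0:n) {       # boundary between day i and day i+1
    p_on <- sp[[types[i + 1]]]
    p_wk <- sp[[types[i + 2]]]
    next_start <- if (i + 1 <= n) roster$start[i + 1] else NA
    ok <- FALSE
    for (try in 1:10) {
      on <- at_clock(d0 + i, p_on$onset_mean + stats::rnorm(1, 0, p_on$onset_sd / 60))
      wk <- at_clock(d0 + i + 1, p_wk$wake_mean + stats::rnorm(1, 0, p_wk$wake_sd / 60))
      dur <- hours_between(on, wk)
      if (dur < 2.5) wk <- on + 7 * 3600
      else if (dur > 16) wk <- on + 9 * 3600
      if (i >= 1 && on <= wake[i]) next       # overlap with previous sleep
      if (!is.na(next_start) && wk >= next_start) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place main sleep at boundary ", i,
                  " for subject ", roster$subject_id[1])
    onset[i + 1] <- on
    wake[i + 1] <- wk
  }
  out <- data.frame(subject_id = roster$subject_id[1], onset = onset,
                    wake = wake, is_main = TRUE)
  # naps before late-start night shifts, between the daytime main sleep and
  # the shift
  naps <- list()
  for (i in seq_len(n)) {
    if (roster$day_type[i] != "night" || is.na(roster$start[i])) next
    if (clock_hours(roster$start[i]) < 22) next
    if (stats::runif(1) > config$nap_prob) next
    wk_prev <- wake[i]                       # wake starting day i
    gap_start <- max(as.numeric(wk_prev) + 3600,
                     as.numeric(at_clock(roster$date[i], 19)))
    latest_end <- as.numeric(roster$start[i]) - 15 * 60
    dur_s <- stats::runif(1, 0.5, 1.2) * 3600
    if (gap_start + dur_s >= latest_end) next
    s <- stats::runif(1, gap_start, latest_end - dur_s)
    naps[[length(naps) + 1]] <- data.frame(
      subject_id = roster$subject_id[1],
      onset = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
      wake = as.POSIXct(s + dur_s, origin = "1970-01-01", tz = "UTC"),
      is_main = FALSE)
  }
  if (length(naps)) out <- rbind(out, do.call(rbind, naps))
  out[order(out$onset), ]
}

# sample one clock hour from a von Mises mixture
sample_mixture_hours <- function(n, components) {
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$weight)
  vapply(comp, function(k)
    angle_to_hours(rvonmises(1, hours_to_angle(components$mu[k]),
                             components$kappa[k])), numeric(1))
}

#' Generate raw meal records for one wake period
#'
#' Draws `Poisson(n_meals_mean) + 1` meals with clock times from the day
#' type's von Mises mixture restricted to the wake period (rejection
#' sampling with a uniform fallback), lognormal kcal, Dirichlet
#' macronutrient kcal (carb + fat + protein + alcohol = kcal exactly),
#' clock-band meal-type labels, occasional same-type record pairs a few
#' minutes apart, and occasional low-kcal beverage-only records.
#'
#' @param wake_start,wake_end POSIXct bounds of the wake period.
#' @param params a [meal_timing_params()].
#' @param subject_id subject identifier.
#' @param naps optional data.frame of nap intervals (`onset`, `wake`) to
#'   avoid.
#' @return data.frame of meal-log rows.
#' @export
generate_meals <- function(wake_start, wake_end, params, subject_id = "s1",
                           naps = NULL) {
  if (!inherits(params, "meal_timing_params")) stop("invalid params")
  span <- hours_between(wake_start, wake_end)
  if (span <= 0) stop("empty wake period")
  n_meals <- stats::rpois(1, params$n_meals_mean) + 1
  d0 <- calendar_date(wake_start)
  times <- as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  in_nap <- function(t) {
    !is.null(naps) && nrow(naps) > 0 &&
      any(naps$onset <= t & t < naps$wake)
  }
  for (m in seq_len(n_meals)) {
    placed <- FALSE
    for (try in 1:50) {
      h <- sample_mixture_hours(1, params$components)
      cand <- at_clock(d0, h)
      while (cand < wake_start) cand <- cand + 24 * 3600
      cands <- cand
      if (cand + 24 * 3600 < wake_end) cands <- c(cands, cand + 24 * 3600)
      cands <- cands[cands < wake_end]
      if (!length(cands)) next
      t <- cands[sample.int(length(cands), 1)]
      if (in_nap(t)) next
      times <- c(times, t)
      placed <- TRUE
      break
    }
    if (!placed)
      times <- c(times, wake_start + stats::runif(1, 0, span) * 3600)
  }
  times <- sort(times)
  n <- length(times)
  kcal <- stats::rlnorm(n, params$kcal_log_mu, params$kcal_log_sigma)
  g <- matrix(stats::rgamma(n * 3, shape = rep(params$macro_alpha,
                                               each = n)), nrow = n)
  shares <- g / rowSums(g)
  carb <- shares[, 1] * kcal
  fat <- shares[, 2] * kcal
  protein <- shares[, 3] * kcal
  sugar <- stats::rbeta(n, params$sugar_frac[1], params$sugar_frac[2]) * carb
  satfat <- stats::rbeta(n, params$satfat_frac[1], params$satfat_frac[2]) * fat
  h <- clock_hours(times)
  meal_type <- ifelse(h >= 5 & h < 10.5, "breakfast",
               ifelse(h >= 10.5 & h < 14.5, "lunch",
               ifelse(h >= 17 & h < 21.5, "dinner", "snack")))
  bev <- stats::runif(n) < params$beverage_prob
  scale <- ifelse(bev, 0.03, 1)
  meal_type[bev] <- "beverage_only"
  rec <- data.frame(subject_id = subject_id, timestamp = times,
                    meal_type = meal_type, kcal = kcal * scale,
                    carb_kcal = carb * scale, sugar_kcal = sugar * scale,
                    fat_kcal = fat * scale, satfat_kcal = satfat * scale,
                    protein_kcal = protein * scale, alcohol_kcal = 0)
  # occasionally split a meal into two same-type records < 15 min apart
  split_rows <- which(stats::runif(n) < params$pair_prob &
                        rec$timestamp + 13 * 60 < wake_end)
  if (length(split_rows)) {
    extra <- rec[split_rows, , drop = FALSE]
    frac <- 0.3
    num_cols <- c("kcal", MACRO_COLS)
    extra[num_cols] <- extra[num_cols] * frac
    rec[split_rows, num_cols] <- rec[split_rows, num_cols] * (1 - frac)
    extra$timestamp <- extra$timestamp + stats::runif(length(split_rows), 3, 12) * 60
    rec <- rbind(rec, extra)
  }
  rec[order(rec$timestamp), ]
}

#' Generate a complete synthetic dataset
#'
#' Subjects (sex ratio, age and anthropometrics matched to the cohort's
#' BMR scale), rosters, sleep logs, meal logs and per-(subject, day type)
#' ground truth. Fully reproducible under `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of data.frames: `subjects`, `work`, `sleep`, `meals`,
#'   `roster`, `ground_truth`.
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 6 / 31, "female", "male")
  age <- pmin(pmax(round(stats::rnorm(n, 32.1, 5.4)), 25), 44)
  height <- ifelse(sex == "male", stats::rnorm(n, 178, 6),
                   stats::rnorm(n, 166, 6))
  weight <- ifelse(sex == "male", stats::rnorm(n, 82.5, 8),
                   stats::rnorm(n, 67, 7))
  subjects <- data.frame(subject_id = ids, sex = sex, age_years = age,
                         height_cm = round(height, 1),
                         weight_kg = round(weight, 1))
  kinds <- if (config$roster_kind == "mixed")
    ifelse(seq_len(n) %% 8 == 0, "cycle28", "cycle35")
  else rep(config$roster_kind, n)
  work <- list(); sleep <- list(); meals <- list(); rosters <- list()
  for (i in seq_len(n)) {
    ros <- generate_roster(config, ids[i], kinds[i])
    slp <- generate_sleep(ros, config)
    mains <- slp[slp$is_main, ]
    day_meals <- list()
    for (d in seq_len(nrow(ros))) {
      wk <- mains$wake[d]            # boundary d-1 -> d wake starts day d
      on <- mains$onset[d + 1]       # onset ending day d
      params <- config$day_type_params[[ros$day_type[d]]]
      naps <- slp[!slp$is_main & slp$onset >= wk & slp$wake <= on, ,
                  drop = FALSE]
      day_meals[[d]] <- generate_meals(wk, on, params, ids[i], naps)
    }
    rosters[[i]] <- ros
    work[[i]] <- ros[!is.na(ros$start), c("subject_id", "start", "end")]
    sleep[[i]] <- slp
    meals[[i]] <- do.call(rbind, day_meals)
  }
  meals <- do.call(rbind, meals)
  rownames(meals) <- NULL
  dataset <- list(subjects = subjects,
                  work = do.call(rbind, work),
                  sleep = do.call(rbind, sleep),
                  meals = meals,
                  roster = do.call(rbind, rosters))
  dataset$ground_truth <- compute_ground_truth(dataset, config)
  dataset
}

# per (subject, day type) summaries recomputable exactly from the emitted
# meal stream: kcal-weighted circular mean/rho of qualifying (> 5 kcal)
# record times, total kcal, mean first/last qualifying clock times, plus
# the dominant mixture component mean as the generative target
compute_ground_truth <- function(dataset, config) {
  ros <- dataset$roster
  meals <- dataset$meals
  meals$date <- calendar_date(meals$timestamp)
  rows <- list()
  for (s in unique(ros$subject_id)) {
    for (ty in unique(ros$day_type[ros$subject_id == s])) {
      mm <- meals[meals$subject_id == s, , drop = FALSE]
      days <- ros$date[ros$subject_id == s & ros$day_type == ty]
      # attribute records to roster days by the wake-to-onset span they
      # were generated in: a record belongs to the latest day whose window
      # started before it
      slp <- dataset$sleep[dataset$sleep$subject_id == s &
                             dataset$sleep$is_main, ]
      wake_by_day <- slp$wake[seq_len(nrow(ros[ros$subject_id == s, ]))]
      all_days <- ros$date[ros$subject_id == s]
      idx <- findInterval(as.numeric(mm$timestamp), as.numeric(wake_by_day))
      mm <- mm[idx >= 1 & all_days[pmax(idx, 1)] %in% days, , drop = FALSE]
      if (!nrow(mm)) next
      q <- mm[mm$kcal > 5, , drop = FALSE]
      cs <- if (nrow(q)) circular_summary(clock_hours(q$timestamp), q$kcal)
            else list(mean_time = NA_real_, rho = NA_real_)
      comp <- config$day_type_params[[ty]]$components
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, day_type = ty, n_days = length(days),
        n_records = nrow(mm), total_kcal = sum(mm$kcal),
        circ_mean_h = cs$mean_time, rho = cs$rho,
        mu_dominant_h = comp$mu[which.max(comp$weight)])
    }
  }
  do.call(rbind, rows)
}

#' Export a synthetic dataset to CSV
#'
#' Writes `meals.csv`, `work.csv`, `sleep.csv`, `subjects.csv` and
#' `ground_truth.csv` in the ingest schemas (ISO-8601 timestamps); the
#' files round-trip losslessly through the package readers.
#'
#' @param dataset from [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
export_dataset <- function(dataset, out_dir) {
  if (is.null(dataset$meals) || nrow(dataset$meals) == 0)
    stop("empty dataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (col in names(df))
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_timestamp(df[[col]])
    df
  }
  paths <- c(meals = file.path(out_dir, "meals.csv"),
             work = file.path(out_dir, "work.csv"),
             sleep = file.path(out_dir, "sleep.csv"),
             subjects = file.path(out_dir, "subjects.csv"),
             ground_truth = file.path(out_dir, "ground_truth.csv"))
  utils::write.csv(fmt(dataset$meals[c("subject_id", "timestamp", "meal_type",
                                       "kcal", MACRO_COLS)]),
                   paths["meals"], row.names = FALSE)
  utils::write.csv(fmt(dataset$work), paths["work"], row.names = FALSE)
  utils::write.csv(fmt(dataset$sleep[c("subject_id", "onset", "wake",
                                       "is_main")]),
                   paths["sleep"], row.names = FALSE)
  utils::write.csv(dataset$subjects, paths["subjects"], row.names = FALSE)
  utils::write.csv(fmt(dataset$ground_truth), paths["ground_truth"],
                   row.names = FALSE)
  invisible(paths)
}
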