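shift_on <- function(start_h, end_h, day = "2024-03-04") {
  d <- as.POSIXct(day, tz = "UTC")
  c(start = d + start_h * 3600, end = d + end_h * 3600)
}

test_that("classify_shift maps the roster catalogue to intended classes", {
  cases <- list(
    list(7, 16, "morning"), list(7, 19, "morning"),
    list(15, 24, "evening"),
    list(22.5, 31.5, "night"), list(23, 32, "night"), list(19, 31, "night"),
    list(7, 21, "excluded"),      # 14 h, > 13.5
    list(7, 11, "excluded"),      # 4 h, < 4.5
    list(18, 26, "evening"),        # ends 0200: evening bound inclusive
    list(18, 27, "unclassified"),   # ends 0300, night core not fully covered
    list(10, 15, "unclassified"))
  d <- as.POSIXct("2024-03-04", tz = "UTC")
  for (cs in cases)
    expect_identical(classify_shift(d + cs[[1]] * 3600, d + cs[[2]] * 3600),
                     cs[[3]])
  # vectorized, total on valid shifts
  starts <- d + c(7, 15, 22.5) * 3600
  ends <- d + c(16, 24, 31.5) * 3600
  expect_identical(classify_shift(starts, ends),
                   c("morning", "evening", "night"))
  expect_error(classify_shift(d + 3600, d), "after start")
})

test_that("resolve_main_sleep flags the longest episode, ties to earlier onset", {
  eps <- data.frame(
    subject_id = "s1",
    onset = c(ts("23:00", "2024-03-03"), ts("14:00")),
    wake = c(ts("06:00"), ts("15:00")))
  out <- resolve_main_sleep(eps)
  expect_identical(out$is_main, c(TRUE, FALSE))

  tie <- data.frame(
    subject_id = "s1",
    onset = c(ts("01:00"), ts("10:00")),
    wake = c(ts("05:00"), ts("14:00")))
  out <- resolve_main_sleep(tie)
  expect_identical(out$is_main, c(TRUE, FALSE))

  overlap <- data.frame(
    subject_id = "s1",
    onset = c(ts("01:00"), ts("03:00")),
    wake = c(ts("05:00"), ts("09:00")))
  expect_error(resolve_main_sleep(overlap), "overlap")
})

test_that("build_day_windows computes wake-to-wake spans and labels", {
  # morning-shift day: wake 0532 -> next wake 0605 (+1 d) = 24.55 h
  eps <- data.frame(
    subject_id = "s1",
    onset = c(ts("22:10", "2024-03-03"), ts("22:15", "2024-03-04")),
    wake = c(ts("05:32", "2024-03-04"), ts("06:05", "2024-03-05")),
    is_main = TRUE)
  shifts <- data.frame(subject_id = "s1",
                       start = ts("07:00"), end = ts("16:00"))
  w <- build_day_windows(shifts, eps)
  expect_equal(nrow(w), 1)
  expect_identical(w$day_type, "morning")
  expect_equal(w$day_length_h, 24.55, tolerance = 1e-9)

  # rest day, exact 24 h
  eps$wake[2] <- ts("05:32", "2024-03-05")
  w <- build_day_windows(shifts[0, ], eps)
  expect_identical(w$day_type, "rest")
  expect_equal(w$day_length_h, 24)
  expect_true(is.na(w$work_start))
})

test_that("windows exclude atypical-shift days and implausible lengths", {
  eps <- data.frame(
    subject_id = "s1",
    onset = c(ts("22:00", "2024-03-03"), ts("22:00", "2024-03-04")),
    wake = c(ts("06:00", "2024-03-04"), ts("06:00", "2024-03-05")),
    is_main = TRUE)
  long_shift <- data.frame(subject_id = "s1",
                           start = ts("07:00"), end = ts("21:00"))  # 14 h
  w <- build_day_windows(long_shift, eps)
  expect_equal(nrow(w), 0)
  expect_match(attr(w, "dropped")$reason, "excluded")
})

test_that("sleep_fraction matches the rest-day benchmark", {
  w <- data.frame(day_length_h = 24, sleep_h = 8.16)
  expect_equal(sleep_fraction(w), 0.34)
  expect_equal(sleep_fraction(data.frame(day_length_h = 24, sleep_h = 0)), 0)
  expect_equal(sleep_fraction(data.frame(day_length_h = 24, sleep_h = 24)), 1)
})

test_that("on synthetic rosters classification recovers generator labels and windows are disjoint", {
  cfg <- generator_config(n_subjects = 2, seed = 21)
  set.seed(21)
  for (kind in c("cycle35", "cycle28")) {
    ros <- generate_roster(cfg, "sX", kind)
    worked <- ros[!is.na(ros$start), ]
    expect_identical(classify_shift(worked$start, worked$end),
                     worked$day_type)
  }
  ds <- generate_dataset(cfg)
  slp <- resolve_main_sleep(ds$sleep[c("subject_id", "onset", "wake")])
  w <- build_day_windows(ds$work, slp)
  expect_gt(nrow(w), 30)
  for (s in unique(w$subject_id)) {
    ws <- w[w$subject_id == s, ]
    ws <- ws[order(ws$window_start), ]
    expect_true(all(diff(as.numeric(ws$window_start)) > 0))
    expect_true(all(as.numeric(ws$window_start[-1]) >=
                    as.numeric(ws$window_end[-nrow(ws)]) - 1e-9))
  }
  expect_true(all(w$day_length_h > 12 & w$day_length_h < 36))
})
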