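test_that("rosters follow the cycle structure", {
  cfg <- generator_config(seed = 1)
  set.seed(1)
  r35 <- generate_roster(cfg, "s1", "cycle35")
  expect_equal(nrow(r35), 35)
  # runs of >= 2 consecutive shifts of each worked type
  runs <- rle(r35$day_type)
  for (ty in c("morning", "evening", "night"))
    expect_true(any(runs$values == ty & runs$lengths >= 2))
  worked <- r35[!is.na(r35$start), ]
  dur <- as.numeric(difftime(worked$end, worked$start, units = "hours"))
  expect_true(all(dur %in% c(9, 12)))

  set.seed(1)
  r28 <- generate_roster(cfg, "s1", "cycle28")
  expect_equal(nrow(r28), 28)
  expect_false(any(r28$day_type == "evening"))
  worked <- r28[!is.na(r28$start), ]
  expect_true(all(as.numeric(difftime(worked$end, worked$start,
                                      units = "hours")) == 12))
  # only the two 12-h catalogue shifts
  expect_true(all(clock_hours(worked$start) %in% c(7, 19)))

  expect_error(generate_roster(cfg, "s1", "cycle99"), "roster_kind")

  # determinism under a fixed seed
  set.seed(42); a <- generate_roster(cfg, "s1", "cycle35")
  set.seed(42); b <- generate_roster(cfg, "s1", "cycle35")
  expect_identical(a, b)
})

test_that("sleep generation hits the day-type clock targets as SDs shrink", {
  sp <- default_sleep_params()
  for (ty in names(sp)) { sp[[ty]]$wake_sd <- 1e-9; sp[[ty]]$onset_sd <- 1e-9 }
  cfg <- generator_config(n_subjects = 1, sleep_params = sp, nap_prob = 0,
                          seed = 3)
  # all-morning stretch: wake 0532, onset 2215
  ros <- data.frame(subject_id = "s1",
                    date = as.Date("2024-01-08") + 0:2,
                    day_type = "morning",
                    start = at_clock(as.Date("2024-01-08") + 0:2, 7),
                    end = at_clock(as.Date("2024-01-08") + 0:2, 16),
                    in_seq = 1:3)
  set.seed(3)
  slp <- generate_sleep(ros, cfg)
  mid <- slp[2, ]  # boundary day1 -> day2
  expect_equal(clock_hours(mid$onset), 22.25, tolerance = 1e-6)
  expect_equal(clock_hours(mid$wake), 5 + 32 / 60, tolerance = 1e-6)

  # rest days: wake 0800, onset 2256
  ros$day_type <- "rest"; ros$start <- NA; ros$end <- NA
  set.seed(3)
  slp <- generate_sleep(ros, cfg)
  expect_equal(clock_hours(slp$onset[2]), 22 + 56 / 60, tolerance = 1e-6)
  expect_equal(clock_hours(slp$wake[2]), 8, tolerance = 1e-6)
})

test_that("generated sleep episodes are pairwise disjoint and miss shifts", {
  cfg <- generator_config(n_subjects = 1, seed = 17, nap_prob = 1)
  set.seed(17)
  ros <- generate_roster(cfg, "s1", "cycle35")
  slp <- generate_sleep(ros, cfg)
  slp <- slp[order(slp$onset), ]
  expect_true(all(as.numeric(slp$onset[-1]) >=
                  as.numeric(slp$wake[-nrow(slp)]) - 1e-9))
  # main sleep never overlaps the shift it precedes
  mains <- slp[slp$is_main, ]
  for (d in which(!is.na(ros$start)))
    expect_lt(as.numeric(mains$wake[d]), as.numeric(ros$start[d]))
})

test_that("generate_meals honours degenerate mixtures and composition", {
  w0 <- ts("08:00:00"); w1 <- ts("23:00:00")
  # kappa -> Inf: every meal at 1800
  pk <- meal_timing_params(data.frame(mu = 18, kappa = 1e7, weight = 1),
                           n_meals_mean = 4, pair_prob = 0,
                           beverage_prob = 0)
  set.seed(5)
  rec <- generate_meals(w0, w1, pk, "s1")
  expect_true(all(abs(clock_hours(rec$timestamp) - 18) < 1e-6))

  # kappa = 0: roughly uniform over the wake period, small rho at scale
  pu <- meal_timing_params(data.frame(mu = 12, kappa = 0, weight = 1),
                           n_meals_mean = 400, pair_prob = 0,
                           beverage_prob = 0)
  set.seed(6)
  rec <- generate_meals(ts("00:00:00"), ts("00:00:00", "2024-03-05"), pu, "s1")
  expect_lt(circular_summary(clock_hours(rec$timestamp))$rho, 0.1)

  # macro kcal sums to total kcal and mean shares track the Dirichlet alpha
  pa <- meal_timing_params(data.frame(mu = 18, kappa = 2, weight = 1),
                           n_meals_mean = 600,
                           macro_alpha = c(44, 36, 18) * 0.2,
                           pair_prob = 0, beverage_prob = 0)
  set.seed(7)
  rec <- generate_meals(w0, w1, pa, "s1")
  macro_sum <- rec$carb_kcal + rec$fat_kcal + rec$protein_kcal +
    rec$alcohol_kcal
  expect_equal(macro_sum / rec$kcal, rep(1, nrow(rec)), tolerance = 1e-6)
  expect_true(all(rec$sugar_kcal <= rec$carb_kcal))
  expect_true(all(rec$satfat_kcal <= rec$fat_kcal))
  shares <- colSums(rec[c("carb_kcal", "fat_kcal", "protein_kcal")]) /
    sum(rec$kcal)
  expect_equal(unname(shares), c(0.44, 0.36, 0.18), tolerance = 0.04)

  expect_error(generate_meals(w1, w0, pa), "empty wake")
})

test_that("datasets export, round-trip and are byte-identical under a seed", {
  cfg <- generator_config(n_subjects = 2, seed = 11)
  ds <- generate_dataset(cfg)
  dir1 <- withr::local_tempdir()
  paths <- export_dataset(ds, dir1)
  expect_true(all(file.exists(paths)))

  meals <- read_meal_log(paths["meals"])
  expect_equal(nrow(meals), nrow(ds$meals))
  expect_equal(sum(meals$kcal), sum(ds$meals$kcal), tolerance = 1e-4)
  work <- read_work_log(paths["work"])
  expect_equal(nrow(work), nrow(ds$work))
  sleep <- read_sleep_log(paths["sleep"])
  expect_equal(nrow(sleep), nrow(ds$sleep))

  # same seed -> byte-identical files
  dir2 <- withr::local_tempdir()
  export_dataset(generate_dataset(cfg), dir2)
  for (f in basename(paths))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))

  expect_error(export_dataset(list(meals = ds$meals[0, ]), withr::local_tempdir()),
               "empty")
})

test_that("pipeline recovers generator circular means on concentrated data", {
  # single dominant component per day type, kappa >= 8, many meals
  comp <- function(mu) data.frame(mu = mu, kappa = 10, weight = 1)
  dtp <- list(
    rest = meal_timing_params(comp(15.5), n_meals_mean = 8, pair_prob = 0,
                              beverage_prob = 0),
    morning = meal_timing_params(comp(14), n_meals_mean = 8, pair_prob = 0,
                                 beverage_prob = 0),
    evening = meal_timing_params(comp(15), n_meals_mean = 8, pair_prob = 0,
                                 beverage_prob = 0),
    night = meal_timing_params(comp(23), n_meals_mean = 8, pair_prob = 0,
                               beverage_prob = 0))
  cfg <- generator_config(n_subjects = 8, day_type_params = dtp, seed = 31)
  b <- suppressWarnings(run_pipeline(pipeline_config(simulate = cfg, seed = 31)))
  gt <- b$dataset$ground_truth
  for (ty in c("rest", "night")) {
    q <- filter_caloric(b$events[!is.na(b$events$day_type) &
                                   b$events$day_type == ty, ])
    expect_gt(nrow(q), 200)
    cs <- circular_summary(q$clock_time_h, q$kcal)
    se <- cs$circ_sd_h / sqrt(nrow(q))
    # pipeline estimate vs the ground-truth stream (exactly recomputable)
    truth <- circular_summary(gt$circ_mean_h[gt$day_type == ty])$mean_time
    expect_lt(abs(((cs$mean_time - truth + 12) %% 24) - 12), 3 * se + 0.05)
    # and vs the generating mu, allowing for wake-period truncation bias
    mu <- dtp[[ty]]$components$mu[1]
    expect_lt(abs(((cs$mean_time - mu + 12) %% 24) - 12), 3 * se + 0.15)
  }
})
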