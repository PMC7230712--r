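test_that("chi_square_gof reproduces the textbook formula and oracle", {
  # hand/brute-force oracle on every case
  brute <- function(obs, w) {
    e <- sum(obs) * w / sum(w)
    sum((obs - e)^2 / e)
  }
  cases <- list(list(c(210, 133, 85, 141), c(28, 21, 17, 24)),
                list(c(210, 141), c(28, 24)),
                list(c(10, 20, 30), c(1, 2, 3)),
                list(c(5, 9, 2, 7, 11), c(3, 1, 4, 1, 5)))
  for (cs in cases) {
    res <- chi_square_gof(cs[[1]], cs[[2]])
    expect_equal(res$statistic, brute(cs[[1]], cs[[2]]), tolerance = 1e-12)
    # independent library oracle
    ct <- suppressWarnings(stats::chisq.test(cs[[1]], p = cs[[2]] / sum(cs[[2]])))
    expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-9)
    expect_equal(res$p_raw, unname(ct$p.value), tolerance = 1e-9)
  }
  # exact proportionality -> 0, p = 1
  res <- chi_square_gof(c(10, 20, 30), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)
  expect_error(chi_square_gof(c(1, 2), c(0, 1)), "zero")
  expect_error(chi_square_gof(c(1), c(1)), "length")
})

test_that("welch_t matches t.test on reconstructed samples", {
  # identical groups: t = 0, p = 1
  res <- welch_t(10, 2, 8, 10, 2, 8)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)

  # construct samples with exact means/SDs and compare with stats::t.test
  mk <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  set.seed(9)
  for (rep in 1:5) {
    n1 <- sample(4:20, 1); n2 <- sample(4:20, 1)
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    x <- mk(n1, m1, s1); y <- mk(n2, m2, s2)
    res <- welch_t(m1, s1, n1, m2, s2, n2)
    tt <- stats::t.test(x, y)
    expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res$df, unname(tt$parameter), tolerance = 1e-8)
    expect_equal(res$p_raw, tt$p.value, tolerance = 1e-8)
  }

  # equal n and SD reduces to the pooled-variance t
  res <- welch_t(3, 1.5, 10, 1, 1.5, 10)
  pooled_t <- (3 - 1) / (1.5 * sqrt(2 / 10))
  expect_equal(res$statistic, pooled_t, tolerance = 1e-12)
  expect_equal(res$df, 18)
  expect_error(welch_t(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(2)
  for (rep in 1:10) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # permutation invariance
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

simulate_metric_table <- function(n_subj = 30, effect_rest = 0, seed = 1,
                                  sd_subj = 25, sd_resid = 40) {
  set.seed(seed)
  day_types <- c("rest", "morning", "evening", "night")
  subj <- sprintf("P%02d", seq_len(n_subj))
  u <- rnorm(n_subj, 0, sd_subj)
  sex <- sample(c("male", "female"), n_subj, replace = TRUE)
  age <- runif(n_subj, 25, 44)
  rows <- expand.grid(subject_id = subj, day_type = day_types,
                      stringsAsFactors = FALSE)
  i <- match(rows$subject_id, subj)
  rows$sex <- sex[i]
  rows$age_years <- age[i]
  rows$y <- 150 + u[i] + ifelse(rows$day_type == "rest", effect_rest, 0) +
    rnorm(nrow(rows), 0, sd_resid)
  rows
}

test_that("fit_day_type_model detects a rest-day effect and respects the null", {
  tab <- simulate_metric_table(effect_rest = 40, seed = 4)
  res <- fit_day_type_model(tab, "y")
  expect_lt(res$omnibus$p_raw, 0.01)
  rest_contrasts <- grepl("rest", res$contrasts$contrast)
  expect_true(any(res$contrasts$p_adj[rest_contrasts] < 0.05))
  expect_equal(res$contrasts$p_adj, bh_adjust(res$contrasts$p_raw))

  # power: detected in nearly all replicates at this effect size
  hits <- vapply(1:15, function(s) {
    r <- suppressWarnings(fit_day_type_model(
      simulate_metric_table(effect_rest = 40, seed = 100 + s), "y"))
    r$omnibus$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # null calibration: rejection rate near alpha
  null_p <- vapply(1:40, function(s) {
    suppressWarnings(fit_day_type_model(
      simulate_metric_table(effect_rest = 0, seed = 500 + s),
      "y"))$omnibus$p_raw
  }, numeric(1))
  expect_lt(mean(null_p < 0.05), 0.2)
  expect_gt(mean(null_p < 0.5), 0.2)

  one <- simulate_metric_table()
  one <- one[one$day_type == "rest", ]
  expect_error(fit_day_type_model(one, "y"), "two day types")
})

test_that("singular fits fall back to a fixed-effects model", {
  tab <- simulate_metric_table(sd_subj = 0, sd_resid = 1, seed = 9,
                               n_subj = 6)
  expect_warning(res <- fit_day_type_model(tab, "y"), "singular|falling back")
  expect_true(res$singular)
  expect_s3_class(res$fit, "lm")
})
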