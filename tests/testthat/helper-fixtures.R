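# Shared fixtures and independent oracles.

ts <- function(x, day = "2024-03-04") {
  as.POSIXct(paste(day, x), tz = "UTC")
}

meal_row <- function(time, type = "snack", kcal = 100, subject = "s1",
                     carb = 0.5, fat = 0.3, protein = 0.2,
                     sugar = 0.2, satfat = 0.1, day = "2024-03-04") {
  data.frame(subject_id = subject, timestamp = ts(time, day),
             meal_type = type, kcal = kcal,
             carb_kcal = kcal * carb, sugar_kcal = kcal * sugar,
             fat_kcal = kcal * fat, satfat_kcal = kcal * satfat,
             protein_kcal = kcal * protein, alcohol_kcal = 0)
}

meal_log <- function(...) do.call(rbind, list(...))

# Brute-force merge oracle: full transitive closure of the pairwise
# "same subject, same type, within gap" relation (repeated boolean matrix
# multiplication), independent of the sequential chaining implementation.
merge_oracle <- function(records, gap_min = 15) {
  records <- records[order(records$subject_id, records$timestamp), ]
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- records$subject_id[i] == records$subject_id[j] &&
      records$meal_type[i] == records$meal_type[j] &&
      abs(as.numeric(records$timestamp[i]) -
          as.numeric(records$timestamp[j])) <= gap_min * 60
  }
  repeat {
    nxt <- (adj %*% adj > 0) | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  for (i in seq_len(n)) comp[i] <- min(which(adj[i, ]))
  agg <- lapply(split(seq_len(n), comp), function(idx) {
    idx <- idx[order(records$timestamp[idx])]
    r <- records[idx[length(idx)], ]
    r$kcal <- sum(records$kcal[idx])
    for (col in c("carb_kcal", "sugar_kcal", "fat_kcal", "satfat_kcal",
                  "protein_kcal", "alcohol_kcal"))
      r[[col]] <- sum(records[[col]][idx])
    r$n_merged <- length(idx)
    r
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$subject_id, out$timestamp), ]
  rownames(out) <- NULL
  out
}

# Brute-force circular-mean oracle: the weighted mean direction maximizes
# sum(w * cos(theta - mu)); locate the maximizer on successively refined
# grids down to ~1e-9 rad.
circ_mean_oracle <- function(hours, weights) {
  theta <- hours / 24 * 2 * pi
  f <- function(mu) sapply(mu, function(m) sum(weights * cos(theta - m)))
  lo <- 0; hi <- 2 * pi
  for (round in 1:6) {
    grid <- seq(lo, hi, length.out = 1001)
    best <- grid[which.max(f(grid))]
    step <- (hi - lo) / 1000
    lo <- best - 2 * step; hi <- best + 2 * step
  }
  (best %% (2 * pi)) / (2 * pi) * 24
}

# random small meal log: times clustered so merges actually occur
random_meal_log <- function(n, seed) {
  set.seed(seed)
  base <- do.call(rbind, lapply(seq_len(n), function(i)
    meal_row("08:00:00",
             type = sample(c("snack", "dinner", "beverage_only"), 1),
             kcal = round(runif(1, 10, 500)))))
  base$timestamp <- ts("08:00:00") + sort(round(runif(n, 0, 150))) * 60
  base
}

expect_hours_equal <- function(a, b, tol = 1e-6) {
  d <- abs(((a - b) %% 24))
  expect_lt(min(d, 24 - d), tol)
}
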