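test_that("window ODBA vanishes for constant and symmetric channels", {
  ts <- as.POSIXct("2018-05-01", tz = "UTC") + (0:39) / 10
  s <- triaxial_series(ts, ax = rep(1234, 40), ay = rep(-500, 40),
                       az = rep(16384, 40))
  w <- compute_window_odba(s)
  expect_true(all(w$odba == 0))
  # one channel alternating +/- k around 0: mean 0, midpoint 0
  s2 <- triaxial_series(ts, ax = rep(c(700, -700), 20), ay = rep(0, 40),
                        az = rep(16384, 40))
  expect_true(all(compute_window_odba(s2)$odba == 0))
})

test_that("window ODBA matches a brute-force oracle exactly", {
  s <- random_windows_series(200, seed = 21)
  w <- compute_window_odba(s)
  bf <- brute_force_window_odba(s$timestamp, s$ax, s$ay, s$az)
  expect_equal(nrow(w), length(bf$odba))
  expect_identical(w$odba, bf$odba)
})

test_that("window ODBA is scale-equivariant and non-negative", {
  s <- random_windows_series(50, seed = 22)
  w1 <- compute_window_odba(s)
  s3 <- triaxial_series(s$timestamp, s$ax * 3, s$ay * 3, s$az * 3)
  w3 <- compute_window_odba(s3)
  expect_equal(w3$odba, 3 * w1$odba)
  expect_true(all(w1$odba >= 0))
})

test_that("aggregation means minutes and sums hours", {
  # 30 windows of 0.1 in one minute: minute mean 0.1, hour contribution 3.0
  w <- tibble::tibble(
    window_start = as.POSIXct("2018-05-01", tz = "UTC") + 2 * (0:29),
    odba = 0.1)
  agg <- aggregate_odba(w)
  expect_equal(agg$minute$odba, 0.1)
  expect_equal(agg$hourly$odba, 3.0)
  expect_false(agg$hourly$complete) # only one minute of the hour present
  # a single window in a minute equals the window value
  w1 <- tibble::tibble(
    window_start = as.POSIXct("2018-05-01", tz = "UTC"), odba = 0.42)
  expect_equal(aggregate_odba(w1)$minute$odba, 0.42)
  # random series: hour sums equal brute-force regrouping by hour key
  s <- random_windows_series(3600, seed = 23) # 2 hours of windows
  w2 <- compute_window_odba(s)
  agg2 <- aggregate_odba(w2)
  key <- format(w2$window_start, "%Y-%m-%d %H")
  expect_equal(agg2$hourly$odba, as.numeric(tapply(w2$odba, key, sum)))
  # conservation: total hourly ODBA equals total window ODBA
  expect_equal(sum(agg2$hourly$odba), sum(w2$odba))
})

test_that("hour classification uses the strict >30-minute rule", {
  mk <- function(odba_by_min) tibble::tibble(
    minute_start = as.POSIXct("2018-05-01", tz = "UTC") +
      60 * (seq_along(odba_by_min) - 1),
    odba = odba_by_min)
  # 31 minutes just above 0.28 -> active
  expect_true(classify_hours(mk(c(rep(0.29, 31), rep(0, 29))))$active)
  # exactly 30 above -> inactive (strictly more than 30 required)
  expect_false(classify_hours(mk(c(rep(0.29, 30), rep(0, 30))))$active)
  # 60 minutes exactly at the threshold -> inactive (strictly above)
  expect_false(classify_hours(mk(rep(0.28, 60)))$active)
  # incomplete hours are flagged and excluded
  out <- classify_hours(mk(rep(0.5, 45)))
  expect_false(out$complete)
  expect_true(is.na(out$active))
})

test_that("bout categorization separates nonstop, gap-resumed and other", {
  one_night <- function(act) {
    start <- as.POSIXct("2018-05-01 12:00:00", tz = "UTC")
    odba <- odba_series_from_minutes(start + 60 * (0:1439),
                                     ifelse(act, 0.5, 0))
    nights <- tibble::tibble(night_id = as.Date("2018-05-01"),
                             start = start, end = start + 86400)
    nightly_summary(odba, nights)
  }
  # one contiguous 300-min run
  act <- rep(FALSE, 1440); act[301:600] <- TRUE
  rec <- one_night(act)
  expect_equal(rec$bout_category, "single_bout")
  expect_equal(rec$active_minutes, 300L)
  # 200 active, 90 inactive, 100 active
  act <- rep(FALSE, 1440); act[101:300] <- TRUE; act[391:490] <- TRUE
  expect_equal(one_night(act)$bout_category, "gap_resumed")
  # no activity at all
  expect_equal(one_night(rep(FALSE, 1440))$bout_category, "other")
  # two runs separated by less than an hour: neither nonstop nor resumed
  act <- rep(FALSE, 1440); act[101:200] <- TRUE; act[231:300] <- TRUE
  expect_equal(one_night(act)$bout_category, "other")
})

test_that("nightly totals conserve hourly ODBA within the window", {
  fix <- bout_fixture(c("single_bout", "gap_resumed", "other_inactive"),
                      seed = 31)
  recs <- nightly_summary(fix$odba, fix$nights)
  expect_equal(nrow(recs), 3)
  expect_true(all(recs$total_odba >= 0))
  for (i in 1:3) {
    sel <- fix$odba$hourly$hour_start >= fix$nights$start[i] &
      fix$odba$hourly$hour_start < fix$nights$end[i]
    expect_equal(recs$total_odba[i], sum(fix$odba$hourly$odba[sel]))
  }
})

test_that("threshold scan recommends a cut between well-separated modes", {
  set.seed(41)
  vals <- c(exp(rnorm(500, log(0.05), 0.3)), exp(rnorm(500, log(0.6), 0.3)))
  vals <- sample(vals)
  cands <- seq(0.02, 1, by = 0.02)
  scan <- threshold_sensitivity(vals, cands)
  expect_false(scan$degenerate)
  expect_gt(scan$recommended, 0.1)
  expect_lt(scan$recommended, 0.5)
  # candidates above the series maximum classify nothing as active
  high <- threshold_sensitivity(vals, c(max(vals) + 1, max(vals) + 2))
  expect_true(all(high$scan$active_minutes == 0))
  # active minutes are non-increasing across sorted candidates
  expect_true(all(diff(scan$scan$active_minutes) <= 0))
  # constant series: explicit degenerate signal
  flat <- threshold_sensitivity(rep(0.3, 100), c(0.1, 0.5))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$recommended))
})

test_that("deployment-day filter drops the first and last analysis days", {
  hours <- tibble::tibble(
    timestamp = seq(as.POSIXct("2018-05-01 15:00:00", tz = "UTC"),
                    as.POSIXct("2018-05-08 09:00:00", tz = "UTC"),
                    by = 3600),
    v = 1)
  out <- filter_deployment_days(hours, min(hours$timestamp),
                                max(hours$timestamp))
  expect_equal(length(attr(out, "retained_nights")), 5)
  # a 2-day deployment yields nothing, with a warning
  short <- hours[hours$timestamp <= as.POSIXct("2018-05-03 09:00:00",
                                               tz = "UTC"), ]
  expect_warning(
    res <- filter_deployment_days(short, min(short$timestamp),
                                  max(short$timestamp)),
    "no data retained")
  expect_equal(nrow(res), 0)
  # 8-day deployment: retained nights equal the brute-force set difference
  hours8 <- tibble::tibble(
    timestamp = seq(as.POSIXct("2018-05-01 15:00:00", tz = "UTC"),
                    as.POSIXct("2018-05-09 09:00:00", tz = "UTC"),
                    by = 3600))
  out8 <- filter_deployment_days(hours8, min(hours8$timestamp),
                                 max(hours8$timestamp))
  all_nights <- as.Date(as.POSIXct(hours8$timestamp) - 12 * 3600)
  all_nights <- sort(unique(all_nights))
  expect_equal(attr(out8, "retained_nights"),
               setdiff(all_nights, range(all_nights)) |> as.Date(
                 origin = "1970-01-01"))
})

test_that("nightly active minutes are monotone in the threshold", {
  fix <- bout_fixture(rep(c("single_bout", "gap_resumed"), 5), seed = 51)
  grid <- c(0.1, 0.28, 0.45, 0.6)
  counts <- sapply(grid, function(th) {
    nightly_summary(fix$odba, fix$nights, threshold = th)$active_minutes
  })
  for (i in seq_len(nrow(counts))) {
    expect_true(all(diff(counts[i, ]) <= 0))
  }
})
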