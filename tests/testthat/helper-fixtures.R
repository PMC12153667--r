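# Programmatic fixtures shared across test files.

# independently coded brute-force evaluation of window ODBA (the oracle is a
# plain loop over windows, deliberately separate from the pipeline code)
brute_force_window_odba <- function(timestamp, ax, ay, az, window_s = 2,
                                    counts_per_g = 2^14) {
  t0 <- as.numeric(timestamp[1])
  idx <- floor((as.numeric(timestamp) - t0) / window_s)
  out <- numeric(0)
  starts <- numeric(0)
  for (w in sort(unique(idx))) {
    sel <- idx == w
    odba <- 0
    for (ch in list(ax[sel], ay[sel], az[sel])) {
      odba <- odba + abs((mean(ch) - (max(ch) + min(ch)) / 2) / counts_per_g)
    }
    out <- c(out, odba)
    starts <- c(starts, t0 + w * window_s)
  }
  list(window_start = starts, odba = out)
}

# a triaxial series of n consecutive 2-s windows of random integer counts
random_windows_series <- function(n_windows, samples_per_window = 10,
                                  seed = 1) {
  set.seed(seed)
  n <- n_windows * samples_per_window
  triaxial_series(
    timestamp = as.POSIXct("2018-05-01", tz = "UTC") +
      (seq_len(n) - 1) * 2 / samples_per_window,
    ax = sample(-20000:20000, n, replace = TRUE),
    ay = sample(-20000:20000, n, replace = TRUE),
    az = sample(-20000:20000, n, replace = TRUE))
}

# minute-activity sequence (length 1440) of a prescribed bout category
make_bout_sequence <- function(category, seed = 1) {
  set.seed(seed)
  act <- rep(FALSE, 1440)
  if (category == "single_bout") {
    len <- sample(60:500, 1)
    start <- sample(1:(1440 - len), 1)
    act[start:(start + len - 1)] <- TRUE
  } else if (category == "gap_resumed") {
    len1 <- sample(30:200, 1)
    gap <- sample(60:180, 1)
    len2 <- sample(30:200, 1)
    start <- sample(1:(1440 - len1 - gap - len2), 1)
    act[start:(start + len1 - 1)] <- TRUE
    s2 <- start + len1 + gap
    act[s2:(s2 + len2 - 1)] <- TRUE
  } else if (category == "other_short_gap") {
    len1 <- sample(30:200, 1)
    gap <- sample(5:59, 1)
    len2 <- sample(30:200, 1)
    start <- sample(1:(1440 - len1 - gap - len2), 1)
    act[start:(start + len1 - 1)] <- TRUE
    s2 <- start + len1 + gap
    act[s2:(s2 + len2 - 1)] <- TRUE
  } # "other_inactive": all FALSE
  act
}

# minute table + night-window rows for a stack of daily activity sequences
bout_fixture <- function(categories, seed = 1) {
  minute_start <- c()
  odba <- c()
  nights <- list()
  origin <- as.POSIXct("2018-05-01 12:00:00", tz = "UTC")
  for (i in seq_along(categories)) {
    act <- make_bout_sequence(categories[i], seed = seed + i)
    start <- origin + (i - 1) * 86400
    minute_start <- c(minute_start, start + 60 * (0:1439))
    odba <- c(odba, ifelse(act, 0.5, 0))
    nights[[i]] <- tibble::tibble(
      night_id = as.Date(start), start = start, end = start + 86400)
  }
  list(odba = odba_series_from_minutes(
         as.POSIXct(minute_start, tz = "UTC", origin = "1970-01-01"), odba),
       nights = dplyr::bind_rows(nights))
}

# small simulated hourly cohort for model tests
sim_cohort_hours <- function(n_ind = 20, n_days = 9, seed = 1,
                             sigma_individual = 0.3, sigma_resid = 0.5,
                             rho = 0.4,
                             beta = c(temp = 0.3, temp_sq = -0.2,
                                      bci = 0.1, bci_temp = 0.2),
                             profile = default_circadian_profile(),
                             activity_logit_params = NULL) {
  wx <- simulate_weather(season_config(), n_days = n_days, seed = seed)
  ind <- simulate_individuals(n_ind, sigma_individual = sigma_individual,
                              seed = seed + 1000)
  coh <- synthetic_cohort(ind, wx)
  pars <- true_parameters(circadian_profile = profile, beta = beta,
                          sigma_individual = sigma_individual,
                          sigma_resid = sigma_resid, rho = rho,
                          activity_logit_params = activity_logit_params)
  sim <- simulate_hourly_odba(coh, pars, seed = seed + 2000)
  attr(sim, "params") <- pars
  sim
}

flat_profile <- function(level = 2) {
  function(hour) rep(level, length(hour))
}
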