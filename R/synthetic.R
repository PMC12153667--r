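# Synthetic weather, cohorts and accelerometry with fully exposed
# generative parameters, used as ground truth in recovery tests.

#' Seasonal weather-generator configuration
#'
#' Means, spreads and diurnal structure for the seven hourly covariates.
#' Air temperature is a sinusoidal diurnal cycle (peak mid-afternoon) around
#' a day-level AR-1 anomaly plus hourly noise; rainfall is zero-inflated
#' exponential; soil temperatures are exponentially smoothed (lagged)
#' transforms of air temperature, which deliberately induces the strong
#' Temp/SoilT collinearity seen in field meteorology; wind, humidity and
#' soil moisture are truncated-Gaussian.
#'
#' @param temp_mean mean air temperature, degrees C.
#' @param temp_diurnal_amplitude half peak-to-trough diurnal range, degrees C.
#' @param temp_day_sd SD of the day-level temperature anomaly, degrees C.
#' @param temp_day_rho AR-1 coefficient of the day-level anomaly.
#' @param temp_hour_sd SD of hourly temperature noise, degrees C.
#' @param rain_zero_prob probability an hour has zero rainfall.
#' @param rain_mean_mm mean rainfall of wet hours, mm.
#' @param wind_mean,wind_sd wind speed moments, m/s.
#' @param rh_mean,rh_sd relative humidity moments, % (clamped to [0, 100]).
#' @param soilm_mean,soilm_sd soil moisture moments, % (day-level AR-1 with
#'   coefficient `soilm_day_rho`).
#' @param soilm_day_rho AR-1 coefficient of the soil-moisture anomaly.
#' @param soilt10_smooth,soilt30_smooth exponential-smoothing coefficients
#'   for the 10 cm and 30 cm soil temperatures (larger = smoother, more
#'   lagged).
#' @return a `season_config` list.
#' @export
season_config <- function(temp_mean = 12, temp_diurnal_amplitude = 4,
                          temp_day_sd = 2.5, temp_day_rho = 0.6,
                          temp_hour_sd = 0.5,
                          rain_zero_prob = 0.8, rain_mean_mm = 0.5,
                          wind_mean = 3, wind_sd = 1.2,
                          rh_mean = 82, rh_sd = 8,
                          soilm_mean = 30, soilm_sd = 4,
                          soilm_day_rho = 0.8,
                          soilt10_smooth = 0.75, soilt30_smooth = 0.975) {
  sds <- c(temp_day_sd = temp_day_sd, temp_hour_sd = temp_hour_sd,
           wind_sd = wind_sd, rh_sd = rh_sd, soilm_sd = soilm_sd)
  if (any(sds < 0)) stop("SDs must be non-negative")
  if (rain_zero_prob < 0 || rain_zero_prob > 1) {
    stop("rain_zero_prob must lie in [0, 1]")
  }
  for (rho in c(temp_day_rho, soilm_day_rho)) {
    if (abs(rho) >= 1) stop("day-level AR-1 coefficients must satisfy |rho| < 1")
  }
  structure(as.list(environment())[c(
    "temp_mean", "temp_diurnal_amplitude", "temp_day_sd", "temp_day_rho",
    "temp_hour_sd", "rain_zero_prob", "rain_mean_mm", "wind_mean", "wind_sd",
    "rh_mean", "rh_sd", "soilm_mean", "soilm_sd", "soilm_day_rho",
    "soilt10_smooth", "soilt30_smooth")], class = "season_config")
}

# stationary AR-1 draw of length n with marginal SD s
ar1_series <- function(n, rho, s) {
  if (n < 1) return(numeric(0))
  if (s == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, s)
  if (n > 1) {
    innov_sd <- s * sqrt(1 - rho^2)
    for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, innov_sd)
  }
  x
}

#' Simulate an hourly weather series
#'
#' @param config a [season_config()].
#' @param n_days number of days (>= 1).
#' @param seed RNG seed.
#' @param start first day (Date), hours begin at 00:00.
#' @return a [weather_series()] of `24 * n_days` hourly records.
#' @export
simulate_weather <- function(config, n_days, seed = 1,
                             start = as.Date("2018-05-01")) {
  stopifnot(inherits(config, "season_config"))
  if (n_days < 1) stop("n_days must be >= 1")
  set.seed(seed)
  n <- 24 * n_days
  hour_start <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n) - 1)
  hod <- (seq_len(n) - 1) %% 24
  day <- rep(seq_len(n_days), each = 24)

  day_anom <- ar1_series(n_days, config$temp_day_rho, config$temp_day_sd)
  temp <- config$temp_mean +
    config$temp_diurnal_amplitude * cos(2 * pi * (hod - 15) / 24) +
    day_anom[day] + rnorm(n, 0, config$temp_hour_sd)

  wet <- runif(n) >= config$rain_zero_prob
  rain <- ifelse(wet & config$rain_mean_mm > 0,
                 rgamma(n, shape = 1, scale = config$rain_mean_mm), 0)

  wind <- pmax(0, rnorm(n, config$wind_mean, config$wind_sd))
  rh <- pmin(100, pmax(0, rnorm(n, config$rh_mean, config$rh_sd)))
  soilm_anom <- ar1_series(n_days, config$soilm_day_rho, config$soilm_sd)
  soilm <- pmax(0, config$soilm_mean + soilm_anom[day])

  smooth_of <- function(x, a) {
    s <- numeric(n)
    prev <- config$temp_mean
    for (i in seq_len(n)) {
      prev <- a * prev + (1 - a) * x[i]
      s[i] <- prev
    }
    s
  }
  soilt10 <- smooth_of(temp, config$soilt10_smooth)
  soilt30 <- smooth_of(temp, config$soilt30_smooth)

  weather_series(tibble::tibble(
    hour_start = hour_start, temp = temp, rain = rain, wind = wind,
    rh = rh, soilm = soilm, soilt10 = soilt10, soilt30 = soilt30))
}

#' Simulate a cohort of individuals
#'
#' Traits are drawn uniformly from configured ranges; BCI is computed with
#' [compute_bci()]; individual intercepts (log2-ODBA scale) are drawn
#' Normal(0, `sigma_individual`^2).
#'
#' @param n number of individuals (>= 1).
#' @param trait_config list with `mass_range` (kg), `length_range` (cm),
#'   `age_range` (years), `sexes` (character vector sampled uniformly).
#' @param sigma_individual SD of individual intercepts, log2 units (>= 0).
#' @param seed RNG seed.
#' @return tibble: `individual_id`, `sex`, `age`, `mass`, `length`, `bci`,
#'   `intercept_draw`.
#' @export
simulate_individuals <- function(n,
                                 trait_config = list(
                                   mass_range = c(7, 14),
                                   length_range = c(68, 82),
                                   age_range = c(2, 10),
                                   sexes = c("F", "M")),
                                 sigma_individual = 0.3, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (sigma_individual < 0) stop("sigma_individual must be >= 0")
  set.seed(seed)
  draw_range <- function(r) {
    if (r[1] == r[2]) rep(r[1], n) else runif(n, r[1], r[2])
  }
  mass <- draw_range(trait_config$mass_range)
  len <- draw_range(trait_config$length_range)
  tibble::tibble(
    individual_id = sprintf("ind%02d", seq_len(n)),
    sex = sample(trait_config$sexes, n, replace = TRUE),
    age = round(draw_range(trait_config$age_range)),
    mass = mass, length = len,
    bci = as.numeric(compute_bci(mass, len)),
    intercept_draw = rnorm(n, 0, sigma_individual))
}

#' Bundle individuals, weather and deployment windows into a cohort
#'
#' @param individuals tibble from [simulate_individuals()].
#' @param weather a [weather_series()].
#' @param deployments optional tibble (`individual_id`, `start`, `end`,
#'   POSIXct); by default every individual is deployed over the full
#'   weather span.
#' @return a `synthetic_cohort` list.
#' @export
synthetic_cohort <- function(individuals, weather, deployments = NULL) {
  if (is.null(deployments)) {
    deployments <- tibble::tibble(
      individual_id = individuals$individual_id,
      start = min(weather$hour_start),
      end = max(weather$hour_start) + 3600)
  }
  if (any(!is.finite(individuals$intercept_draw))) {
    stop("non-finite intercept draws")
  }
  if (any(deployments$end <= deployments$start)) {
    stop("empty deployment window")
  }
  if (any(deployments$start < min(weather$hour_start)) ||
      any(deployments$end > max(weather$hour_start) + 3600)) {
    stop("deployments extend beyond the weather series")
  }
  structure(list(individuals = individuals, weather = weather,
                 deployments = deployments), class = "synthetic_cohort")
}

#' Default bimodal nocturnal circadian profile
#'
#' Log2-ODBA offset by hour of day: low through daylight, with activity
#' peaks shortly after dusk (~22 h) and before dawn (~4 h). Exactly
#' periodic over 24 h.
#'
#' @param base daytime log2-ODBA level.
#' @param dusk_peak,dawn_peak peak heights (log2 units).
#' @param concentration bump concentration (larger = narrower peaks).
#' @return vectorized function of hour of day.
#' @export
default_circadian_profile <- function(base = 1, dusk_peak = 2.2,
                                      dawn_peak = 1.8, concentration = 5) {
  function(hour) {
    bump <- function(h0) exp(concentration * (cos(2 * pi * (hour - h0) / 24) - 1))
    base + dusk_peak * bump(22) + dawn_peak * bump(4)
  }
}

#' Generative parameters of the hourly ODBA simulator
#'
#' @param circadian_profile function of hour of day (periodic over 24 h)
#'   giving the log2-ODBA circadian offset.
#' @param beta named numeric vector of effects on standardized terms; valid
#'   names: `temp`, `temp_sq`, `rain`, `rain_sq`, `wind`, `rh`, `soilm`,
#'   `soilt10`, `soilt30`, `age`, `bci`, `sex`, `bci_temp`, `bci_rain`,
#'   `bci_sex`.
#' @param sigma_individual SD of individual intercepts (log2 scale, >= 0).
#' @param sigma_resid marginal SD of the AR-1 residual (log2 scale, > 0).
#' @param rho AR-1 coefficient, |rho| < 1.
#' @param activity_logit_params optional list (`intercept`, `beta` named as
#'   above, optional `circadian` function) for the generative binary
#'   activity model; when `NULL`, the activity flag is the deterministic
#'   threshold rule on implied minute ODBA.
#' @param threshold_true minute-ODBA activity cut used by the generator.
#' @return a `true_parameters` list.
#' @export
true_parameters <- function(circadian_profile = default_circadian_profile(),
                            beta = c(temp = 0.3, temp_sq = -0.2),
                            sigma_individual = 0.3, sigma_resid = 0.5,
                            rho = 0.4, activity_logit_params = NULL,
                            threshold_true = 0.28) {
  if (sigma_individual < 0) stop("sigma_individual must be >= 0")
  if (sigma_resid <= 0) stop("sigma_resid must be > 0")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  valid <- c("temp", "temp_sq", "rain", "rain_sq", "wind", "rh", "soilm",
             "soilt10", "soilt30", "age", "bci", "sex", "bci_temp",
             "bci_rain", "bci_sex")
  if (length(beta) > 0 && (is.null(names(beta)) ||
                           !all(names(beta) %in% valid))) {
    stop("beta names must be among: ", paste(valid, collapse = ", "))
  }
  if (!isTRUE(all.equal(circadian_profile(0), circadian_profile(24)))) {
    stop("circadian profile must be periodic over 24 h")
  }
  structure(list(circadian_profile = circadian_profile, beta = beta,
                 sigma_individual = sigma_individual,
                 sigma_resid = sigma_resid, rho = rho,
                 activity_logit_params = activity_logit_params,
                 threshold_true = threshold_true),
            class = "true_parameters")
}

zscore_or_zero <- function(x) {
  if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
}

term_value <- function(term, row) {
  switch(term,
    temp_sq = row$temp^2,
    rain_sq = row$rain^2,
    sex = as.numeric(row$sex == "M"),
    bci_temp = row$bci * row$temp,
    bci_rain = row$bci * row$rain,
    bci_sex = row$bci * as.numeric(row$sex == "M"),
    row[[term]])
}

#' Simulate hourly ODBA for a cohort
#'
#' Generates, per individual-deployment hour,
#' `log2(odba) = circadian(hour) + sum(beta * standardized terms)
#'  + intercept_draw + eps`, with `eps` a stationary AR-1 process
#' (coefficient `rho`, marginal SD `sigma_resid`). Weather covariates and
#' the age/BCI traits are standardized internally over the emitted
#' deployment-covered rows (exactly as the downstream analysis
#' standardizes its modeling subset), so `beta` is on the standardized
#' scale; the standardization record is attached as an attribute. ODBA is strictly
#' positive by construction (`2^` of a finite value).
#'
#' @param cohort a [synthetic_cohort()].
#' @param params a [true_parameters()].
#' @param seed RNG seed.
#' @return tibble with `individual_id`, `hour_start`, `hour`,
#'   `hourly_odba`, `log2_odba`, `active` (generative ground truth),
#'   standardized covariate columns, `sex`, standardized `age` and `bci`,
#'   and `intercept_draw`; attribute `standardization` holds the weather
#'   z-moments.
#' @export
simulate_hourly_odba <- function(cohort, params, seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(params, "true_parameters"))
  set.seed(seed)
  wz <- cohort$weather
  out <- vector("list", nrow(cohort$individuals))
  for (i in seq_len(nrow(cohort$individuals))) {
    ind <- cohort$individuals[i, ]
    dep <- cohort$deployments[
      cohort$deployments$individual_id == ind$individual_id, ][1, ]
    hours <- wz[wz$hour_start >= dep$start & wz$hour_start < dep$end, ]
    span <- seq(from = trunc_time(dep$start, 3600),
                to = dep$end - 1, by = 3600)
    if (nrow(hours) < length(span)) {
      stop("missing weather hours within deployment of ", ind$individual_id)
    }
    n <- nrow(hours)
    hod <- as.numeric(format(hours$hour_start, "%H"))
    out[[i]] <- tibble::tibble(
      individual_id = ind$individual_id, hour_start = hours$hour_start,
      hour = hod,
      temp = hours$temp, rain = hours$rain, wind = hours$wind,
      rh = hours$rh, soilm = hours$soilm, soilt10 = hours$soilt10,
      soilt30 = hours$soilt30,
      sex = ind$sex, age = ind$age, bci = ind$bci,
      intercept_draw = ind$intercept_draw,
      eps = ar1_series(n, params$rho, params$sigma_resid))
  }
  res <- dplyr::bind_rows(out)
  # effects act on the modeling scale: covariates and traits standardized
  # over the emitted (deployment-covered) rows, as the analysis would
  means <- vapply(WEATHER_COVARIATES, function(v) mean(res[[v]]), numeric(1))
  sds <- vapply(WEATHER_COVARIATES, function(v) sd(res[[v]]), numeric(1))
  for (v in WEATHER_COVARIATES) res[[v]] <- zscore_or_zero(res[[v]])
  res$age <- zscore_or_zero(res$age)
  res$bci <- zscore_or_zero(res$bci)
  eta <- params$circadian_profile(res$hour) + res$intercept_draw
  for (term in names(params$beta)) {
    eta <- eta + params$beta[[term]] * term_value(term, res)
  }
  res$log2_odba <- eta + res$eps
  res$hourly_odba <- 2^res$log2_odba
  res$active <- if (!is.null(params$activity_logit_params)) {
    a <- params$activity_logit_params
    eta_a <- rep(a$intercept, nrow(res))
    if (!is.null(a$circadian)) eta_a <- eta_a + a$circadian(res$hour)
    for (term in names(a$beta)) {
      eta_a <- eta_a + a$beta[[term]] * term_value(term, res)
    }
    rbinom(nrow(res), 1, 1 / (1 + exp(-eta_a))) == 1
  } else {
    # implied flat minute mean: hourly sum over 1800 2-s windows
    res$hourly_odba / 1800 > params$threshold_true
  }
  res$eps <- NULL
  attr(res, "standardization") <- tibble::tibble(
    covariate = WEATHER_COVARIATES, mean = means, sd = sds)
  res
}

#' Simulate night-level records with known variance components
#'
#' Direct night-scale generator for repeatability recovery:
#' `y = mu + sum(beta * z-covariates) + b_i + e`, with
#' `b_i ~ N(0, sigma_individual^2)` and `e ~ N(0, sigma_resid^2)`, so the
#' generative ICC is `sigma_individual^2 / (sigma_individual^2 +
#' sigma_resid^2)`.
#'
#' @param n_individuals,n_nights design size.
#' @param sigma_individual,sigma_resid variance-component SDs.
#' @param beta named effects on the standard-normal night covariates `temp`
#'   and `rain`.
#' @param mu grand mean.
#' @param seed RNG seed.
#' @return tibble: `individual_id`, `night_id`, `temp`, `rain`,
#'   `total_odba`.
#' @export
simulate_nightly_records <- function(n_individuals, n_nights,
                                     sigma_individual, sigma_resid,
                                     beta = c(temp = 0.5), mu = 5,
                                     seed = 1) {
  if (sigma_individual < 0 || sigma_resid <= 0) {
    stop("invalid variance-component SDs")
  }
  set.seed(seed)
  b <- rnorm(n_individuals, 0, sigma_individual)
  grid <- expand.grid(ind = seq_len(n_individuals),
                      night = seq_len(n_nights))
  n <- nrow(grid)
  temp <- rnorm(n)
  rain <- rnorm(n)
  y <- mu + b[grid$ind] + rnorm(n, 0, sigma_resid)
  if ("temp" %in% names(beta)) y <- y + beta[["temp"]] * temp
  if ("rain" %in% names(beta)) y <- y + beta[["rain"]] * rain
  tibble::tibble(
    individual_id = sprintf("ind%02d", grid$ind),
    night_id = as.Date("2018-05-01") + grid$night - 1,
    temp = temp, rain = rain, total_odba = y)
}

#' Synthesize raw logger windows hitting minute-ODBA targets
#'
#' Inverse of the ODBA pipeline: emits integer tri-axial counts whose
#' per-window dynamic components (as computed by [compute_window_odba()])
#' reproduce each minute-averaged ODBA target to within one count
#' quantization unit (`1 / counts_per_g`). All dynamic signal is placed on
#' the x axis as a symmetric +/-h excursion pair (zero midpoint) plus a
#' constant fill level that sets the window mean; gravity is a constant
#' `+counts_per_g` offset on the z axis. The `seed` only randomises the
#' position of the excursion pair within each window.
#'
#' @param minute_odba_targets non-negative minute-averaged ODBA targets
#'   (g units), one per consecutive minute.
#' @param sample_rate_hz sampling frequency; `sample_rate_hz * window_s`
#'   must be at least 2 (and at least 3 for non-zero targets).
#' @param counts_per_g integer counts per g (default 2^14).
#' @param seed RNG seed (placement only).
#' @param start_time POSIXct time of the first sample.
#' @param window_s window length in seconds (default 2).
#' @param individual_id identifier for the emitted series.
#' @return a [triaxial_series()].
#' @export
synthesize_raw_windows <- function(minute_odba_targets, sample_rate_hz = 50,
                                   counts_per_g = 2^14, seed = 1,
                                   start_time = as.POSIXct(
                                     "2018-05-01 00:00:00", tz = "UTC"),
                                   window_s = 2,
                                   individual_id = "synthetic") {
  if (any(minute_odba_targets < 0)) stop("targets must be non-negative")
  n_samp <- as.integer(round(sample_rate_hz * window_s))
  if (n_samp < 2) stop("need at least 2 samples per window")
  if (n_samp < 3 && any(minute_odba_targets > 0)) {
    stop("non-zero targets need at least 3 samples per window")
  }
  set.seed(seed)
  per_min <- as.integer(60 / window_s)
  n_win <- length(minute_odba_targets) * per_min
  target_w <- rep(minute_odba_targets, each = per_min)

  dc <- target_w * counts_per_g                      # target counts
  fill <- round(dc * n_samp / (n_samp - 2))          # fill level
  h <- abs(fill) + 8                                 # excursion magnitude
  if (any(h + 1 > 32767)) stop("target exceeds signed 16-bit count range")

  ax <- matrix(rep(fill, each = n_samp), nrow = n_samp)
  pos <- vapply(seq_len(n_win), function(i) {
    sample.int(n_samp, 2)
  }, integer(2))
  zero_tgt <- target_w == 0
  for (i in seq_len(n_win)) {
    if (zero_tgt[i]) next
    ax[pos[1, i], i] <- h[i]
    ax[pos[2, i], i] <- -h[i]
  }
  # zero targets: constant channels (mean equals midpoint exactly)
  ax_vec <- as.vector(ax)
  total <- n_win * n_samp
  timestamp <- start_time +
    rep((seq_len(n_win) - 1) * window_s, each = n_samp) +
    rep((seq_len(n_samp) - 1) / sample_rate_hz, times = n_win)
  triaxial_series(timestamp,
                  ax = ax_vec,
                  ay = rep(0, total),
                  az = rep(counts_per_g, total),
                  counts_per_g = counts_per_g,
                  individual_id = individual_id)
}

#' Write a cohort and its ground truth to CSV files
#'
#' Emits `weather.csv`, `traits.csv`, `deployments.csv` and a
#' `true_parameters.csv` sidecar (scalar parameters, beta coefficients, and
#' the circadian profile sampled at each hour) into a directory.
#'
#' @param cohort a [synthetic_cohort()].
#' @param params a [true_parameters()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csvs <- function(cohort, params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_weather_csv(cohort$weather, file.path(dir, "weather.csv"))
  readr::write_csv(cohort$individuals, file.path(dir, "traits.csv"))
  dep <- cohort$deployments
  dep$start <- format(dep$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  dep$end <- format(dep$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(dep, file.path(dir, "deployments.csv"))
  side <- dplyr::bind_rows(
    tibble::tibble(name = c("sigma_individual", "sigma_resid", "rho",
                            "threshold_true"),
                   value = c(params$sigma_individual, params$sigma_resid,
                             params$rho, params$threshold_true)),
    tibble::tibble(name = paste0("beta_", names(params$beta)),
                   value = as.numeric(params$beta)),
    tibble::tibble(name = paste0("circadian_h", 0:23),
                   value = params$circadian_profile(0:23)))
  readr::write_csv(side, file.path(dir, "true_parameters.csv"))
  invisible(dir)
}
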