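# Weather ingestion, covariate standardization, collinearity screening,
# long-term anomalies, and the body-condition index.

WEATHER_COVARIATES <- c("temp", "rain", "wind", "rh",
                        "soilm", "soilt10", "soilt30")

#' Construct an hourly weather series
#'
#' Validates and classes a data frame of hourly meteorological records.
#' Expected columns: `hour_start` (POSIXct, UTC), `temp` (air temperature,
#' degrees C), `rain` (total rainfall, mm), `wind` (m/s), `rh` (relative
#' humidity, %), `soilm` (soil moisture, %), `soilt10` and `soilt30` (soil
#' temperature at 10 and 30 cm, degrees C). Missing hours are permitted and
#' simply absent; downstream night averaging flags incomplete windows.
#'
#' @param x data frame with the columns listed above.
#' @return a `weather_series` tibble.
#' @export
weather_series <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("hour_start", WEATHER_COVARIATES)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("weather series missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!inherits(x$hour_start, "POSIXct")) {
    stop("hour_start must be POSIXct")
  }
  if (anyDuplicated(x$hour_start)) stop("duplicate hour_start values")
  if (is.unsorted(x$hour_start)) x <- dplyr::arrange(x, .data$hour_start)
  if (any(x$rain < 0, na.rm = TRUE)) stop("rain must be non-negative")
  if (any(x$rh < 0 | x$rh > 100, na.rm = TRUE)) {
    stop("relative humidity must lie in [0, 100]")
  }
  class(x) <- c("weather_series", class(x))
  x
}

#' Read an hourly weather CSV
#'
#' Reads a CSV with an ISO-8601 `hour_start` column and the seven covariate
#' columns of [weather_series()]. Rows are returned in time order; gaps in
#' the hourly grid are left as absent rows rather than imputed.
#'
#' @param path file path.
#' @return a `weather_series` tibble.
#' @export
read_weather_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x$hour_start <- as.POSIXct(x$hour_start, tz = "UTC")
  weather_series(x)
}

#' Write an hourly weather CSV
#' @param weather a `weather_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  out <- as.data.frame(weather)
  out$hour_start <- format(out$hour_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Body-condition index
#'
#' BCI = ln(mass) / ln(length), a body-fat proxy for a medium-sized
#' carnivore. Units are fixed to kilograms and centimetres and recorded in
#' the result's attributes.
#'
#' @param mass_kg body mass in kg; must be positive.
#' @param length_cm body length in cm; must exceed 1 (so the log is
#'   positive).
#' @return numeric vector of BCI values with a `units` attribute.
#' @examples
#' compute_bci(10, 75)
#' @export
compute_bci <- function(mass_kg, length_cm) {
  if (any(!is.finite(mass_kg)) || any(!is.finite(length_cm))) {
    stop("mass and length must be finite")
  }
  if (any(mass_kg <= 0)) stop("mass must be positive")
  if (any(length_cm <= 1)) stop("length must exceed 1 cm")
  out <- log(mass_kg) / log(length_cm)
  attr(out, "units") <- c(mass = "kg", length = "cm")
  out
}

#' Read an individual trait table
#'
#' Expects columns `individual_id`, `sex`, `age` (years), `mass` (kg),
#' `length` (cm), and optionally `lactating`; computes `bci` when absent.
#'
#' @param path CSV path.
#' @return tibble of trait records.
#' @export
read_traits_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("individual_id", "sex", "age", "mass", "length")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("trait table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"bci" %in% names(x)) x$bci <- as.numeric(compute_bci(x$mass, x$length))
  tibble::as_tibble(x)
}

#' Standardize covariates to zero mean and unit SD
#'
#' Centres and scales each covariate with its sample mean and sample
#' (n - 1) standard deviation, returning both the transformed data and the
#' standardization record needed to back-transform model predictions.
#' Quadratic model terms are formed downstream as squares of these
#' standardized values.
#'
#' @param data data frame containing `covariates`.
#' @param covariates character vector of column names to standardize.
#' @param season optional season label stored in the record.
#' @return list with `data` (covariates replaced by z-scores) and `record`
#'   (tibble: covariate, mean, sd, season).
#' @export
standardize_covariates <- function(data, covariates, season = NA_character_) {
  stopifnot(all(covariates %in% names(data)))
  record <- lapply(covariates, function(v) {
    x <- data[[v]]
    if (sum(!is.na(x)) < 2 || length(unique(x[!is.na(x)])) < 2) {
      stop("covariate '", v, "' is constant; cannot standardize")
    }
    tibble::tibble(covariate = v, mean = mean(x, na.rm = TRUE),
                   sd = sd(x, na.rm = TRUE), season = season)
  })
  record <- dplyr::bind_rows(record)
  out <- data
  for (i in seq_len(nrow(record))) {
    v <- record$covariate[i]
    out[[v]] <- (data[[v]] - record$mean[i]) / record$sd[i]
  }
  list(data = out, record = record)
}

#' Back-transform a standardized value to its original scale
#'
#' @param z standardized values.
#' @param record standardization record from [standardize_covariates()].
#' @param covariate covariate name to look up.
#' @return values on the original measurement scale.
#' @export
back_standardize <- function(z, record, covariate) {
  row <- record[record$covariate == covariate, ]
  if (nrow(row) != 1) stop("covariate '", covariate, "' not in record")
  z * row$sd + row$mean
}

#' Screen covariate pairs for collinearity
#'
#' Lists all covariate pairs whose absolute Pearson correlation reaches the
#' threshold. Downstream all-subsets selection refuses any candidate model
#' containing both members of a flagged pair.
#'
#' @param data data frame of (standardized or raw) covariates.
#' @param covariates columns to screen.
#' @param r_threshold absolute correlation cut, default 0.7.
#' @return tibble with columns `var1`, `var2`, `r` (one row per unordered
#'   flagged pair, `var1` < `var2` alphabetically).
#' @export
collinearity_screen <- function(data, covariates, r_threshold = 0.7) {
  stopifnot(all(covariates %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 observations")
  cm <- cor(data[covariates], use = "pairwise.complete.obs")
  out <- tibble::tibble(var1 = character(), var2 = character(), r = numeric())
  for (i in seq_along(covariates)) {
    for (j in seq_along(covariates)) {
      if (j <= i) next
      r <- cm[i, j]
      if (is.finite(r) && abs(r) >= r_threshold) {
        pair <- sort(c(covariates[i], covariates[j]))
        out <- dplyr::bind_rows(out, tibble::tibble(
          var1 = pair[1], var2 = pair[2], r = r))
      }
    }
  }
  out
}

#' Long-term anomaly of a study period
#'
#' Expresses a study-period mean as a z-score against a long-term
#' climatological mean and SD, with a two-sided one-sample t-test of the
#' period values against the long-term mean.
#'
#' @param period_values covariate values observed during the study period.
#' @param long_term_mean,long_term_sd climatological reference moments;
#'   `long_term_sd` must be positive.
#' @return list: `z` (anomaly in long-term SD units), `period_mean`,
#'   `p_value` (two-sided t-test), `n`.
#' @export
long_term_anomaly <- function(period_values, long_term_mean, long_term_sd) {
  if (!is.finite(long_term_sd) || long_term_sd <= 0) {
    stop("long-term SD must be positive")
  }
  period_values <- period_values[is.finite(period_values)]
  if (length(period_values) < 1) stop("no finite period values")
  pm <- mean(period_values)
  p <- if (length(period_values) >= 2 && sd(period_values) > 0) {
    t.test(period_values, mu = long_term_mean)$p.value
  } else {
    NA_real_
  }
  list(z = (pm - long_term_mean) / long_term_sd,
       period_mean = pm, p_value = p, n = length(period_values))
}
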