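# Raw tri-axial counts -> windowed ODBA -> minute/hour aggregation ->
# activity classification, bout segmentation, deployment-day filtering.

#' Construct a tri-axial accelerometer series
#'
#' @param timestamp POSIXct sample times, strictly increasing.
#' @param ax,ay,az integer acceleration counts per axis.
#' @param counts_per_g counts corresponding to 1 g (default 2^14, the scale
#'   programmed into the study loggers).
#' @param individual_id optional identifier carried through the pipeline.
#' @return a `triaxial_series` tibble with attributes `counts_per_g` and
#'   `individual_id`.
#' @export
triaxial_series <- function(timestamp, ax, ay, az, counts_per_g = 2^14,
                            individual_id = NA_character_) {
  if (!inherits(timestamp, "POSIXct")) stop("timestamp must be POSIXct")
  n <- length(timestamp)
  if (n == 0) stop("empty series")
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  for (v in list(ax, ay, az)) {
    if (length(v) != n) stop("axis lengths must match timestamps")
    if (any(!is.finite(v))) stop("counts must be finite")
  }
  out <- tibble::tibble(timestamp = timestamp,
                        ax = as.numeric(ax), ay = as.numeric(ay),
                        az = as.numeric(az))
  attr(out, "counts_per_g") <- counts_per_g
  attr(out, "individual_id") <- individual_id
  class(out) <- c("triaxial_series", class(out))
  out
}

#' Read a logger CSV into a tri-axial series
#'
#' Columns: `timestamp` (ISO-8601), `ax`, `ay`, `az` (integer counts).
#'
#' @param path CSV path.
#' @inheritParams triaxial_series
#' @return a `triaxial_series`.
#' @export
read_logger_csv <- function(path, counts_per_g = 2^14,
                            individual_id = NA_character_) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  triaxial_series(as.POSIXct(x$timestamp, tz = "UTC"), x$ax, x$ay, x$az,
                  counts_per_g = counts_per_g, individual_id = individual_id)
}

#' Write a tri-axial series to a logger CSV
#' @param series a `triaxial_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    ax = series$ax, ay = series$ay, az = series$az)
  readr::write_csv(out, path)
  invisible(path)
}

#' Window-resolution ODBA from raw counts
#'
#' Tiles non-overlapping windows of `window_s` seconds from the first
#' sample. Within each window the dynamic component of each channel is the
#' difference between the channel mean and its midpoint, divided by
#' `counts_per_g`; ODBA is the L1 norm of the three dynamic components:
#' ODBA = |d_x| + |d_y| + |d_z|.
#'
#' The midpoint is `(max + min) / 2` of the channel within the window
#' (`midpoint = "window"`, the default, which removes the static/gravity
#' component locally). Alternatively a fixed device midpoint per axis can be
#' supplied (`midpoint = "static"` with `static_midpoint`), for loggers
#' whose static reference is calibrated once.
#'
#' A trailing window with fewer samples than the rest is dropped.
#'
#' @param series a [triaxial_series()].
#' @param window_s window length in seconds (default 2).
#' @param midpoint `"window"` or `"static"`.
#' @param static_midpoint numeric length-3 (ax, ay, az) counts, required for
#'   `midpoint = "static"`.
#' @return tibble: `window_start` (POSIXct), `odba` (g units), always >= 0.
#' @export
compute_window_odba <- function(series, window_s = 2,
                                midpoint = c("window", "static"),
                                static_midpoint = NULL) {
  midpoint <- match.arg(midpoint)
  if (window_s <= 0) stop("window length must be positive")
  if (nrow(series) == 0) stop("empty series")
  cpg <- attr(series, "counts_per_g")
  if (is.null(cpg)) cpg <- 2^14
  t0 <- as.numeric(series$timestamp[1])
  idx <- floor((as.numeric(series$timestamp) - t0) / window_s)
  uidx <- sort(unique(idx))
  f <- factor(idx, levels = uidx)

  chan_dyn <- function(x) {
    m <- vapply(split(x, f), mean, numeric(1))
    mid <- if (midpoint == "window") {
      (vapply(split(x, f), max, numeric(1)) +
         vapply(split(x, f), min, numeric(1))) / 2
    } else {
      if (is.null(static_midpoint) || length(static_midpoint) != 3) {
        stop("static midpoint requires a length-3 static_midpoint")
      }
      stop("internal: static handled separately")
    }
    (m - mid) / cpg
  }
  if (midpoint == "static") {
    if (is.null(static_midpoint) || length(static_midpoint) != 3) {
      stop("static midpoint requires a length-3 static_midpoint")
    }
    d <- abs((vapply(split(series$ax, f), mean, numeric(1)) -
                static_midpoint[1]) / cpg) +
      abs((vapply(split(series$ay, f), mean, numeric(1)) -
             static_midpoint[2]) / cpg) +
      abs((vapply(split(series$az, f), mean, numeric(1)) -
             static_midpoint[3]) / cpg)
  } else {
    d <- abs(chan_dyn(series$ax)) + abs(chan_dyn(series$ay)) +
      abs(chan_dyn(series$az))
  }
  n_per <- as.integer(table(f))
  out <- tibble::tibble(
    window_start = as.POSIXct(t0 + uidx * window_s, tz = "UTC",
                              origin = "1970-01-01"),
    odba = as.numeric(d))
  # drop a short trailing window
  if (length(n_per) > 1 && n_per[length(n_per)] < max(n_per)) {
    out <- out[-nrow(out), ]
  }
  out
}

#' Aggregate window ODBA to minute and hour resolution
#'
#' Minute value = arithmetic mean of member windows (the minute-averaged
#' ODBA used for activity thresholding); hourly value = sum of member
#' windows (hourly mechanical energy expenditure). Partial minutes or hours
#' at the series edges are flagged `complete = FALSE` and should be excluded
#' from modeling.
#'
#' @param window_odba tibble from [compute_window_odba()].
#' @param window_s window length used, seconds.
#' @return an `odba_series`: list with tibbles `window`, `minute`
#'   (`minute_start`, `odba`, `n_windows`, `complete`) and `hourly`
#'   (`hour_start`, `odba`, `n_windows`, `complete`).
#' @export
aggregate_odba <- function(window_odba, window_s = 2) {
  if (nrow(window_odba) == 0) stop("empty window series")
  per_min <- 60 / window_s
  per_hour <- 3600 / window_s
  minute <- window_odba |>
    dplyr::group_by(minute_start = trunc_time(.data$window_start, 60)) |>
    dplyr::summarise(odba = mean(.data$odba), n_windows = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(complete = .data$n_windows == per_min)
  hourly <- window_odba |>
    dplyr::group_by(hour_start = trunc_time(.data$window_start, 3600)) |>
    dplyr::summarise(odba = sum(.data$odba), n_windows = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(complete = .data$n_windows == per_hour)
  structure(list(window = window_odba, minute = minute, hourly = hourly,
                 window_s = window_s),
            class = "odba_series")
}

trunc_time <- function(t, unit_s) {
  as.POSIXct(floor(as.numeric(t) / unit_s) * unit_s, tz = "UTC",
             origin = "1970-01-01")
}

#' Build an ODBA series directly from minute-averaged values
#'
#' Convenience constructor for simulated or pre-aggregated data: takes
#' minute-averaged ODBA and reconstructs the implied hourly sums under the
#' uniform tiling of `3600 / window_s` windows per hour (hour sum = sum over
#' member minutes of minute mean x windows per minute).
#'
#' @param minute_start POSIXct minute starts.
#' @param minute_odba minute-averaged ODBA values (g units), non-negative.
#' @param window_s nominal window length, seconds.
#' @return an `odba_series` with `window = NULL`.
#' @export
odba_series_from_minutes <- function(minute_start, minute_odba,
                                     window_s = 2) {
  stopifnot(length(minute_start) == length(minute_odba))
  if (any(minute_odba < 0)) stop("minute ODBA must be non-negative")
  per_min <- 60 / window_s
  minute <- tibble::tibble(minute_start = minute_start, odba = minute_odba,
                           n_windows = per_min, complete = TRUE)
  hourly <- minute |>
    dplyr::group_by(hour_start = trunc_time(.data$minute_start, 3600)) |>
    dplyr::summarise(odba = sum(.data$odba) * per_min,
                     n_windows = dplyr::n() * per_min, .groups = "drop") |>
    dplyr::mutate(complete = .data$n_windows == 3600 / window_s)
  structure(list(window = NULL, minute = minute, hourly = hourly,
                 window_s = window_s),
            class = "odba_series")
}

#' Classify hours as active or inactive
#'
#' An hour is active when strictly more than 30 of its minutes have
#' minute-averaged ODBA strictly above the threshold. Hours with fewer than
#' 60 minutes of data are flagged incomplete and their activity state is set
#' to `NA` (excluded from modeling).
#'
#' @param minute_odba minute tibble (`minute_start`, `odba`) from
#'   [aggregate_odba()] or [odba_series_from_minutes()].
#' @param threshold minute-ODBA activity cut in g units (default 0.28, the
#'   calibrated study value).
#' @return tibble: `hour_start`, `n_minutes`, `active_minutes`, `complete`,
#'   `active` (logical, `NA` when incomplete).
#' @export
classify_hours <- function(minute_odba, threshold = 0.28) {
  if (threshold <= 0) stop("threshold must be positive")
  minute_odba |>
    dplyr::group_by(hour_start = trunc_time(.data$minute_start, 3600)) |>
    dplyr::summarise(n_minutes = dplyr::n(),
                     active_minutes = sum(.data$odba > threshold),
                     .groups = "drop") |>
    dplyr::mutate(complete = .data$n_minutes == 60,
                  active = ifelse(.data$complete,
                                  .data$active_minutes > 30, NA))
}

# Categorize one ordered logical minute-activity vector into
# single_bout / gap_resumed / other.
bout_category_of <- function(active, gap_min = 60) {
  if (!any(active)) return(list(category = "other", n_bouts = 0L))
  r <- rle(active)
  n_bouts <- sum(r$values)
  first_act <- min(which(r$values))
  last_act <- max(which(r$values))
  interior_gaps <- r$lengths[!r$values &
                               seq_along(r$values) > first_act &
                               seq_along(r$values) < last_act]
  category <- if (length(interior_gaps) > 0 &&
                  any(interior_gaps >= gap_min)) {
    "gap_resumed"
  } else if (n_bouts == 1) {
    "single_bout"
  } else {
    "other"
  }
  list(category = category, n_bouts = as.integer(n_bouts))
}

#' Summarise noon-to-noon nights
#'
#' For each night window: total ODBA (sum of hourly ODBA from noon to the
#' next noon), number of active minutes (minute ODBA strictly above the
#' threshold), and a bout category describing how activity was organised:
#' \describe{
#'   \item{`single_bout`}{all activity in one non-stop contiguous run.}
#'   \item{`gap_resumed`}{activity, then at least `gap_min` consecutive
#'     inactive minutes, then renewed activity (an intra-night rest of an
#'     hour or more).}
#'   \item{`other`}{no activity at all, or several runs separated only by
#'     gaps shorter than `gap_min`.}
#' }
#'
#' @param odba an `odba_series` (from [aggregate_odba()] or
#'   [odba_series_from_minutes()]). A column `individual_id` may be present
#'   in its `minute`/`hourly` tibbles; otherwise the series-level id is
#'   used.
#' @param nights night-window tibble from [night_windows()] (only `night_id`,
#'   `start`, `end` are used).
#' @param threshold minute-ODBA activity cut (g units).
#' @param gap_min inactive-gap length (minutes) defining a broken night.
#' @return tibble of night records: `night_id`, `total_odba`,
#'   `active_minutes`, `n_minutes`, `incomplete`, `bout_category`,
#'   `n_bouts`.
#' @export
nightly_summary <- function(odba, nights, threshold = 0.28, gap_min = 60) {
  if (threshold <= 0) stop("threshold must be positive")
  minute <- dplyr::arrange(odba$minute, .data$minute_start)
  hourly <- odba$hourly
  rows <- lapply(seq_len(nrow(nights)), function(i) {
    w <- nights[i, ]
    msub <- minute[minute$minute_start >= w$start &
                     minute$minute_start < w$end, ]
    hsub <- hourly[hourly$hour_start >= w$start & hourly$hour_start < w$end, ]
    act <- msub$odba > threshold
    bc <- bout_category_of(act, gap_min = gap_min)
    tibble::tibble(night_id = w$night_id,
                   total_odba = sum(hsub$odba),
                   active_minutes = sum(act),
                   n_minutes = nrow(msub),
                   incomplete = nrow(msub) < 1440,
                   bout_category = bc$category,
                   n_bouts = bc$n_bouts)
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity scan for the activity threshold
#'
#' Evaluates candidate minute-ODBA cuts by the between-class variance of the
#' induced two-class split of log2 minute ODBA (an Otsu-style criterion):
#' the recommended threshold maximises the separation between the putative
#' inactive and active classes. Total active minutes and the number of
#' activity bouts per candidate are tabulated so the scan can be inspected
#' and overridden.
#'
#' Zero minute values are floored at half the smallest positive value before
#' the log transform (the statistic only orders class means, so the floor
#' choice is immaterial to the recommendation for well-separated classes).
#'
#' @param minute_odba numeric vector of minute-averaged ODBA in time order.
#' @param candidates numeric vector (length >= 2) of candidate thresholds.
#' @return list: `scan` (tibble: threshold, active_minutes, n_bouts,
#'   between_var), `recommended` (numeric, `NA` for a degenerate constant
#'   series), `degenerate` flag.
#' @export
threshold_sensitivity <- function(minute_odba, candidates) {
  if (length(candidates) < 2) stop("need at least 2 candidate thresholds")
  candidates <- sort(candidates)
  degenerate <- length(unique(minute_odba)) < 2
  pos <- minute_odba[minute_odba > 0]
  floor_val <- if (length(pos) > 0) min(pos) / 2 else 1e-6
  y <- log2(pmax(minute_odba, floor_val))
  scan <- lapply(candidates, function(th) {
    act <- minute_odba > th
    n_bouts <- sum(rle(act)$values)
    bv <- if (any(act) && any(!act)) {
      w1 <- mean(act)
      w0 <- 1 - w1
      w0 * w1 * (mean(y[act]) - mean(y[!act]))^2
    } else {
      NA_real_
    }
    tibble::tibble(threshold = th, active_minutes = sum(act),
                   n_bouts = n_bouts, between_var = bv)
  })
  scan <- dplyr::bind_rows(scan)
  recommended <- if (degenerate || all(is.na(scan$between_var))) {
    NA_real_
  } else {
    scan$threshold[which.max(scan$between_var)]
  }
  list(scan = scan, recommended = recommended, degenerate = degenerate)
}

# Noon-to-noon night id of a timestamp: night d spans [d 12:00, d+1 12:00).
night_id_of <- function(timestamp) {
  as.Date(as.POSIXct(as.numeric(timestamp) - 12 * 3600, tz = "UTC",
                     origin = "1970-01-01"))
}

#' Drop first and last deployment days
#'
#' Activity is depressed on the release day and the final day of a
#' deployment is truncated by recapture, so both are removed: of the
#' noon-to-noon analysis days overlapping the deployment, the first and the
#' last are excluded and all records falling on them dropped.
#'
#' @param x data frame with a POSIXct time column.
#' @param deployment_start,deployment_end POSIXct deployment bounds.
#' @param time_col name of the time column (default "timestamp").
#' @return `x` restricted to retained analysis days, with attribute
#'   `retained_nights` (Date vector). Deployments spanning two or fewer
#'   noon-to-noon days yield an empty result with a warning.
#' @export
filter_deployment_days <- function(x, deployment_start, deployment_end,
                                   time_col = "timestamp") {
  if (!time_col %in% names(x)) stop("no column '", time_col, "' in x")
  if (deployment_end <= deployment_start) stop("empty deployment window")
  nights <- seq(night_id_of(deployment_start), night_id_of(deployment_end),
                by = "day")
  retained <- if (length(nights) <= 2) {
    as.Date(character(0))
  } else {
    nights[-c(1, length(nights))]
  }
  if (length(retained) == 0) {
    warning("deployment spans <= 2 analysis days; no data retained")
  }
  out <- x[night_id_of(x[[time_col]]) %in% retained, , drop = FALSE]
  attr(out, "retained_nights") <- retained
  out
}
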