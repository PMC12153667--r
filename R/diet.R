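# Fecal diet tabulation: chaetae counts as an earthworm-consumption index,
# and monthly frequency of occurrence of diet items.

#' Chaetae index of one fecal sample
#'
#' Arithmetic mean of the chaetae counted in the 10 one-square-centimetre
#' Petri-dish squares scored for the sample.
#'
#' @param counts integer vector of exactly 10 non-negative square counts.
#' @return mean count.
#' @export
chaetae_index <- function(counts) {
  if (length(counts) != 10) stop("exactly 10 square counts required")
  if (any(counts < 0)) stop("counts must be non-negative")
  mean(counts)
}

#' Monthly frequency of occurrence of diet items
#'
#' For each month: FO = samples containing the item / samples in the month;
#' RFO = occurrences of the item / total item occurrences in the month
#' (sums to 1 within a month whenever any occurrences exist).
#'
#' @param samples tibble: `sample_id`, `date` (Date), `item` — one row per
#'   (sample, diet item present). Samples with no items may appear with
#'   `item = NA`; they count toward the month's sample total only.
#' @return tibble: `month` (first day of month), `item`, `n_samples`,
#'   `occurrences`, `fo`, `rfo`.
#' @export
monthly_fo_rfo <- function(samples) {
  stopifnot(all(c("sample_id", "date", "item") %in% names(samples)))
  if (nrow(samples) == 0) stop("no samples")
  samples$month <- as.Date(format(as.Date(samples$date), "%Y-%m-01"))
  out <- list()
  for (m in sort(unique(samples$month))) {
    sub <- samples[samples$month == m, ]
    n_samples <- length(unique(sub$sample_id))
    occ <- sub[!is.na(sub$item), ]
    occ <- unique(occ[, c("sample_id", "item")]) # presence, not multiplicity
    total_occ <- nrow(occ)
    if (total_occ == 0) next
    per_item <- table(occ$item)
    out[[length(out) + 1]] <- tibble::tibble(
      month = as.Date(m, origin = "1970-01-01"),
      item = names(per_item),
      n_samples = n_samples,
      occurrences = as.integer(per_item),
      fo = as.integer(per_item) / n_samples,
      rfo = as.integer(per_item) / total_occ)
  }
  dplyr::bind_rows(out)
}

#' Read a fecal diet sample CSV
#'
#' Long format: `sample_id`, `date`, `item` (one row per item present;
#' `item` empty for itemless samples), plus optional `sq1`..`sq10` chaetae
#' square counts.
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_diet_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x$date <- as.Date(x$date)
  tibble::as_tibble(x)
}
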