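#' Night-level wear validity
#'
#' A valid night has at least `min_worn_min` minutes (default 360, i.e. 6 h)
#' of worn epochs inside the night window running from 22:00 of `night_date`
#' to 06:59 of the next day. Worn means present in the recording and neither
#' `NONWEAR` nor `EXCLUDED`; the worn minutes need not be contiguous. Epochs
#' not covered by the recording count as not worn.
#'
#' @param series An [epoch_series()] with 60-s epochs.
#' @param labels Aligned label vector (typically from [detect_nonwear()],
#'   possibly after [truncate_after_nonwear()]).
#' @param night_date A `Date` (or string): the calendar date whose 22:00
#'   starts the night.
#' @param min_worn_min Minimum worn minutes for validity (default 360).
#' @return `TRUE`/`FALSE`.
#' @export
is_valid_night <- function(series, labels, night_date, min_worn_min = 360) {
  stopifnot(inherits(series, "epoch_series"))
  check_labels(labels, series)
  night_date <- as.Date(night_date)
  win_start <- as.POSIXct(paste(night_date, "22:00:00"), tz = "UTC")
  win_end <- win_start + 9 * 3600  # exclusive: epochs starting before 07:00
  tt <- epoch_times(series)
  inside <- tt >= win_start & tt < win_end
  worn <- inside & !(labels %in% c("NONWEAR", "EXCLUDED"))
  sum(worn) * series$epoch_length / 60 >= min_worn_min
}

#' Exclude data after a prolonged non-wear run
#'
#' Marks every epoch after the first maximal `NONWEAR` run lasting at least
#' `limit_h` hours (inclusive; default 48) as `EXCLUDED`. Epochs inside the
#' run keep their `NONWEAR` state.
#'
#' @inheritParams is_valid_night
#' @param limit_h Non-wear duration, in hours, that triggers discarding of
#'   all subsequent data.
#' @return The label vector with post-run epochs set to `"EXCLUDED"`, and an
#'   attribute `truncated_at` giving the 1-based index of the first excluded
#'   epoch (`NA` if nothing was excluded).
#' @export
truncate_after_nonwear <- function(series, labels, limit_h = 48) {
  stopifnot(inherits(series, "epoch_series"))
  check_labels(labels, series)
  limit_epochs <- limit_h * 3600 / series$epoch_length
  r <- rle(labels == "NONWEAR")
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= limit_epochs)
  truncated_at <- NA_integer_
  if (length(hit) > 0) {
    first_after <- ends[hit[1]] + 1L
    if (first_after <= length(labels)) {
      labels[first_after:length(labels)] <- "EXCLUDED"
      truncated_at <- first_after
    }
  }
  attr(labels, "truncated_at") <- truncated_at
  labels
}

#' Recording-level validity report
#'
#' Applies the study selection rules to one recording: data after a 48-h
#' non-wear run are excluded, every calendar night covered by the recording
#' is tested with [is_valid_night()], and the recording is valid when it has
#' at least 3 valid nights of which at least 2 are weeknights and at least 1
#' is a weekend night. Weekend nights are those starting on Friday or
#' Saturday at 22:00.
#'
#' @inheritParams truncate_after_nonwear
#' @return A list of class `validity_report` with fields `valid_nights`,
#'   `weeknights`, `weekend_nights`, `truncated_at` (1-based index or `NA`),
#'   `is_valid`, and `night_dates` (the valid nights' start dates).
#' @export
validate_recording <- function(series, labels, limit_h = 48) {
  stopifnot(inherits(series, "epoch_series"))
  check_labels(labels, series)
  labels <- truncate_after_nonwear(series, labels, limit_h = limit_h)
  tt <- epoch_times(series)
  first_date <- as.Date(tt[1], tz = "UTC")
  last_date <- as.Date(tt[length(tt)], tz = "UTC")
  # a night starting the evening before the first epoch can still cover it
  nights <- seq(first_date - 1, last_date, by = "day")
  valid <- vapply(nights, function(d) is_valid_night(series, labels, d),
                  logical(1))
  night_dates <- nights[valid]
  # %u: ISO weekday 1 (Mon) .. 7 (Sun); weekend nights start Fri (5) or Sat (6)
  wd <- as.integer(format(night_dates, "%u"))
  weekend <- sum(wd %in% c(5L, 6L))
  weeknight <- length(night_dates) - weekend
  structure(
    list(valid_nights = length(night_dates),
         weeknights = weeknight,
         weekend_nights = weekend,
         truncated_at = attr(labels, "truncated_at"),
         is_valid = length(night_dates) >= 3 && weeknight >= 2 && weekend >= 1,
         night_dates = night_dates),
    class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "<validity_report> %d valid night(s): %d weeknight(s), %d weekend night(s)%s -> %s\n",
    x$valid_nights, x$weeknights, x$weekend_nights,
    if (!is.na(x$truncated_at)) sprintf("; truncated at epoch %d", x$truncated_at) else "",
    if (x$is_valid) "VALID" else "INVALID"))
  invisible(x)
}
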