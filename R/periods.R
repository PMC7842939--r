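#' Classify labeled output into naps, bedrest periods and awakenings
#'
#' Applies the duration rules used for reporting: bedrest episodes shorter
#' than 30 min are relabeled wake; episodes of 30-90 min are naps; episodes
#' longer than 90 min are bedrest periods. Wake gaps of 5-15 min lying
#' between bedrest episodes are awakenings when the enclosing merged span
#' (flanking bedrest plus the gaps) exceeds 90 min; at the epoch level the
#' gap epochs stay wake, and at the period level the flanking bedrest spans
#' are reported as a single bedrest period.
#'
#' @param labels Per-epoch label vector from any detector.
#' @param epoch_length Epoch duration in seconds (default 60).
#' @param min_bedrest_min Bedrest episodes below this are relabeled wake
#'   (default 30).
#' @param nap_range_min Two-element inclusive range of nap durations in
#'   minutes (default `c(30, 90)`).
#' @param awakening_range_min Two-element inclusive range of awakening
#'   durations in minutes (default `c(5, 15)`).
#' @param long_bedrest_min Merged spans longer than this many minutes are
#'   bedrest periods (default 90).
#' @return A list of class `period_classification`:
#' * `labels` — epoch labels after the short-bedrest demotion (awakening
#'   epochs stay `WAKE`);
#' * `periods` — tibble with `tag` (`WAKE`, `NAP`, `BEDREST_PERIOD`,
#'   `NONWEAR`, `EXCLUDED`), `start_index`, `end_index` (1-based inclusive,
#'   spanning internal awakenings for merged bedrest periods),
#'   `duration_min` (bedrest minutes only, for bedrest tags), and
#'   `n_awakenings`, `awakening_min` inside each period;
#' * `awakenings` — tibble of the awakening gaps with the row number of
#'   their enclosing period (`period`).
#'
#' The nap plus bedrest-period minutes always equal the number of `BEDREST`
#' epochs remaining after demotion.
#' @export
classify_periods <- function(labels, epoch_length = 60,
                             min_bedrest_min = 30,
                             nap_range_min = c(30, 90),
                             awakening_range_min = c(5, 15),
                             long_bedrest_min = 90) {
  check_labels(labels)
  epm <- epoch_length / 60  # minutes per epoch
  # demote short bedrest to wake at the epoch level
  r <- rle(labels)
  r$values[r$values == "BEDREST" & r$lengths * epm < min_bedrest_min] <- "WAKE"
  labels <- inverse.rle(r)

  ep <- labels_to_episodes(labels, epoch_length)
  k <- nrow(ep)
  tags <- character(0)
  rows <- list()
  awk <- list()
  is_gap <- function(i) {
    ep$state[i] == "WAKE" &&
      ep$duration_min[i] >= awakening_range_min[1] &&
      ep$duration_min[i] <= awakening_range_min[2]
  }
  i <- 1L
  while (i <= k) {
    st <- ep$state[i]
    if (st != "BEDREST") {
      rows[[length(rows) + 1L]] <- list(tag = st, start = ep$start_index[i],
                                        end = ep$end_index[i],
                                        dur = ep$duration_min[i],
                                        n_awk = 0L, awk_min = 0)
      i <- i + 1L
      next
    }
    # chain bedrest episodes linked by candidate awakening gaps
    members <- i
    j <- i
    while (j + 2L <= k && is_gap(j + 1L) && ep$state[j + 2L] == "BEDREST") {
      members <- c(members, j + 2L)
      j <- j + 2L
    }
    span_start <- ep$start_index[members[1]]
    span_end <- ep$end_index[members[length(members)]]
    span_min <- (span_end - span_start + 1L) * epm
    bed_min <- sum(ep$duration_min[members])
    gaps <- if (length(members) > 1) members[-length(members)] + 1L else integer(0)
    if (span_min > long_bedrest_min) {
      # one bedrest period; internal gaps are awakenings
      rows[[length(rows) + 1L]] <- list(tag = "BEDREST_PERIOD",
                                        start = span_start, end = span_end,
                                        dur = bed_min,
                                        n_awk = length(gaps),
                                        awk_min = sum(ep$duration_min[gaps]))
      for (g in gaps) {
        awk[[length(awk) + 1L]] <- list(start = ep$start_index[g],
                                        end = ep$end_index[g],
                                        dur = ep$duration_min[g],
                                        period = length(rows))
      }
      i <- j + 1L
    } else {
      # short merged span: classify this episode alone; gaps stay wake
      tag <- if (ep$duration_min[i] >= nap_range_min[1] &&
                 ep$duration_min[i] <= nap_range_min[2]) "NAP"
             else "BEDREST_PERIOD"
      rows[[length(rows) + 1L]] <- list(tag = tag, start = ep$start_index[i],
                                        end = ep$end_index[i],
                                        dur = ep$duration_min[i],
                                        n_awk = 0L, awk_min = 0)
      i <- i + 1L
    }
  }
  periods <- tibble::tibble(
    tag = vapply(rows, `[[`, character(1), "tag"),
    start_index = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end_index = vapply(rows, function(r) as.integer(r$end), integer(1)),
    duration_min = vapply(rows, function(r) as.numeric(r$dur), numeric(1)),
    n_awakenings = vapply(rows, function(r) as.integer(r$n_awk), integer(1)),
    awakening_min = vapply(rows, function(r) as.numeric(r$awk_min), numeric(1)))
  awakenings <- if (length(awk) > 0) {
    tibble::tibble(
      start_index = vapply(awk, function(r) as.integer(r$start), integer(1)),
      end_index = vapply(awk, function(r) as.integer(r$end), integer(1)),
      duration_min = vapply(awk, function(r) as.numeric(r$dur), numeric(1)),
      period = vapply(awk, function(r) as.integer(r$period), integer(1)))
  } else {
    tibble::tibble(start_index = integer(), end_index = integer(),
                   duration_min = numeric(), period = integer())
  }
  structure(list(labels = labels, periods = periods, awakenings = awakenings),
            class = "period_classification")
}

#' @export
print.period_classification <- function(x, ...) {
  tab <- table(x$periods$tag)
  cat(sprintf("<period_classification> %s; %d awakening(s)\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$awakenings)))
  invisible(x)
}

#' Per-day summary of bedrest, naps and awakenings
#'
#' Computes, for each calendar day the recording covers, worn minutes in
#' bedrest and wake (non-wear and excluded epochs contribute to neither) and
#' the number and total duration of naps and awakenings. Minutes of a period
#' crossing midnight accrue to each day it covers; a nap or awakening is
#' counted on the day it starts. Overall means across days are attached.
#'
#' @param labels Per-epoch label vector (from any detector; the short-bedrest
#'   demotion of [classify_periods()] is applied internally).
#' @param series The aligned [epoch_series()].
#' @param ... Passed on to [classify_periods()].
#' @return A list of class `daily_summary` with `days` (a tibble with one
#'   row per calendar day: `date`, `bedrest_min`, `wake_min`, `nonwear_min`,
#'   `nap_count`, `nap_min`, `awakening_count`, `awakening_min`) and `means`
#'   (named numeric vector of across-day means of those columns).
#' @export
summarize_days <- function(labels, series, ...) {
  stopifnot(inherits(series, "epoch_series"))
  check_labels(labels, series)
  cls <- classify_periods(labels, epoch_length = series$epoch_length, ...)
  labels <- cls$labels
  epm <- series$epoch_length / 60
  dates <- as.Date(epoch_times(series), tz = "UTC")
  all_days <- seq(min(dates), max(dates), by = "day")
  count_min <- function(state) {
    vapply(all_days, function(d) sum(labels == state & dates == d) * epm,
           numeric(1))
  }
  naps <- cls$periods[cls$periods$tag == "NAP", ]
  nap_day <- dates[naps$start_index]
  awk_day <- dates[cls$awakenings$start_index]
  days <- tibble::tibble(
    date = all_days,
    bedrest_min = count_min("BEDREST"),
    wake_min = count_min("WAKE"),
    nonwear_min = vapply(all_days, function(d)
      sum(labels %in% c("NONWEAR", "EXCLUDED") & dates == d) * epm, numeric(1)),
    nap_count = vapply(all_days, function(d) sum(nap_day == d), numeric(1)),
    nap_min = vapply(all_days, function(d)
      sum(naps$duration_min[nap_day == d]), numeric(1)),
    awakening_count = vapply(all_days, function(d) sum(awk_day == d), numeric(1)),
    awakening_min = vapply(all_days, function(d)
      sum(cls$awakenings$duration_min[awk_day == d]), numeric(1)))
  means <- colMeans(days[, -1])
  structure(list(days = days, means = means), class = "daily_summary")
}

#' @export
print.daily_summary <- function(x, ...) {
  cat(sprintf("<daily_summary> %d day(s); mean bedrest %.0f min/day, mean wake %.0f min/day\n",
              nrow(x$days), x$means[["bedrest_min"]], x$means[["wake_min"]]))
  invisible(x)
}
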