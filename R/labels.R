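#' Per-epoch label states
#'
#' Label sequences are plain character vectors aligned 1:1 with an
#' [epoch_series()]. The recognised states are `"BEDREST"`, `"WAKE"`,
#' `"NONWEAR"` (device off-body) and `"EXCLUDED"` (discarded by quality
#' control). The Sadeh scorer reports sleep epochs as `"BEDREST"` so that all
#' detectors share one label vocabulary.
#'
#' @format Character vector of the four state names.
#' @export
label_states <- c("BEDREST", "WAKE", "NONWEAR", "EXCLUDED")

check_labels <- function(labels, series = NULL, arg = "labels") {
  if (!is.character(labels) || !all(labels %in% label_states)) {
    stop(sprintf("`%s` must be a character vector of states in {%s}",
                 arg, paste(label_states, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(series) && length(labels) != length(series)) {
    stop(sprintf("`%s` (length %d) is not aligned to the series (length %d)",
                 arg, length(labels), length(series)), call. = FALSE)
  }
  invisible(labels)
}

#' Maximal same-state episodes of a label sequence
#'
#' Collapses a per-epoch label sequence into its maximal runs. Episodes are
#' reported with 1-based inclusive epoch indices; together they tile the
#' sequence without overlap.
#'
#' @param labels Character vector of states (see [label_states]).
#' @param epoch_length Epoch duration in seconds (default 60).
#' @return A tibble with columns `state`, `start_index`, `end_index`
#'   (1-based, inclusive) and `duration_min`.
#' @export
#' @examples
#' labels_to_episodes(c("WAKE", "BEDREST", "BEDREST", "WAKE"))
labels_to_episodes <- function(labels, epoch_length = 60) {
  check_labels(labels)
  if (length(labels) == 0L) {
    return(tibble::tibble(state = character(), start_index = integer(),
                          end_index = integer(), duration_min = numeric()))
  }
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  tibble::tibble(state = r$values,
                 start_index = as.integer(start),
                 end_index = as.integer(end),
                 duration_min = r$lengths * epoch_length / 60)
}

#' Episode table with calendar timestamps
#'
#' Attaches start/end clock times from a series to the episodes of an aligned
#' label sequence. `end_time` is the end of the last epoch of the episode
#' (exclusive instant).
#'
#' @inheritParams labels_to_episodes
#' @param series The aligned [epoch_series()].
#' @return A tibble with columns `state`, `start_time`, `end_time`,
#'   `duration_min`.
#' @export
episode_table <- function(labels, series) {
  check_labels(labels, series)
  ep <- labels_to_episodes(labels, series$epoch_length)
  times <- epoch_times(series)
  tibble::tibble(state = ep$state,
                 start_time = times[ep$start_index],
                 end_time = times[ep$end_index] + series$epoch_length,
                 duration_min = ep$duration_min)
}
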