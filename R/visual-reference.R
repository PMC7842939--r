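#' Heuristic reference-scorer parameters
#'
#' Parameters of the automated version of the raters' visual-scoring rules.
#' A bedrest-start is the first minute of `start_run_min` consecutive minutes
#' at or below `low_threshold` counts/min whose following `start_confirm_min`
#' minutes contain at most `start_confirm_exceptions` minutes above the
#' threshold. A bedrest-end is the minute preceding the first minute at or
#' above `high_threshold` that is followed by at least `end_confirm_hits` of
#' the next `end_confirm_window` minutes at or above `high_threshold`.
#' Episodes shorter than the minima are merged into their neighbours.
#'
#' @param low_threshold Counts/min at or below which a minute is "low"
#'   (default 100).
#' @param start_run_min Consecutive low minutes that open a candidate
#'   bedrest-start (default 10).
#' @param start_confirm_min Length of the confirmation window after the run
#'   (default 20).
#' @param start_confirm_exceptions Minutes above `low_threshold` tolerated in
#'   the confirmation window (default 2).
#' @param high_threshold Counts/min at or above which a minute is "high"
#'   (default 500).
#' @param end_confirm_window,end_confirm_hits The end rule: at least
#'   `end_confirm_hits` of the `end_confirm_window` minutes after the trigger
#'   minute must be high (defaults 5 of 9).
#' @param min_bedrest_episode_min Smallest bedrest episode kept (default 30).
#' @param min_wake_episode_min Smallest wake episode kept between bedrest
#'   episodes (default 10).
#' @return A list of class `heuristic_params`.
#' @export
heuristic_params <- function(low_threshold = 100, start_run_min = 10,
                             start_confirm_min = 20,
                             start_confirm_exceptions = 2,
                             high_threshold = 500, end_confirm_window = 9,
                             end_confirm_hits = 5,
                             min_bedrest_episode_min = 30,
                             min_wake_episode_min = 10) {
  stopifnot(low_threshold >= 0, start_run_min > 0, start_confirm_min > 0,
            start_confirm_exceptions >= 0, high_threshold > 0,
            end_confirm_window > 0, end_confirm_hits > 0,
            end_confirm_hits <= end_confirm_window,
            min_bedrest_episode_min > 0, min_wake_episode_min > 0)
  structure(list(low_threshold = low_threshold, start_run_min = start_run_min,
                 start_confirm_min = start_confirm_min,
                 start_confirm_exceptions = start_confirm_exceptions,
                 high_threshold = high_threshold,
                 end_confirm_window = end_confirm_window,
                 end_confirm_hits = end_confirm_hits,
                 min_bedrest_episode_min = min_bedrest_episode_min,
                 min_wake_episode_min = min_wake_episode_min),
            class = "heuristic_params")
}

#' Automated visual-reference scoring
#'
#' Applies the raters' heuristic rules to a 60-s vector-magnitude series,
#' producing the reference `BEDREST`/`WAKE` labels the decision tree is
#' optimised and tested against. Boundaries are found by a forward scan that
#' alternates bedrest-start and bedrest-end searches (rules in
#' [heuristic_params()]); epochs before the first boundary and after the
#' last take the state the adjacent boundary implies. Finally the episode
#' minima are enforced, in this order: wake runs shorter than
#' `min_wake_episode_min` lying strictly between two bedrest episodes are
#' absorbed into bedrest, then bedrest runs shorter than
#' `min_bedrest_episode_min` are demoted to wake. When a confirmation window
#' extends past the end of the data, the rule is applied to the minutes that
#' exist.
#'
#' Pre-flagged `NONWEAR`/`EXCLUDED` epochs (passed via `labels`) are skipped:
#' each maximal worn segment is scored independently and the flags are
#' preserved in the output.
#'
#' @param series An [epoch_series()] with 60-s epochs.
#' @param params A [heuristic_params()].
#' @param labels Optional pre-existing labels carrying `NONWEAR`/`EXCLUDED`
#'   flags; default none.
#' @return Character label vector aligned to `series`.
#' @export
score_reference <- function(series, params = heuristic_params(),
                            labels = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_length != 60L) {
    stop("reference scoring requires 60-s epochs; re-integrate the series first",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("WAKE", length(series))
  check_labels(labels, series)
  out <- labels
  worn <- !(labels %in% c("NONWEAR", "EXCLUDED"))
  for (seg in worn_segments(worn)) {
    out[seg] <- score_reference_segment(series$vm[seg], params)
  }
  out
}

# maximal runs of worn epochs, as a list of index vectors
worn_segments <- function(worn) {
  if (!any(worn)) return(list())
  r <- rle(worn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) starts[i]:ends[i])
}

score_reference_segment <- function(x, params) {
  n <- length(x)
  if (n < params$start_run_min + params$start_confirm_min) {
    warning(sprintf(
      "segment of %d epochs is shorter than start-run + confirmation window (%d); labeling all WAKE",
      n, params$start_run_min + params$start_confirm_min), call. = FALSE)
    return(rep("WAKE", n))
  }
  low <- x <= params$low_threshold
  high <- x >= params$high_threshold
  states <- rep("WAKE", n)
  pos <- 1L
  in_bedrest <- FALSE
  repeat {
    if (!in_bedrest) {
      s <- find_heuristic_start(low, pos, params)
      if (is.na(s)) break                     # no further bedrest: rest stays WAKE
      pos <- s
      in_bedrest <- TRUE
    } else {
      e <- find_heuristic_end(high, pos + 1L, params)
      if (is.na(e)) {                          # bedrest runs to the end
        states[pos:n] <- "BEDREST"
        pos <- n + 1L
        break
      }
      states[pos:e] <- "BEDREST"
      pos <- e + 1L
      in_bedrest <- FALSE
    }
    if (pos > n) break
  }
  enforce_episode_minima(states,
                         min_bedrest = params$min_bedrest_episode_min,
                         min_wake = params$min_wake_episode_min)
}

# first candidate start at or after `pos`: start_run_min consecutive low
# minutes, then a confirmation window with at most the allowed exceptions
find_heuristic_start <- function(low, pos, params) {
  n <- length(low)
  run <- params$start_run_min
  i <- pos
  while (i + run - 1L <= n) {
    if (all(low[i:(i + run - 1L)])) {
      cfrom <- i + run
      cto <- min(n, i + run + params$start_confirm_min - 1L)
      exceptions <- if (cfrom <= cto) sum(!low[cfrom:cto]) else 0L
      if (exceptions <= params$start_confirm_exceptions) return(i)
    }
    i <- i + 1L
  }
  NA_integer_
}

# first trigger minute at or after `pos` that satisfies the end rule; the
# bedrest-end is the minute before it
find_heuristic_end <- function(high, pos, params) {
  n <- length(high)
  m <- pos
  while (m <= n) {
    if (high[m]) {
      cfrom <- m + 1L
      cto <- min(n, m + params$end_confirm_window)
      hits <- if (cfrom <= cto) sum(high[cfrom:cto]) else 0L
      if (hits >= params$end_confirm_hits) return(m - 1L)
    }
    m <- m + 1L
  }
  NA_integer_
}

# order matters and is part of the documented contract: short wake inside
# bedrest is absorbed first, then short bedrest is demoted
enforce_episode_minima <- function(states, min_bedrest, min_wake) {
  r <- rle(states)
  k <- length(r$lengths)
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (r$values[i] == "WAKE" && r$lengths[i] < min_wake &&
          r$values[i - 1] == "BEDREST" && r$values[i + 1] == "BEDREST") {
        r$values[i] <- "BEDREST"
      }
    }
  }
  states <- inverse.rle(r)
  r <- rle(states)
  r$values[r$values == "BEDREST" & r$lengths < min_bedrest] <- "WAKE"
  inverse.rle(r)
}

#' Merge two raters' label sequences
#'
#' Resolves per-epoch disagreements between two raters restricted to
#' `BEDREST`/`WAKE`: under `"True1"` a disputed epoch is assumed truly wake,
#' under `"True2"` truly bedrest. Agreeing epochs keep the agreed state.
#' Epochs flagged `NONWEAR`/`EXCLUDED` by either rater keep that flag.
#'
#' @param a,b Equal-length label vectors.
#' @param mode `"True1"` (disagreement is wake) or `"True2"` (disagreement is
#'   bedrest).
#' @return Merged label vector. The `True2` bedrest set always contains the
#'   `True1` bedrest set.
#' @export
merge_raters <- function(a, b, mode = c("True1", "True2")) {
  mode <- match.arg(mode)
  check_labels(a, arg = "a")
  check_labels(b, arg = "b")
  if (length(a) != length(b)) {
    stop(sprintf("rater sequences differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  }
  out <- a
  a_worn <- !(a %in% c("NONWEAR", "EXCLUDED"))
  b_worn <- !(b %in% c("NONWEAR", "EXCLUDED"))
  out[!b_worn & a_worn] <- b[!b_worn & a_worn]
  both <- a_worn & b_worn
  disputed <- both & a != b
  out[disputed] <- if (mode == "True1") "WAKE" else "BEDREST"
  out
}
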