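#' Sadeh scoring parameters
#'
#' Configuration of the Sadeh sleep/wake scoring function used as the
#' head-to-head comparator. Counts are capped at `count_cap` before scoring.
#' For each epoch the linear statistic
#'
#' `PS = c0 + c_avg * AVG + c_nat * NAT + c_sd * SD + c_lg * LG`
#'
#' is evaluated, where `AVG` is the mean capped count over the centred
#' window of `2 * window_half_width + 1` epochs, `NAT` the number of epochs
#' in that window with counts in `[nat_low, nat_high)`, `SD` the standard
#' deviation of the current and five preceding epochs, and `LG` the natural
#' log of the current count plus one. `PS >= 0` scores the epoch as sleep.
#' The shipped coefficients are the published Sadeh et al. values as used in
#' common actigraphy software (7.601, -0.065, -1.08, -0.056, -0.703);
#' alternative published variants can be configured here.
#'
#' @param window_half_width Epochs on each side of the centred window
#'   (default 5, an 11-epoch window).
#' @param count_cap Counts are truncated at this value before scoring
#'   (default 300).
#' @param nat_low,nat_high Half-open count band of the NAT term (defaults
#'   50, 100).
#' @param coefficients Named numeric vector with elements `intercept`,
#'   `avg`, `nat`, `sd`, `lg`.
#' @param edge `"truncate"` (default) evaluates edge epochs over the window
#'   minutes that exist; `"zero_pad"` pads the series with zero-count epochs
#'   instead.
#' @return A list of class `sadeh_params`.
#' @export
sadeh_params <- function(window_half_width = 5L, count_cap = 300,
                         nat_low = 50, nat_high = 100,
                         coefficients = c(intercept = 7.601, avg = -0.065,
                                          nat = -1.08, sd = -0.056,
                                          lg = -0.703),
                         edge = c("truncate", "zero_pad")) {
  edge <- match.arg(edge)
  stopifnot(window_half_width >= 1, count_cap > 0, nat_low < nat_high,
            all(c("intercept", "avg", "nat", "sd", "lg") %in% names(coefficients)))
  structure(list(window_half_width = as.integer(window_half_width),
                 count_cap = count_cap, nat_low = nat_low,
                 nat_high = nat_high, coefficients = coefficients,
                 edge = edge),
            class = "sadeh_params")
}

#' Sadeh epoch-by-epoch sleep scoring
#'
#' Scores each 60-s epoch as sleep or wake from single-axis (vertical)
#' counts by default, the axis the algorithm was developed on; a
#' vector-magnitude mode exists for exploratory comparisons only. Sleep
#' epochs are labeled `"BEDREST"` so the output shares the package label
#' vocabulary ([label_states]) and can be compared directly with the
#' decision tree; pre-flagged `NONWEAR`/`EXCLUDED` epochs are preserved.
#'
#' @param series An [epoch_series()] with 60-s epochs.
#' @param params A [sadeh_params()].
#' @param labels Optional pre-existing labels carrying `NONWEAR`/`EXCLUDED`
#'   flags.
#' @param signal `"axis1"` (vertical, default) or `"vm"`.
#' @return Character label vector aligned to `series`.
#' @export
sadeh_score <- function(series, params = sadeh_params(), labels = NULL,
                        signal = c("axis1", "vm")) {
  stopifnot(inherits(series, "epoch_series"))
  signal <- match.arg(signal)
  if (series$epoch_length != 60L) {
    stop("Sadeh scoring requires 60-s epochs; re-integrate the series first",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("WAKE", length(series))
  check_labels(labels, series)
  x_all <- if (signal == "axis1") as.numeric(series$axis1) else series$vm
  out <- labels
  worn <- !(labels %in% c("NONWEAR", "EXCLUDED"))
  for (seg in worn_segments(worn)) {
    out[seg] <- sadeh_score_segment(x_all[seg], params)
  }
  out
}

sadeh_score_segment <- function(x, params) {
  n <- length(x)
  if (n == 0L) return(character(0))
  h <- params$window_half_width
  capped <- pmin(x, params$count_cap)
  pad <- params$edge == "zero_pad"
  if (pad) {
    capped_w <- c(numeric(h), capped, numeric(h))
    offset <- h
  } else {
    capped_w <- capped
    offset <- 0L
  }
  nat_flag <- capped_w >= params$nat_low & capped_w < params$nat_high
  co <- params$coefficients
  ps <- numeric(n)
  for (i in seq_len(n)) {
    ctr <- i + offset
    lo <- if (pad) ctr - h else max(1L, ctr - h)
    hi <- if (pad) ctr + h else min(n, ctr + h)
    win <- lo:hi
    avg <- mean(capped_w[win])
    nat <- sum(nat_flag[win])
    slo <- if (pad) ctr - 5L else max(1L, ctr - 5L)
    trail <- capped_w[slo:ctr]
    sdv <- if (length(trail) >= 2) stats::sd(trail) else 0
    lg <- log(capped[i] + 1)
    ps[i] <- co[["intercept"]] + co[["avg"]] * avg + co[["nat"]] * nat +
      co[["sd"]] * sdv + co[["lg"]] * lg
  }
  ifelse(ps >= 0, "BEDREST", "WAKE")
}
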