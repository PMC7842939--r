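#' Non-wear detection parameters
#'
#' Parameters of the zero-run non-wear rule applied before bedrest detection,
#' following the published Choi defaults (90-min window, up to 2 min of
#' tolerated nonzero "artifactual" counts, 30-min zero flanks around a
#' tolerated spike).
#'
#' @param window_min Minimum length, in minutes, of a (spike-tolerant) run of
#'   zero counts that counts as non-wear. Default 90.
#' @param spike_tolerance_min Maximum length, in minutes, of a nonzero spike
#'   tolerated inside a non-wear window. Default 2.
#' @param spike_flank_min Minutes of zeros required immediately upstream and
#'   downstream of a tolerated spike. Default 30.
#' @param signal Which signal the zero test uses: `"vm"` (default; a zero VM
#'   epoch is exactly an all-axes-zero epoch) or `"axis1"`.
#' @return A list of class `nonwear_params`.
#' @export
nonwear_params <- function(window_min = 90, spike_tolerance_min = 2,
                           spike_flank_min = 30, signal = c("vm", "axis1")) {
  signal <- match.arg(signal)
  stopifnot(window_min > 0, spike_tolerance_min > 0, spike_flank_min > 0,
            spike_tolerance_min < window_min)
  structure(list(window_min = window_min,
                 spike_tolerance_min = spike_tolerance_min,
                 spike_flank_min = spike_flank_min,
                 signal = signal),
            class = "nonwear_params")
}

#' Flag non-wear epochs
#'
#' Scans a 60-s epoch series for maximal runs of zero counts of at least
#' `window_min` minutes and labels them `"NONWEAR"`. A nonzero spike of at
#' most `spike_tolerance_min` minutes inside such a run is tolerated
#' (absorbed into the run) when it is flanked on both sides by at least
#' `spike_flank_min` consecutive zero minutes. All other epochs are returned
#' as `"WAKE"`, the provisional state later detectors refine; non-wear epochs
#' are excluded from bedrest detection and from all agreement statistics so
#' an off-body device is never scored as bedrest.
#'
#' @param series An [epoch_series()] with 60-s epochs (re-integrate first
#'   otherwise).
#' @param params A [nonwear_params()].
#' @return Character label vector aligned to `series` with states
#'   `"NONWEAR"`/`"WAKE"`.
#' @export
#' @examples
#' s <- epoch_series("2023-03-06 00:00:00",
#'                   axis1 = rep(c(500L, 0L), c(30, 90)),
#'                   axis2 = integer(120), axis3 = integer(120))
#' table(detect_nonwear(s))
detect_nonwear <- function(series, params = nonwear_params()) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_length != 60L) {
    stop("non-wear detection requires 60-s epochs; re-integrate the series first",
         call. = FALSE)
  }
  x <- if (params$signal == "vm") series$vm else series$axis1
  n <- length(x)
  is_zero <- x == 0

  r <- rle(is_zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$lengths)

  # a nonzero run is a tolerated spike when short enough and flanked by long
  # zero runs on both sides
  absorbed <- is_zero
  if (k >= 3) {
    for (i in seq_len(k)) {
      if (!r$values[i] && i > 1 && i < k &&
          r$lengths[i] <= params$spike_tolerance_min &&
          r$lengths[i - 1] >= params$spike_flank_min &&
          r$lengths[i + 1] >= params$spike_flank_min) {
        absorbed[starts[i]:ends[i]] <- TRUE
      }
    }
  }

  labels <- rep("WAKE", n)
  r2 <- rle(absorbed)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  for (i in seq_along(r2$lengths)) {
    if (r2$values[i] && r2$lengths[i] >= params$window_min) {
      labels[s2[i]:e2[i]] <- "NONWEAR"
    }
  }
  labels
}
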