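#' Epoch count series
#'
#' An `epoch_series` holds a gap-free, fixed-interval sequence of per-epoch
#' triaxial activity counts together with their vector magnitude (VM).
#' Epoch `i` covers the interval starting at `start_time + (i - 1) *
#' epoch_length` seconds. Gaps must be represented explicitly (zero-filled or
#' non-wear flagged epochs), never as missing rows.
#'
#' @param start_time Start instant of the first epoch (`POSIXct`, or a string
#'   parseable by [as.POSIXct()]; stored in UTC unless a timezone is given).
#' @param axis1,axis2,axis3 Non-negative integer activity counts per epoch,
#'   equal length.
#' @param epoch_length Epoch duration in seconds (positive integer; 60 for
#'   the minute epochs all detectors operate on).
#' @param meta Optional named list of free-form device/subject annotations.
#'
#' @return An object of class `epoch_series`: a list with fields
#'   `start_time`, `epoch_length`, `axis1`, `axis2`, `axis3`, `vm`, `meta`.
#'   `vm[i]` is always `sqrt(axis1[i]^2 + axis2[i]^2 + axis3[i]^2)`, stored
#'   unrounded.
#' @seealso [compute_vector_magnitude()], [reintegrate()], [read_epoch_csv()]
#' @export
#' @examples
#' s <- epoch_series("2023-03-06 08:00:00", axis1 = c(3, 0), axis2 = c(4, 0),
#'                   axis3 = c(0, 0))
#' s$vm  # 5, 0
epoch_series <- function(start_time, axis1, axis2, axis3,
                         epoch_length = 60L, meta = list()) {
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  if (length(start_time) != 1L || is.na(start_time)) {
    stop("`start_time` must be a single, parseable timestamp", call. = FALSE)
  }
  epoch_length <- as.integer(epoch_length)
  if (is.na(epoch_length) || epoch_length <= 0L) {
    stop("`epoch_length` must be a positive integer number of seconds",
         call. = FALSE)
  }
  vm <- compute_vector_magnitude(axis1, axis2, axis3)
  structure(
    list(start_time = start_time,
         epoch_length = epoch_length,
         axis1 = as.integer(axis1),
         axis2 = as.integer(axis2),
         axis3 = as.integer(axis3),
         vm = vm,
         meta = meta),
    class = "epoch_series"
  )
}

#' @export
length.epoch_series <- function(x) length(x$vm)

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<epoch_series> %d epochs of %d s, starting %s\n",
              n, x$epoch_length,
              format(x$start_time, "%Y-%m-%d %H:%M:%S %Z")))
  if (n > 0) {
    cat(sprintf("  vm: min %.1f, median %.1f, max %.1f counts/epoch\n",
                min(x$vm), stats::median(x$vm), max(x$vm)))
  }
  invisible(x)
}

#' Per-epoch start timestamps of a series
#'
#' @param series An [epoch_series()].
#' @return `POSIXct` vector, one start instant per epoch.
#' @export
epoch_times <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  series$start_time + (seq_len(length(series)) - 1L) * series$epoch_length
}

#' Convert an epoch series to a tibble
#'
#' Returns one row per epoch with columns `time`, `axis1`, `axis2`, `axis3`,
#' `vm`.
#'
#' @param x An [epoch_series()].
#' @param ... Unused.
#' @export
#' @method as_tibble epoch_series
as_tibble.epoch_series <- function(x, ...) {
  tibble::tibble(time = epoch_times(x), axis1 = x$axis1, axis2 = x$axis2,
                 axis3 = x$axis3, vm = x$vm)
}

#' @export
as.data.frame.epoch_series <- function(x, ...) {
  as.data.frame(as_tibble.epoch_series(x))
}

#' Vector magnitude of triaxial counts
#'
#' Element-wise Euclidean norm of the three per-axis counts of each epoch.
#' The result is never rounded: threshold comparisons downstream use the real
#' value.
#'
#' @param axis1,axis2,axis3 Non-negative numeric vectors of equal length.
#' @return Numeric vector of per-epoch vector magnitudes.
#' @export
#' @examples
#' compute_vector_magnitude(3, 4, 0)  # 5
compute_vector_magnitude <- function(axis1, axis2, axis3) {
  n <- length(axis1)
  if (length(axis2) != n || length(axis3) != n) {
    stop("axis vectors must have equal length", call. = FALSE)
  }
  if (anyNA(axis1) || anyNA(axis2) || anyNA(axis3)) {
    stop("axis counts must not contain missing values", call. = FALSE)
  }
  if (any(axis1 < 0) || any(axis2 < 0) || any(axis3 < 0)) {
    stop("axis counts must be non-negative", call. = FALSE)
  }
  sqrt(as.numeric(axis1)^2 + as.numeric(axis2)^2 + as.numeric(axis3)^2)
}

#' Re-integrate a series to a longer epoch length
#'
#' Sums per-axis counts within consecutive windows of `target_epoch` seconds
#' and recomputes the vector magnitude from the summed axes (the norm of the
#' sum, not the sum of per-epoch norms). A trailing partial window is dropped
#' with a warning, because a partial window would bias block averages
#' downstream.
#'
#' @param series An [epoch_series()].
#' @param target_epoch Target epoch length in seconds; must be a positive
#'   integer multiple of `series$epoch_length`.
#' @return A new `epoch_series` with the same `start_time`.
#' @export
#' @examples
#' s <- epoch_series("2023-03-06 08:00:00", axis1 = c(3, 0), axis2 = c(0, 4),
#'                   axis3 = c(0, 0), epoch_length = 30)
#' reintegrate(s, 60)$vm  # 5 (norm of the summed axes), not 3 + 4
reintegrate <- function(series, target_epoch) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch <- as.integer(target_epoch)
  if (is.na(target_epoch) || target_epoch <= 0L ||
      target_epoch %% series$epoch_length != 0L) {
    stop(sprintf(
      "`target_epoch` must be a positive integer multiple of the source epoch length (%d s)",
      series$epoch_length), call. = FALSE)
  }
  ratio <- target_epoch %/% series$epoch_length
  if (ratio == 1L) return(series)
  n <- length(series)
  n_full <- n %/% ratio
  if (n %% ratio != 0L) {
    warning(sprintf("dropping trailing partial window of %d epoch(s)",
                    n %% ratio), call. = FALSE)
  }
  idx <- rep(seq_len(n_full), each = ratio)
  keep <- seq_len(n_full * ratio)
  sum_by <- function(v) as.integer(rowsum(as.numeric(v[keep]), idx))
  epoch_series(series$start_time,
               axis1 = sum_by(series$axis1),
               axis2 = sum_by(series$axis2),
               axis3 = sum_by(series$axis3),
               epoch_length = target_epoch,
               meta = series$meta)
}
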