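#' Decision-tree detector parameters
#'
#' The four tunable parameters of the bedrest decision tree plus the minimum
#' bedrest duration. The defaults are the optimum for preschool children
#' (3-6 y): 36-min blocks, a 230 counts/min block threshold, a 305 counts/min
#' bedrest-start trigger and a 1129 counts/min bedrest-end trigger, with a
#' 30-min minimum bedrest period.
#'
#' * `block_length` — number of 1-min epochs averaged per block; the block
#'   means coarse-classify the record as bedrest-like (below threshold) or
#'   wake-like (above).
#' * `threshold` — counts/min separating bedrest-like from wake-like blocks.
#' * `bedrest_start_trigger` — counts/min level whose last consecutive
#'   exceeding pair pinpoints where wake ends and bedrest starts.
#' * `bedrest_end_trigger` — counts/min level whose first consecutive
#'   exceeding pair pinpoints where bedrest ends.
#' * `min_bedrest_min` — bedrest periods shorter than this many minutes are
#'   relabeled wake in the final pass.
#'
#' @param block_length Positive integer number of epochs per block (>= 2).
#' @param threshold Non-negative counts/min.
#' @param bedrest_start_trigger,bedrest_end_trigger Non-negative counts/min.
#' @param min_bedrest_min Minimum bedrest duration in minutes (default 30).
#' @return A list of class `dt_params`.
#' @export
dt_params <- function(block_length = 36, threshold = 230,
                      bedrest_start_trigger = 305,
                      bedrest_end_trigger = 1129,
                      min_bedrest_min = 30) {
  block_length <- as.integer(round(block_length))
  if (is.na(block_length) || block_length < 2L) {
    stop("`block_length` must be an integer >= 2", call. = FALSE)
  }
  stopifnot(threshold >= 0, bedrest_start_trigger >= 0,
            bedrest_end_trigger >= 0, min_bedrest_min > 0)
  structure(list(block_length = block_length, threshold = threshold,
                 bedrest_start_trigger = bedrest_start_trigger,
                 bedrest_end_trigger = bedrest_end_trigger,
                 min_bedrest_min = min_bedrest_min),
            class = "dt_params")
}

#' @export
print.dt_params <- function(x, ...) {
  cat(sprintf(
    "<dt_params> block %d min | threshold %g | start trigger %g | end trigger %g | min bedrest %g min\n",
    x$block_length, x$threshold, x$bedrest_start_trigger,
    x$bedrest_end_trigger, x$min_bedrest_min))
  invisible(x)
}

#' Partition a count signal into block averages
#'
#' Divides a per-epoch count vector into consecutive non-overlapping blocks
#' of `block_length` epochs and averages the counts in each; a final partial
#' block is averaged over the epochs it actually contains.
#'
#' @param x Numeric per-epoch counts (a VM or single-axis signal).
#' @param block_length Epochs per block.
#' @return A tibble with columns `block`, `start_index`, `end_index`
#'   (1-based, inclusive) and `mean_counts`.
#' @export
partition_blocks <- function(x, block_length) {
  block_length <- as.integer(block_length)
  stopifnot(block_length >= 1L, length(x) >= 1L)
  n <- length(x)
  nb <- (n + block_length - 1L) %/% block_length
  start <- (seq_len(nb) - 1L) * block_length + 1L
  end <- pmin(seq_len(nb) * block_length, n)
  idx <- (seq_len(n) - 1L) %/% block_length + 1L
  means <- as.numeric(rowsum(as.numeric(x), idx)) / (end - start + 1L)
  tibble::tibble(block = seq_len(nb), start_index = start, end_index = end,
                 mean_counts = means)
}

#' Initial block status
#'
#' Classifies the first block of a record: a mean at or below the threshold
#' starts the record in bedrest (the detector then searches for a
#' bedrest-end), a mean above it starts the record in wake.
#'
#' @param block_mean Mean counts/epoch of the first block.
#' @param threshold Counts/min threshold.
#' @return `"BEDREST"` or `"WAKE"`.
#' @export
initial_status <- function(block_mean, threshold) {
  if (block_mean <= threshold) "BEDREST" else "WAKE"
}

# block geometry helpers (1-based)
block_of <- function(i, block_length) (i - 1L) %/% block_length + 1L
block_start <- function(k, block_length) (k - 1L) * block_length + 1L

#' Locate the next bedrest-start
#'
#' Starting in wake at `from_epoch`, scans the block means forward for the
#' first block whose mean is strictly below the threshold. Within that block
#' and the preceding one (clamped so the search never reaches behind
#' `from_epoch`), the *last* two consecutive epochs both strictly above the
#' bedrest-start trigger are located; the epoch after that pair is the
#' bedrest-start. If no such pair exists the start falls back to the first
#' epoch of the identified block (clamped to `from_epoch`).
#'
#' @param x Numeric per-epoch counts.
#' @param params A [dt_params()].
#' @param from_epoch 1-based epoch index at which the scan resumes.
#' @return The bedrest-start epoch index, or `NA` when no block below the
#'   threshold remains (no further bedrest) or the located start would lie
#'   past the end of the record.
#' @export
find_bedrest_start <- function(x, params, from_epoch = 1L) {
  dt_find_boundary(x, params, from_epoch, what = "start")
}

#' Locate the next bedrest-end
#'
#' Starting in bedrest at `from_epoch`, scans the block means forward for
#' the first block whose mean is strictly above the threshold. Within that
#' block and the preceding one (clamped to `from_epoch`), the *first* two
#' consecutive epochs both strictly above the bedrest-end trigger are
#' located; the epoch immediately before that pair is the bedrest-end. If no
#' pair exists the end falls back to the first epoch of the identified
#' block. The returned end is clamped to at least `from_epoch`, so a bedrest
#' period always retains its start epoch.
#'
#' @inheritParams find_bedrest_start
#' @return The bedrest-end epoch index, or `NA` when no block above the
#'   threshold remains (bedrest continues to the end of the record).
#' @export
find_bedrest_end <- function(x, params, from_epoch = 1L) {
  dt_find_boundary(x, params, from_epoch, what = "end")
}

dt_find_boundary <- function(x, params, from_epoch, what) {
  n <- length(x)
  B <- params$block_length
  stopifnot(from_epoch >= 1L, from_epoch <= n)
  blocks <- partition_blocks(x, B)
  k0 <- block_of(from_epoch, B)
  hit <- if (what == "start") {
    blocks$mean_counts < params$threshold
  } else {
    blocks$mean_counts > params$threshold
  }
  k <- which(hit & blocks$block >= k0)[1]
  if (is.na(k)) return(NA_integer_)
  wlo <- max(from_epoch, block_start(max(k - 1L, 1L), B))
  whi <- blocks$end_index[k]
  trig <- if (what == "start") params$bedrest_start_trigger else params$bedrest_end_trigger
  pair_first <- integer(0)
  if (wlo < whi) {
    i <- wlo:(whi - 1L)
    above <- x > trig
    pair_first <- i[above[i] & above[i + 1L]]
  }
  if (what == "start") {
    if (length(pair_first) > 0) {
      s <- pair_first[length(pair_first)] + 2L
      if (s > n) return(NA_integer_)
      s
    } else {
      max(block_start(k, B), from_epoch)
    }
  } else {
    e <- if (length(pair_first) > 0) pair_first[1] - 1L else block_start(k, B)
    max(e, from_epoch)
  }
}

#' Detect bedrest and wake periods with the decision tree
#'
#' Runs the four-step decision tree over a 60-s epoch series. Step 1
#' partitions each worn segment into blocks and sets the initial status from
#' the first block mean ([initial_status()]). The detector then alternates
#' Step 2 ([find_bedrest_start()]) and Step 3 ([find_bedrest_end()]) until
#' no qualifying block remains; epochs after the last identified change are
#' marked with the prevailing state. Step 4 is a final pass relabeling every
#' bedrest period shorter than `min_bedrest_min` minutes as wake.
#'
#' Epochs flagged `NONWEAR`/`EXCLUDED` in `labels` are skipped: each maximal
#' worn segment is processed independently (blocks never span non-wear) and
#' the flags are preserved.
#'
#' @param series An [epoch_series()] with 60-s epochs.
#' @param params A [dt_params()].
#' @param labels Optional pre-existing labels carrying `NONWEAR`/`EXCLUDED`
#'   flags (e.g. from [detect_nonwear()]).
#' @param signal `"vm"` (default) or `"axis1"` for single-axis operation.
#' @return A list of class `bedrest_detection` with `labels` (per-epoch
#'   states) and `episodes` (the tiled episode tibble from
#'   [labels_to_episodes()]).
#' @export
#' @examples
#' prof <- sim_profile(n_days = 2, seed = 1)
#' sim <- generate_actigraphy(prof)
#' det <- detect_bedrest(sim$series, dt_params())
#' head(det$episodes)
detect_bedrest <- function(series, params = dt_params(), labels = NULL,
                           signal = c("vm", "axis1")) {
  stopifnot(inherits(series, "epoch_series"), inherits(params, "dt_params"))
  signal <- match.arg(signal)
  if (series$epoch_length != 60L) {
    stop("the decision tree requires 60-s epochs; re-integrate the series first",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("WAKE", length(series))
  check_labels(labels, series)
  x_all <- if (signal == "vm") series$vm else as.numeric(series$axis1)
  out <- labels
  worn <- !(labels %in% c("NONWEAR", "EXCLUDED"))
  for (seg in worn_segments(worn)) {
    out[seg] <- dt_label_segment(x_all[seg], params)
  }
  structure(list(labels = out,
                 episodes = labels_to_episodes(out, series$epoch_length),
                 params = params, signal = signal),
            class = "bedrest_detection")
}

#' @export
print.bedrest_detection <- function(x, ...) {
  tab <- table(factor(x$labels, levels = label_states))
  cat(sprintf("<bedrest_detection> %d epochs: %s\n", length(x$labels),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Steps 1-4 on one contiguous worn segment of per-epoch counts
dt_label_segment <- function(x, params) {
  n <- length(x)
  if (n == 0L) return(character(0))
  states <- rep("WAKE", n)
  first_mean <- mean(x[seq_len(min(params$block_length, n))])
  status <- initial_status(first_mean, params$threshold)
  pos <- 1L
  bs <- if (status == "BEDREST") 1L else NA_integer_
  while (pos <= n) {
    if (status == "WAKE") {
      s <- find_bedrest_start(x, params, pos)
      if (is.na(s)) break                       # no further bedrest
      bs <- s
      pos <- s
      status <- "BEDREST"
    } else {
      e <- find_bedrest_end(x, params, pos)
      if (is.na(e)) {                           # bedrest to end of segment
        states[bs:n] <- "BEDREST"
        break
      }
      states[bs:e] <- "BEDREST"
      pos <- e + 1L
      status <- "WAKE"
    }
  }
  # Step 4: drop bedrest periods shorter than the user minimum
  r <- rle(states)
  r$values[r$values == "BEDREST" & r$lengths < params$min_bedrest_min] <- "WAKE"
  inverse.rle(r)
}
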