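#' Simulation profile for synthetic preschool actigraphy
#'
#' Describes a multi-day minute-epoch trace with the diurnal structure the
#' detectors are built for: one long nighttime bedrest period per day,
#' optional daytime naps, brief awakenings inside night bedrest, right-skewed
#' high-count wake activity, zero-inflated low-count bedrest activity with
#' occasional movement bursts, and optional inserted non-wear runs of exact
#' zeros. The count regimes straddle the decision boundaries the detectors
#' use: wake counts have median ~1500 counts/min (well above the 230
#' counts/min block threshold), bedrest epochs are ~80% zeros with the rest
#' at or below 100 counts/min, and bursts reach ~600 counts/min to exercise
#' the 500 counts/min end rule.
#'
#' @param n_days Number of simulated days (default 7).
#' @param night_start_mean,night_start_sd Bedtime as minutes after midnight
#'   (defaults 1230 +/- 30, i.e. 20:30).
#' @param night_duration_mean,night_duration_sd Night bedrest duration in
#'   minutes (defaults 630 +/- 45).
#' @param nap_probability Probability of one daytime nap per day (default
#'   0.5).
#' @param nap_start_mean,nap_start_sd Nap start as minutes after midnight
#'   (defaults 780 +/- 45, i.e. 13:00).
#' @param nap_duration_range Inclusive nap duration range in minutes
#'   (default `c(30, 90)`, the nap classification band).
#' @param awakening_rate Expected awakenings per hour of night bedrest
#'   (default 0.2).
#' @param awakening_duration_range Awakening duration range in minutes
#'   (default `c(5, 15)`, the awakening classification band).
#' @param wake_meanlog,wake_sdlog Log-normal location/scale of wake
#'   vector-magnitude counts (defaults `log(1500)`, 0.6).
#' @param bedrest_zero_prob Proportion of exact-zero bedrest epochs
#'   (default 0.8).
#' @param bedrest_count_range Range of nonzero bedrest counts (default
#'   `c(1, 100)`).
#' @param burst_rate Probability that a bedrest epoch is a movement burst
#'   (default 0.02).
#' @param burst_range Burst magnitude range in counts/min (default
#'   `c(100, 600)`).
#' @param nonwear_runs List of `c(start_min, duration_min)` runs (1-based
#'   minute index; duration >= 90) replaced by exact zeros and labeled
#'   `NONWEAR`.
#' @param start_date Calendar date of the first midnight (default
#'   `"2023-03-06"`, a Monday).
#' @param seed Integer seed; the same profile always generates the same
#'   trace.
#' @return A list of class `sim_profile`.
#' @export
sim_profile <- function(n_days = 7L,
                        night_start_mean = 1230, night_start_sd = 30,
                        night_duration_mean = 630, night_duration_sd = 45,
                        nap_probability = 0.5,
                        nap_start_mean = 780, nap_start_sd = 45,
                        nap_duration_range = c(30, 90),
                        awakening_rate = 0.2,
                        awakening_duration_range = c(5, 15),
                        wake_meanlog = log(1500), wake_sdlog = 0.6,
                        bedrest_zero_prob = 0.8,
                        bedrest_count_range = c(1, 100),
                        burst_rate = 0.02, burst_range = c(100, 600),
                        nonwear_runs = list(),
                        start_date = "2023-03-06",
                        seed = 1L) {
  stopifnot(n_days >= 1, night_duration_mean > 0, nap_probability >= 0,
            nap_probability <= 1, awakening_rate >= 0,
            nap_duration_range[1] <= nap_duration_range[2],
            awakening_duration_range[1] <= awakening_duration_range[2],
            bedrest_zero_prob >= 0, bedrest_zero_prob <= 1)
  for (run in nonwear_runs) {
    if (length(run) != 2 || run[2] < 90) {
      stop("each non-wear run must be c(start_min, duration_min) with duration >= 90",
           call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "sim_profile")
}

#' Generate a synthetic actigraphy trace with ground truth
#'
#' Realises a [sim_profile()] as a minute-epoch triaxial series plus the
#' per-epoch truth labels and truth episodes. Per-epoch vector magnitudes
#' are drawn from the state-appropriate distribution, then decomposed onto
#' three axes along a random direction in the positive octant and rounded to
#' integer counts, so the stored vector magnitude is exactly the norm of the
#' integer axis counts. Non-wear runs are exact zeros. Generation is a pure
#' function of the profile (including its seed).
#'
#' @param profile A [sim_profile()].
#' @return A list with `series` (an [epoch_series()]), `truth` (per-epoch
#'   labels), `episodes` (truth episodes) and `profile`.
#' @export
#' @examples
#' sim <- generate_actigraphy(sim_profile(n_days = 2, seed = 42))
#' table(sim$truth)
generate_actigraphy <- function(profile) {
  stopifnot(inherits(profile, "sim_profile"))
  withr::with_seed(profile$seed, generate_actigraphy_impl(profile))
}

generate_actigraphy_impl <- function(p) {
  n <- p$n_days * 1440L
  truth <- rep("WAKE", n)

  # nights: one per evening, plus the tail of the previous night covering the
  # first morning; [start, start + duration)
  for (d in seq.int(-1L, p$n_days - 1L)) {
    bed <- d * 1440L + round(stats::rnorm(1, p$night_start_mean, p$night_start_sd))
    dur <- max(60L, round(stats::rnorm(1, p$night_duration_mean, p$night_duration_sd)))
    lo <- max(1L, bed); hi <- min(n, bed + dur - 1L)
    if (lo <= hi) truth[lo:hi] <- "BEDREST"
  }

  # daytime naps, kept clear of night bedrest by a 30-min wake margin so a
  # nap never merges with (or becomes an awakening gap of) the night period
  for (d in seq_len(p$n_days) - 1L) {
    if (stats::runif(1) >= p$nap_probability) next
    start <- d * 1440L + round(stats::rnorm(1, p$nap_start_mean, p$nap_start_sd))
    dur <- round(stats::runif(1, p$nap_duration_range[1], p$nap_duration_range[2]))
    lo <- start; hi <- start + dur - 1L
    guard_lo <- max(1L, lo - 30L); guard_hi <- min(n, hi + 30L)
    if (lo < 1L || hi > n) next
    if (all(truth[guard_lo:guard_hi] == "WAKE")) truth[lo:hi] <- "BEDREST"
  }

  # awakenings inside long bedrest runs, >= 30 min from the edges and from
  # each other so the flanking bedrest pieces keep their structure
  ep <- labels_to_episodes(truth)
  for (i in which(ep$state == "BEDREST" & ep$duration_min > 150)) {
    run_len <- ep$end_index[i] - ep$start_index[i] + 1L
    k <- stats::rpois(1, p$awakening_rate * run_len / 60)
    if (k == 0) next
    taken <- integer(0)
    for (a in seq_len(k)) {
      dur <- round(stats::runif(1, p$awakening_duration_range[1],
                                p$awakening_duration_range[2]))
      lo_min <- ep$start_index[i] + 30L
      hi_max <- ep$end_index[i] - 30L - dur + 1L
      if (hi_max < lo_min) next
      start <- round(stats::runif(1, lo_min, hi_max))
      span <- seq.int(start - 30L, start + dur + 29L)
      if (any(span %in% taken)) next
      truth[start:(start + dur - 1L)] <- "WAKE"
      taken <- c(taken, span)
    }
  }

  # inserted non-wear runs of exact zeros
  for (run in p$nonwear_runs) {
    lo <- run[1]; hi <- run[1] + run[2] - 1L
    if (lo < 1L || hi > n) {
      stop("non-wear run extends outside the simulated trace", call. = FALSE)
    }
    if (any(truth[lo:hi] == "BEDREST")) {
      stop("requested non-wear run overlaps a night or nap window", call. = FALSE)
    }
    truth[lo:hi] <- "NONWEAR"
  }

  # per-epoch vector magnitudes from the state-appropriate distribution
  vm <- numeric(n)
  is_wake <- truth == "WAKE"
  vm[is_wake] <- stats::rlnorm(sum(is_wake), p$wake_meanlog, p$wake_sdlog)
  is_bed <- truth == "BEDREST"
  nb <- sum(is_bed)
  if (nb > 0) {
    b <- ifelse(stats::runif(nb) < p$bedrest_zero_prob, 0,
                stats::runif(nb, p$bedrest_count_range[1], p$bedrest_count_range[2]))
    burst <- stats::runif(nb) < p$burst_rate
    b[burst] <- stats::runif(sum(burst), p$burst_range[1], p$burst_range[2])
    vm[is_bed] <- b
  }

  # decompose onto the positive octant and round to integer counts
  dirs <- matrix(abs(stats::rnorm(3L * n)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  axes <- round(dirs * vm)

  series <- epoch_series(
    as.POSIXct(paste(p$start_date, "00:00:00"), tz = "UTC"),
    axis1 = axes[, 1], axis2 = axes[, 2], axis3 = axes[, 3],
    epoch_length = 60L,
    meta = list(generator = "sim_profile", seed = p$seed))
  list(series = series, truth = truth,
       episodes = labels_to_episodes(truth), profile = p)
}

#' Deterministic boundary-case fixtures
#'
#' Builds the small canonical fixtures the tests exercise, each a
#' deterministic series plus truth labels: an all-zero day, an all-active
#' day, bedrest episodes of 29/30/90/91 min (the nap classification
#' boundaries), wake gaps of 4/5/15/16 min inside long bedrest (the
#' awakening boundaries), and zero-run non-wear cases of 89/90 min and a
#' tolerated-spike run. Wake epochs count 1000 on axis 1, bedrest and
#' non-wear epochs count 0.
#'
#' @return Named list; each element has `series` and `truth`.
#' @export
fixture_suite <- function() {
  mk <- function(lens, states) {
    counts <- rep(ifelse(states == "WAKE", 1000L, 0L), lens)
    list(series = epoch_series("2023-03-06 00:00:00", axis1 = counts,
                               axis2 = integer(length(counts)),
                               axis3 = integer(length(counts))),
         truth = rep(states, lens))
  }
  out <- list(
    all_zero_day = mk(1440, "BEDREST"),
    all_active_day = mk(1440, "WAKE"))
  for (d in c(29, 30, 90, 91)) {
    out[[paste0("nap_", d)]] <-
      mk(c(240, d, 600 - 240 - d), c("WAKE", "BEDREST", "WAKE"))
  }
  for (g in c(4, 5, 15, 16)) {
    out[[paste0("awakening_", g)]] <-
      mk(c(120, 200, g, 200, 200 - g),
         c("WAKE", "BEDREST", "WAKE", "BEDREST", "WAKE"))
  }
  spike <- mk(c(100, 45, 1, 45, 100),
              c("WAKE", "NONWEAR", "NONWEAR", "NONWEAR", "WAKE"))
  spike$series$axis1[146] <- 50L
  spike$series$vm[146] <- 50
  out$nonwear_spike_tolerated <- spike
  out$nonwear_89 <- mk(c(100, 89, 100), c("WAKE", "WAKE", "WAKE"))
  out$nonwear_90 <- mk(c(100, 90, 100), c("WAKE", "NONWEAR", "WAKE"))
  out
}

#' Write the fixture suite to disk
#'
#' Serialises every [fixture_suite()] case as a plain-dialect trace CSV and
#' a labeled truth CSV (see [write_labeled_csv()]).
#'
#' @param out_dir Output directory (created if missing).
#' @return Invisible character vector of the written paths.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- fixture_suite()
  paths <- character(0)
  for (nm in names(suite)) {
    fx <- suite[[nm]]
    trace <- file.path(out_dir, paste0(nm, "_trace.csv"))
    df <- data.frame(timestamp = format(epoch_times(fx$series),
                                        "%Y-%m-%d %H:%M:%S"),
                     axis1 = fx$series$axis1, axis2 = fx$series$axis2,
                     axis3 = fx$series$axis3)
    utils::write.csv(df, trace, row.names = FALSE, quote = FALSE)
    truth <- file.path(out_dir, paste0(nm, "_truth.csv"))
    write_labeled_csv(fx$series, fx$truth, truth)
    paths <- c(paths, trace, truth)
  }
  invisible(paths)
}
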