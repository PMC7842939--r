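# Independent naive reference implementation of the four-step detector:
# a literal forward scan with explicit loops and no shared code with the
# package internals. Used to cross-validate detect_bedrest() epoch-for-epoch.
oracle_detect_bedrest <- function(x, block_length, threshold,
                                  start_trigger, end_trigger, min_bedrest) {
  n <- length(x)
  if (n == 0) return(character(0))

  nblocks <- ceiling(n / block_length)
  bstart <- integer(nblocks); bend <- integer(nblocks); bmean <- numeric(nblocks)
  for (k in seq_len(nblocks)) {
    bstart[k] <- (k - 1) * block_length + 1
    bend[k] <- min(k * block_length, n)
    s <- 0
    for (i in bstart[k]:bend[k]) s <- s + x[i]
    bmean[k] <- s / (bend[k] - bstart[k] + 1)
  }

  st <- rep("WAKE", n)
  status <- if (bmean[1] <= threshold) "BEDREST" else "WAKE"
  pos <- 1
  bs <- if (status == "BEDREST") 1 else NA
  repeat {
    if (pos > n) break
    kpos <- floor((pos - 1) / block_length) + 1
    if (status == "WAKE") {
      k <- NA
      for (kk in kpos:nblocks) if (bmean[kk] < threshold) { k <- kk; break }
      if (is.na(k)) break                                   # no further bedrest
      lo <- max(pos, bstart[max(k - 1, 1)]); hi <- bend[k]
      last_pair <- NA
      if (lo < hi) {
        for (i in lo:(hi - 1)) {
          if (x[i] > start_trigger && x[i + 1] > start_trigger) last_pair <- i
        }
      }
      if (!is.na(last_pair)) {
        s <- last_pair + 2
        if (s > n) break
      } else {
        s <- max(bstart[k], pos)
      }
      bs <- s; pos <- s; status <- "BEDREST"
    } else {
      k <- NA
      for (kk in kpos:nblocks) if (bmean[kk] > threshold) { k <- kk; break }
      if (is.na(k)) { st[bs:n] <- "BEDREST"; break }        # bedrest to end
      lo <- max(pos, bstart[max(k - 1, 1)]); hi <- bend[k]
      first_pair <- NA
      if (lo < hi) {
        for (i in lo:(hi - 1)) {
          if (x[i] > end_trigger && x[i + 1] > end_trigger) { first_pair <- i; break }
        }
      }
      e <- if (!is.na(first_pair)) first_pair - 1 else bstart[k]
      if (e < pos) e <- pos
      st[bs:e] <- "BEDREST"
      pos <- e + 1; status <- "WAKE"
    }
  }

  # final pass: drop bedrest runs shorter than the minimum, by manual scan
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && st[j + 1] == st[i]) j <- j + 1
    if (st[i] == "BEDREST" && (j - i + 1) < min_bedrest) st[i:j] <- "WAKE"
    i <- j + 1
  }
  st
}

# random piecewise-constant trace with per-epoch noise, spanning the count
# regimes on both sides of typical thresholds/triggers
random_trace <- function(n) {
  levels <- c(0, 20, 100, 250, 350, 600, 1200, 2000)
  x <- numeric(0)
  while (length(x) < n) {
    len <- sample(5:200, 1)
    lev <- sample(levels, 1)
    x <- c(x, pmax(0, lev + round(stats::rnorm(len, 0, lev * 0.1 + 5))))
  }
  x[seq_len(n)]
}

random_dt_params <- function() {
  dt_params(block_length = sample(2:60, 1),
            threshold = sample(50:500, 1),
            bedrest_start_trigger = sample(100:600, 1),
            bedrest_end_trigger = sample(300:2000, 1),
            min_bedrest_min = sample(10:60, 1))
}

# wraps a bare count vector as a 60-s epoch series (axis1 carries the signal)
series_from_counts <- function(x, start = "2023-03-06 00:00:00") {
  epoch_series(start, axis1 = as.integer(round(x)),
               axis2 = integer(length(x)), axis3 = integer(length(x)))
}

# runs detect_bedrest on a bare vector and returns the label vector
dt_labels <- function(x, params) {
  detect_bedrest(series_from_counts(x), params)$labels
}
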