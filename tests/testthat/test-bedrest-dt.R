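test_that("blocks partition the signal with an averaged partial tail", {
  b1 <- partition_blocks(rep(230, 72), 36)
  expect_equal(nrow(b1), 2)
  expect_equal(b1$mean_counts, c(230, 230))
  b2 <- partition_blocks(c(rep(100, 72), rep(500, 8)), 36)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$end_index[3] - b2$start_index[3] + 1L, 8L)
  expect_equal(b2$mean_counts[3], 500)
})

test_that("initial status groups a threshold tie with bedrest", {
  expect_equal(initial_status(0, 230), "BEDREST")
  expect_equal(initial_status(1000, 230), "WAKE")
  expect_equal(initial_status(230, 230), "BEDREST")
})

test_that("bedrest-start follows the last trigger pair before the quiet block", {
  p <- dt_params()
  x <- c(rep(1000, 36), rep(0, 36))
  expect_equal(find_bedrest_start(x, p, 1), 37L)  # pair at 35-36, start after
  # no trigger pair anywhere: fall back to the quiet block's first epoch
  x2 <- c(rep(250, 36), rep(0, 36))
  expect_equal(find_bedrest_start(x2, p, 1), 37L)
  # no block below threshold: no further bedrest
  x3 <- rep(1000, 144)
  expect_true(is.na(find_bedrest_start(x3, p, 1)))
})

test_that("bedrest-end precedes the first trigger pair in the active block", {
  p <- dt_params()
  x <- c(rep(0, 400), rep(2000, 72))
  expect_equal(find_bedrest_end(x, p, 1), 400L)
  # trigger pair straddling the block boundary is found (joint window)
  x2 <- c(rep(0, 34), rep(2000, 110))
  e2 <- find_bedrest_end(x2, p, 1)
  expect_equal(e2, 34L)
  # nothing above threshold: bedrest to end of series
  expect_true(is.na(find_bedrest_end(rep(0, 144), p, 1)))
})

test_that("whole-series detection labels the obvious extremes", {
  p <- dt_params()
  quiet <- dt_labels(rep(0, 600), p)
  expect_true(all(quiet == "BEDREST"))
  active <- dt_labels(rep(2000, 600), p)
  expect_true(all(active == "WAKE"))
})

test_that("a 20-min quiet dip inside active daytime is wake after the final pass", {
  x <- c(rep(2000, 300), rep(0, 20), rep(2000, 300))
  lab <- dt_labels(x, dt_params())
  expect_true(all(lab == "WAKE"))
})

test_that("detection matches the naive forward-scan oracle on random traces", {
  withr::with_seed(41, {
    for (rep_i in 1:150) {
      n <- sample(50:2000, 1)
      x <- random_trace(n)
      p <- random_dt_params()
      got <- dt_labels(x, p)
      want <- oracle_detect_bedrest(x, p$block_length, p$threshold,
                                    p$bedrest_start_trigger,
                                    p$bedrest_end_trigger, p$min_bedrest_min)
      expect_identical(got, want)
    }
  })
})

test_that("every worn epoch is labeled and short bedrest never survives", {
  withr::with_seed(42, {
    for (rep_i in 1:30) {
      x <- random_trace(800)
      p <- random_dt_params()
      lab <- dt_labels(x, p)
      expect_true(all(lab %in% c("BEDREST", "WAKE")))
      ep <- labels_to_episodes(lab)
      expect_true(all(ep$duration_min[ep$state == "BEDREST"] >=
                        p$min_bedrest_min))
      expect_equal(sum(ep$end_index - ep$start_index + 1L), length(x))
    }
  })
})

test_that("raising the end trigger never ends a bedrest episode earlier", {
  withr::with_seed(43, x <- random_trace(1200))
  ends <- lapply(c(600, 900, 1129, 1500), function(tr) {
    lab <- dt_labels(x, dt_params(bedrest_end_trigger = tr))
    ep <- labels_to_episodes(lab)
    ep[ep$state == "BEDREST", ]
  })
  for (i in seq_len(length(ends) - 1)) {
    lo <- ends[[i]]; hi <- ends[[i + 1]]
    # match episodes by overlapping start; compare their end indices
    for (j in seq_len(nrow(lo))) {
      k <- which(hi$start_index <= lo$end_index & hi$end_index >= lo$start_index)
      if (length(k) > 0) {
        expect_gte(max(hi$end_index[k]), lo$end_index[j] - 0)
      }
    }
  }
})

test_that("different parameter sets change the labels on a designed trace", {
  # activity level 700 sits between the preschool end trigger (1129) and a
  # lower alternative (500): only the latter ends bedrest at the bump
  x <- c(rep(0, 200), rep(700, 40), rep(0, 200))
  preschool <- dt_labels(x, dt_params())
  alt <- dt_labels(x, dt_params(block_length = 60, threshold = 400,
                                bedrest_start_trigger = 400,
                                bedrest_end_trigger = 500))
  expect_false(identical(preschool, alt))
})

test_that("non-wear segments are skipped and blocks never span them", {
  x <- c(rep(0, 120), rep(0, 100), rep(2000, 120))
  labels <- rep("WAKE", length(x))
  labels[121:220] <- "NONWEAR"
  det <- detect_bedrest(series_from_counts(x), dt_params(), labels = labels)
  expect_true(all(det$labels[121:220] == "NONWEAR"))
  expect_true(all(det$labels[1:120] == "BEDREST"))
  expect_true(all(det$labels[221:340] == "WAKE"))
})
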