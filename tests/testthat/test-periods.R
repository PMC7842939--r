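lab_run <- function(lens, states) rep(states, lens)

test_that("bedrest durations map to wake, nap and bedrest-period tags", {
  cases <- list(c(29, "WAKE"), c(30, "NAP"), c(45, "NAP"), c(90, "NAP"),
                c(91, "BEDREST_PERIOD"), c(600, "BEDREST_PERIOD"))
  for (cs in cases) {
    d <- as.numeric(cs[1])
    lab <- lab_run(c(120, d, 120), c("WAKE", "BEDREST", "WAKE"))
    cls <- classify_periods(lab)
    got <- cls$periods$tag[cls$periods$tag != "WAKE"]
    if (cs[2] == "WAKE") {
      expect_length(got, 0)
      expect_true(all(cls$labels == "WAKE"))
    } else {
      expect_identical(got, cs[2])
      expect_equal(cls$periods$duration_min[cls$periods$tag == cs[2]], d)
    }
  }
})

test_that("wake gaps of 5-15 min inside long bedrest are awakenings", {
  for (g in c(4, 5, 15, 16)) {
    lab <- lab_run(c(60, 200, g, 200, 60),
                   c("WAKE", "BEDREST", "WAKE", "BEDREST", "WAKE"))
    cls <- classify_periods(lab)
    if (g %in% c(5, 15)) {
      # one merged bedrest period containing one awakening
      expect_equal(sum(cls$periods$tag == "BEDREST_PERIOD"), 1)
      expect_equal(nrow(cls$awakenings), 1)
      expect_equal(cls$awakenings$duration_min, g)
      per <- cls$periods[cls$periods$tag == "BEDREST_PERIOD", ]
      expect_equal(per$duration_min, 400)      # bedrest minutes only
      expect_equal(per$end_index - per$start_index + 1L, 400L + g)
    } else {
      # gap outside the awakening band: two separate bedrest periods
      expect_equal(sum(cls$periods$tag == "BEDREST_PERIOD"), 2)
      expect_equal(nrow(cls$awakenings), 0)
    }
    # awakening epochs stay wake at the epoch level
    expect_equal(sum(cls$labels == "WAKE"), 120 + g)
  }
})

test_that("a candidate gap in a short merged span is not an awakening", {
  # 40 + 10 + 40 = 90-min span does not exceed the long-bedrest bound
  lab <- lab_run(c(60, 40, 10, 40, 60),
                 c("WAKE", "BEDREST", "WAKE", "BEDREST", "WAKE"))
  cls <- classify_periods(lab)
  expect_equal(nrow(cls$awakenings), 0)
  expect_equal(sum(cls$periods$tag == "NAP"), 2)
  # 45 + 10 + 45 = 100-min span exceeds it: merged period with awakening
  lab2 <- lab_run(c(60, 45, 10, 45, 60),
                  c("WAKE", "BEDREST", "WAKE", "BEDREST", "WAKE"))
  cls2 <- classify_periods(lab2)
  expect_equal(sum(cls2$periods$tag == "BEDREST_PERIOD"), 1)
  expect_equal(nrow(cls2$awakenings), 1)
})

test_that("nap plus bedrest-period minutes equal surviving bedrest epochs", {
  withr::with_seed(71, {
    for (rep_i in 1:20) {
      lab <- dt_labels(random_trace(1500), random_dt_params())
      cls <- classify_periods(lab)
      tagged <- cls$periods$duration_min[cls$periods$tag %in%
                                           c("NAP", "BEDREST_PERIOD")]
      expect_equal(sum(tagged), sum(cls$labels == "BEDREST"))
    }
  })
})

test_that("daily summaries split by calendar day and skip excluded time", {
  # two days: night bedrest crossing midnight + one nap on day 2
  lens <- c(1000, 480, 300, 60, 120, 200, 720)
  states <- c("WAKE", "BEDREST", "WAKE", "BEDREST", "WAKE", "EXCLUDED", "WAKE")
  lab <- lab_run(lens, states)
  s <- epoch_series("2023-03-06 00:00:00", axis1 = integer(sum(lens)),
                    axis2 = integer(sum(lens)), axis3 = integer(sum(lens)))
  summ <- summarize_days(lab, s)
  expect_equal(nrow(summ$days), 2)
  # night: starts 10:00, 480 min -> 440 min on day 1, 40 min on day 2
  expect_equal(summ$days$bedrest_min[1], 440)
  expect_equal(summ$days$bedrest_min[2], 40 + 60)
  expect_equal(summ$days$nonwear_min[2], 200)
  # the 60-min bedrest block is one nap, counted on its start day (day 2)
  expect_equal(summ$days$nap_count, c(0, 1))
  expect_equal(summ$days$nap_min, c(0, 60))
  expect_equal(summ$means[["nap_count"]], 0.5)
  # excluded time contributes to neither bedrest nor wake
  expect_equal(summ$days$bedrest_min + summ$days$wake_min +
                 summ$days$nonwear_min, c(1440, 1440))
})
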