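# worn series of n minutes starting at `start`; counts are nonzero so the
# wear state is carried entirely by the labels passed alongside
worn_series <- function(start, n) {
  epoch_series(start, axis1 = rep(500L, n), axis2 = integer(n),
               axis3 = integer(n))
}

test_that("night validity turns on 360 worn minutes in the 22:00-06:59 window", {
  # series covering exactly the night window of 2023-03-06 (540 min)
  s <- worn_series("2023-03-06 22:00:00", 540)
  all_worn <- rep("WAKE", 540)
  expect_true(is_valid_night(s, all_worn, "2023-03-06"))
  # exactly 360 worn minutes: valid (inclusive bound)
  lab360 <- c(rep("WAKE", 360), rep("NONWEAR", 180))
  expect_true(is_valid_night(s, lab360, "2023-03-06"))
  # 359 worn minutes: invalid
  lab359 <- c(rep("WAKE", 359), rep("NONWEAR", 181))
  expect_false(is_valid_night(s, lab359, "2023-03-06"))
  # non-contiguous worn minutes count toward the total
  lab_alt <- rep(c("WAKE", "NONWEAR"), 270)
  expect_false(is_valid_night(s, lab_alt, "2023-03-06"))  # 270 < 360
  # coverage missing from the recording counts as not worn
  s_half <- worn_series("2023-03-07 01:00:00", 300)
  expect_false(is_valid_night(s_half, rep("WAKE", 300), "2023-03-06"))
})

test_that("data after a 48-hour non-wear run are excluded (inclusive threshold)", {
  n <- 4 * 1440
  s <- worn_series("2023-03-06 00:00:00", n)
  # 48-h run exactly, starting at hour 12
  lab <- rep("WAKE", n)
  run <- 721:(720 + 2880)
  lab[run] <- "NONWEAR"
  out <- truncate_after_nonwear(s, lab)
  expect_equal(attr(out, "truncated_at"), 720 + 2880 + 1)
  expect_true(all(out[(720 + 2881):n] == "EXCLUDED"))
  expect_true(all(out[run] == "NONWEAR"))
  expect_true(all(out[1:720] == "WAKE"))
  # one minute short of the limit: untouched
  lab2 <- rep("WAKE", n)
  lab2[721:(720 + 2879)] <- "NONWEAR"
  out2 <- truncate_after_nonwear(s, lab2)
  expect_true(is.na(attr(out2, "truncated_at")))
  expect_false(any(out2 == "EXCLUDED"))
})

test_that("recording validity needs 3 valid nights incl. 2 weeknights and 1 weekend night", {
  # 2023-03-06 is a Monday; a fully worn week gives 7+ valid nights
  week <- worn_series("2023-03-06 00:00:00", 7 * 1440)
  rep_week <- validate_recording(week, rep("WAKE", length(week)))
  expect_true(rep_week$is_valid)
  expect_gte(rep_week$valid_nights, 7)
  expect_gte(rep_week$weekend_nights, 2)  # Friday and Saturday nights

  # Monday noon to Thursday noon: only weeknights are covered
  midweek <- worn_series("2023-03-06 12:00:00", 3 * 1440)
  rep_mid <- validate_recording(midweek, rep("WAKE", length(midweek)))
  expect_gte(rep_mid$valid_nights, 3)
  expect_equal(rep_mid$weekend_nights, 0)
  expect_false(rep_mid$is_valid)

  # Wednesday noon to Saturday noon: 2 weeknights + 1 weekend night
  wed <- worn_series("2023-03-08 12:00:00", 3 * 1440)
  rep_wed <- validate_recording(wed, rep("WAKE", length(wed)))
  expect_equal(rep_wed$weeknights, 2)
  expect_equal(rep_wed$weekend_nights, 1)
  expect_true(rep_wed$is_valid)
})

test_that("adding worn epochs never invalidates a valid night", {
  s <- worn_series("2023-03-06 22:00:00", 540)
  lab <- c(rep("WAKE", 400), rep("NONWEAR", 140))
  expect_true(is_valid_night(s, lab, "2023-03-06"))
  for (k in c(100, 50, 0)) {
    lab_more <- c(rep("WAKE", 540 - k), rep("NONWEAR", k))
    expect_true(is_valid_night(s, lab_more, "2023-03-06"))
  }
})
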