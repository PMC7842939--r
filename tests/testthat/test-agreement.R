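lab_of <- function(tp, tn, fp, fn) {
  test <- rep(c("BEDREST", "WAKE", "BEDREST", "WAKE"), c(tp, tn, fp, fn))
  ref <- rep(c("BEDREST", "WAKE", "WAKE", "BEDREST"), c(tp, tn, fp, fn))
  list(test = test, ref = ref)
}

test_that("confusion tallies the four cells and drops unworn epochs", {
  p <- lab_of(8, 9, 1, 2)
  cc <- confusion(p$test, p$ref)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(8, 9, 1, 2))
  expect_equal(cc$n_compared, 20)
  # identical sequences: no errors
  ident <- confusion(p$ref, p$ref)
  expect_equal(c(ident$fp, ident$fn), c(0, 0))
  # all-bedrest vs all-wake
  cc2 <- confusion(rep("BEDREST", 10), rep("WAKE", 10))
  expect_equal(cc2$fp, 10)
  # non-wear in either sequence removes the epoch from the comparison
  test <- c("BEDREST", "NONWEAR", "WAKE")
  ref <- c("BEDREST", "BEDREST", "EXCLUDED")
  expect_equal(confusion(test, ref)$n_compared, 1)
  expect_error(confusion(test, ref[1:2]), "length")
})

test_that("confusion agrees with an exhaustive per-epoch tally on random pairs", {
  withr::with_seed(61, {
    for (rep_i in 1:10) {
      test <- sample(label_states, 200, replace = TRUE)
      ref <- sample(label_states, 200, replace = TRUE)
      cc <- confusion(test, ref)
      tp <- tn <- fp <- fn <- 0
      for (i in 1:200) {
        if (test[i] %in% c("NONWEAR", "EXCLUDED") ||
            ref[i] %in% c("NONWEAR", "EXCLUDED")) next
        if (test[i] == "BEDREST" && ref[i] == "BEDREST") tp <- tp + 1
        else if (test[i] == "WAKE" && ref[i] == "WAKE") tn <- tn + 1
        else if (test[i] == "BEDREST") fp <- fp + 1
        else fn <- fn + 1
      }
      expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(tp, tn, fp, fn))
      expect_equal(cc$n_compared, tp + tn + fp + fn)
    }
  })
})

test_that("performance implements the three defining ratios", {
  p <- lab_of(8, 9, 1, 2)
  perf <- performance(confusion(p$test, p$ref))
  expect_equal(unname(perf), c(0.8, 0.9, 0.85))
  perfect <- performance(confusion(p$ref, p$ref))
  expect_equal(unname(perfect), c(1, 1, 1))
  # undefined sensitivity (no reference bedrest) is NA, not 0
  noref <- confusion(rep("WAKE", 5), rep("WAKE", 5))
  expect_true(is.na(performance(noref)[["sensitivity"]]))
  expect_error(performance(confusion(rep("NONWEAR", 3), rep("WAKE", 3))),
               "no compared")
})

test_that("kappa matches a hand-computed 2x2 table and its edge cases", {
  # table: both-bedrest 45, a-bedrest/b-wake 15, a-wake/b-bedrest 25, both-wake 15
  a <- rep(c("BEDREST", "BEDREST", "WAKE", "WAKE"), c(45, 15, 25, 15))
  b <- rep(c("BEDREST", "WAKE", "BEDREST", "WAKE"), c(45, 15, 25, 15))
  # po = 0.60, pe = 0.6*0.7 + 0.4*0.3 = 0.54, kappa = 0.06/0.46
  expect_equal(cohen_kappa(a, b), 0.06 / 0.46, tolerance = 1e-12)
  # binary: linear, quadratic and unweighted coincide
  expect_equal(cohen_kappa(a, b, "quadratic"), cohen_kappa(a, b, "linear"))
  expect_equal(cohen_kappa(a, b, "unweighted"), cohen_kappa(a, b, "linear"))
  # identical non-constant sequences
  expect_equal(cohen_kappa(a, a), 1)
  # identical constant sequences: total agreement with a degeneracy warning
  expect_warning(k1 <- cohen_kappa(rep("WAKE", 10), rep("WAKE", 10)),
                 "degenerate")
  expect_equal(k1, 1)
  # symmetry
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
})

test_that("kappa cross-checks against an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(62, {
    for (rep_i in 1:5) {
      a <- sample(c("BEDREST", "WAKE"), 300, replace = TRUE, prob = c(0.6, 0.4))
      b <- ifelse(stats::runif(300) < 0.8, a,
                  sample(c("BEDREST", "WAKE"), 300, replace = TRUE))
      want <- e1071::classAgreement(table(a, b))$kappa
      expect_equal(cohen_kappa(a, b, "unweighted"), want, tolerance = 1e-10)
    }
  })
})

test_that("kappa of independent labels is near zero at large n", {
  withr::with_seed(63, {
    a <- sample(c("BEDREST", "WAKE"), 2e4, replace = TRUE)
    b <- sample(c("BEDREST", "WAKE"), 2e4, replace = TRUE)
  })
  expect_lt(abs(cohen_kappa(a, b)), 0.03)
})

test_that("overlap coefficient handles subset, disjoint and partial cases", {
  a <- rep(c("BEDREST", "WAKE"), c(60, 120))
  b <- rep(c("BEDREST", "WAKE"), c(90, 90))
  expect_equal(overlap_coefficient(a, b), 1)   # subset
  expect_equal(overlap_coefficient(b, a), 1)   # symmetric
  disj <- rep(c("WAKE", "BEDREST"), c(90, 90))
  expect_equal(overlap_coefficient(b, disj), 0)
  # 60 vs 90 min with 30 min intersection
  c1 <- rep(c("BEDREST", "WAKE"), c(60, 120))
  c2 <- rep(c("WAKE", "BEDREST", "WAKE"), c(30, 90, 60))
  expect_equal(overlap_coefficient(c1, c2), 0.5)
  # empty set: not applicable
  expect_true(is.na(overlap_coefficient(rep("WAKE", 10), rep("BEDREST", 10))))
})
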