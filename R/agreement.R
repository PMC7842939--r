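#' Epoch-level confusion counts
#'
#' Tallies synchronized epoch pairs of a test and a reference label
#' sequence. Bedrest is the positive class; epochs that are `NONWEAR` or
#' `EXCLUDED` in *either* sequence are dropped from the comparison, so
#' off-body and discarded time never enters the agreement statistics.
#'
#' @param test,reference Equal-length label vectors (see [label_states]).
#' @return A list of class `confusion_counts` with fields `tp` (both
#'   bedrest), `tn` (both wake), `fp` (test bedrest, reference wake), `fn`
#'   (test wake, reference bedrest) and `n_compared`.
#' @export
confusion <- function(test, reference) {
  check_labels(test, arg = "test")
  check_labels(reference, arg = "reference")
  if (length(test) != length(reference)) {
    stop(sprintf("sequences differ in length (%d vs %d)",
                 length(test), length(reference)), call. = FALSE)
  }
  keep <- !(test %in% c("NONWEAR", "EXCLUDED")) &
    !(reference %in% c("NONWEAR", "EXCLUDED"))
  t_bed <- test[keep] == "BEDREST"
  r_bed <- reference[keep] == "BEDREST"
  structure(list(tp = sum(t_bed & r_bed),
                 tn = sum(!t_bed & !r_bed),
                 fp = sum(t_bed & !r_bed),
                 fn = sum(!t_bed & r_bed),
                 n_compared = sum(keep)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d | tn %d | fp %d | fn %d (n = %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$n_compared))
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' Computes sensitivity `TP/(TP+FN)` (bedrest epochs correctly identified),
#' specificity `TN/(TN+FP)` (wake epochs correctly identified) and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`. A metric whose denominator is zero is reported
#' as `NA` (not applicable), never as 0.
#'
#' @param counts A `confusion_counts` object from [confusion()].
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
#' @examples
#' performance(structure(list(tp = 8, tn = 9, fp = 1, fn = 2),
#'                       class = "confusion_counts"))
performance <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("no compared epochs: all counts are zero", call. = FALSE)
  sens <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  spec <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp) else NA_real_
  c(sensitivity = sens, specificity = spec,
    accuracy = (counts$tp + counts$tn) / total)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between two label sequences,
#' `1 - observed disagreement / chance disagreement`, with disagreement
#' weights `|i - j| / (k - 1)` (linear, the default), its square
#' (quadratic), or 0/1 (unweighted) over the `k` ordered states present.
#' For two-state sequences all three weightings coincide. Epochs that are
#' `NONWEAR`/`EXCLUDED` in either sequence are dropped first. Two identical
#' constant sequences have degenerate marginals (the formula is 0/0); the
#' agreement is total, so kappa is reported as 1 with a warning.
#'
#' @param a,b Equal-length label vectors.
#' @param weighting `"linear"`, `"quadratic"` or `"unweighted"`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b, weighting = c("linear", "quadratic", "unweighted")) {
  weighting <- match.arg(weighting)
  check_labels(a, arg = "a")
  check_labels(b, arg = "b")
  if (length(a) != length(b)) {
    stop(sprintf("sequences differ in length (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  }
  keep <- !(a %in% c("NONWEAR", "EXCLUDED")) & !(b %in% c("NONWEAR", "EXCLUDED"))
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop("no compared epochs", call. = FALSE)
  states <- sort(unique(c(a, b)))
  k <- length(states)
  if (k == 1) {
    warning("both sequences are the same constant state: marginals are degenerate; reporting kappa = 1",
            call. = FALSE)
    return(1)
  }
  tab <- table(factor(a, levels = states), factor(b, levels = states))
  p <- tab / sum(tab)
  pe <- outer(rowSums(p), colSums(p))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  d <- switch(weighting, linear = d, quadratic = d^2, unweighted = (d > 0) * 1)
  1 - sum(d * p) / sum(d * pe)
}

#' Overlap coefficient of two bedrest sets
#'
#' The time both methods agree on bedrest divided by the smaller of the two
#' total bedrest times: `|A intersect B| / min(|A|, |B|)`. When one method's
#' bedrest set is a subset of the other's the coefficient is exactly 1.
#' Inputs may be label vectors (bedrest epochs are taken) or logical
#' per-minute indicator vectors; epochs `NONWEAR`/`EXCLUDED` in either label
#' vector are dropped first. If either set is empty the coefficient is not
#' applicable (`NA`).
#'
#' @param a,b Equal-length label vectors or logical indicator vectors.
#' @return Overlap coefficient in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' a <- rep(c("BEDREST", "WAKE"), c(60, 120))
#' b <- rep(c("BEDREST", "WAKE"), c(90, 90))
#' overlap_coefficient(a, b)  # 1: a's bedrest is a subset of b's
overlap_coefficient <- function(a, b) {
  if (is.character(a)) {
    check_labels(a, arg = "a")
    check_labels(b, arg = "b")
    if (length(a) != length(b)) {
      stop(sprintf("sequences differ in length (%d vs %d)", length(a), length(b)),
           call. = FALSE)
    }
    keep <- !(a %in% c("NONWEAR", "EXCLUDED")) & !(b %in% c("NONWEAR", "EXCLUDED"))
    a <- a[keep] == "BEDREST"
    b <- b[keep] == "BEDREST"
  }
  stopifnot(is.logical(a), is.logical(b), length(a) == length(b))
  na <- sum(a); nb <- sum(b)
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a & b) / min(na, nb)
}

#' Full agreement report between two label sequences
#'
#' Convenience wrapper combining [confusion()], [performance()],
#' [cohen_kappa()] and [overlap_coefficient()].
#'
#' @inheritParams confusion
#' @return A list with `confusion`, `performance`, `kappa`, `overlap`.
#' @export
agreement_report <- function(test, reference) {
  cc <- confusion(test, reference)
  list(confusion = cc,
       performance = performance(cc),
       kappa = suppressWarnings(cohen_kappa(test, reference)),
       overlap = overlap_coefficient(test, reference))
}
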