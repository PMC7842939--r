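#' Nelder-Mead simplex configuration
#'
#' Coefficients and iteration budget of the simplex search used to tune the
#' decision-tree parameters: reflection `rho`, expansion `chi`, contraction
#' `gamma` and shrinkage `alpha_shrink`, with the standard values 1, 2, 0.5
#' and 0.5, run for a fixed number of iterations (100 by default; the search
#' typically converges in about 80).
#'
#' @param rho,chi,gamma,alpha_shrink Positive simplex coefficients.
#' @param max_iterations Iterations to run (default 100).
#' @param initial_vertices Optional numeric matrix with one starting vertex
#'   per row (for a d-dimensional search, d + 1 rows of d columns). When
#'   `NULL`, [optimize_dt_params()] uses its documented default simplex.
#' @return A list of class `simplex_config`.
#' @export
simplex_config <- function(rho = 1, chi = 2, gamma = 0.5, alpha_shrink = 0.5,
                           max_iterations = 100L, initial_vertices = NULL) {
  stopifnot(rho > 0, chi > 0, gamma > 0, alpha_shrink > 0, max_iterations >= 1)
  structure(list(rho = rho, chi = chi, gamma = gamma,
                 alpha_shrink = alpha_shrink,
                 max_iterations = as.integer(max_iterations),
                 initial_vertices = initial_vertices),
            class = "simplex_config")
}

#' Nelder-Mead simplex minimisation
#'
#' A from-scratch downhill-simplex minimiser with the standard
#' reflect/expand/contract/shrink moves and a fixed iteration budget.
#' Vertices with equal objective values are ordered by lexicographically
#' smaller parameter vector, making the search fully deterministic. The
#' best-ever evaluated point (not merely the final simplex best) is
#' returned, together with a per-iteration trace.
#'
#' @param fn Objective function of a numeric vector, to be minimised.
#' @param vertices Numeric matrix of starting vertices, one per row
#'   (`d + 1` rows, `d` columns).
#' @param config A [simplex_config()].
#' @return A list with `par` (best-ever vector), `value` (its objective),
#'   `trace` (tibble with `iteration`, `current_best`, `best_so_far`) and
#'   `n_evaluations`. `best_so_far` is non-increasing by construction.
#' @export
#' @examples
#' sq <- function(p) sum((p - c(1, 2, 3, 4))^2)
#' v <- diag(4) * 2 + 1
#' fit <- nelder_mead(sq, rbind(rep(0, 4), v), simplex_config(max_iterations = 200))
#' round(fit$par, 3)
nelder_mead <- function(fn, vertices, config = simplex_config()) {
  stopifnot(inherits(config, "simplex_config"))
  v <- as.matrix(vertices)
  d <- ncol(v)
  if (nrow(v) != d + 1L) {
    stop(sprintf("a %d-dimensional search needs %d vertices, got %d",
                 d, d + 1L, nrow(v)), call. = FALSE)
  }
  best_par <- NULL
  best_val <- Inf
  n_eval <- 0L
  eval_fn <- function(p) {
    n_eval <<- n_eval + 1L
    val <- fn(p)
    better <- val < best_val ||
      (val == best_val && !is.null(best_par) && lex_less(p, best_par))
    if (better) {
      best_val <<- val
      best_par <<- p
    }
    val
  }
  f <- apply(v, 1, eval_fn)
  it_idx <- integer(0); it_cur <- numeric(0); it_best <- numeric(0)
  for (iter in seq_len(config$max_iterations)) {
    o <- simplex_order(f, v)
    v <- v[o, , drop = FALSE]
    f <- f[o]
    centroid <- colMeans(v[seq_len(d), , drop = FALSE])
    worst <- v[d + 1L, ]
    xr <- centroid + config$rho * (centroid - worst)
    fr <- eval_fn(xr)
    if (fr < f[1]) {
      xe <- centroid + config$rho * config$chi * (centroid - worst)
      fe <- eval_fn(xe)
      if (fe < fr) { v[d + 1L, ] <- xe; f[d + 1L] <- fe }
      else { v[d + 1L, ] <- xr; f[d + 1L] <- fr }
    } else if (fr < f[d]) {
      v[d + 1L, ] <- xr; f[d + 1L] <- fr
    } else {
      if (fr < f[d + 1L]) {  # outside contraction
        xc <- centroid + config$gamma * config$rho * (centroid - worst)
        fc <- eval_fn(xc)
        if (fc <= fr) { v[d + 1L, ] <- xc; f[d + 1L] <- fc }
        else { shr <- simplex_shrink(v, f, eval_fn, config$alpha_shrink)
               v <- shr$v; f <- shr$f }
      } else {               # inside contraction
        xc <- centroid - config$gamma * (centroid - worst)
        fc <- eval_fn(xc)
        if (fc < f[d + 1L]) { v[d + 1L, ] <- xc; f[d + 1L] <- fc }
        else { shr <- simplex_shrink(v, f, eval_fn, config$alpha_shrink)
               v <- shr$v; f <- shr$f }
      }
    }
    it_idx <- c(it_idx, iter)
    it_cur <- c(it_cur, min(f))
    it_best <- c(it_best, best_val)
  }
  list(par = best_par, value = best_val,
       trace = tibble::tibble(iteration = it_idx, current_best = it_cur,
                              best_so_far = it_best),
       n_evaluations = n_eval)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

simplex_order <- function(f, v) {
  do.call(order, c(list(f), lapply(seq_len(ncol(v)), function(j) v[, j])))
}

simplex_shrink <- function(v, f, eval_fn, sigma) {
  for (i in 2:nrow(v)) {
    v[i, ] <- v[1, ] + sigma * (v[i, ] - v[1, ])
    f[i] <- eval_fn(v[i, ])
  }
  list(v = v, f = f)
}

#' Detection accuracy of a parameter set over a development set
#'
#' Runs [detect_bedrest()] with the given parameters on every recording of
#' the development set and measures epoch accuracy against each recording's
#' reference labels, either pooled over all compared epochs (the default,
#' matching an epoch-count-weighted development criterion) or as the mean of
#' per-recording accuracies. A recording whose detection fails is excluded
#' with a warning, never silently.
#'
#' @param params A [dt_params()].
#' @param dataset List of recordings, each a list with elements `series` (an
#'   [epoch_series()]), `reference` (aligned reference labels) and
#'   optionally `labels` (pre-existing non-wear flags).
#' @param mode `"pooled"` or `"per_recording_mean"`.
#' @param signal `"vm"` or `"axis1"`.
#' @return Accuracy in `[0, 1]`.
#' @export
dt_objective <- function(params, dataset,
                         mode = c("pooled", "per_recording_mean"),
                         signal = "vm") {
  mode <- match.arg(mode)
  stopifnot(length(dataset) > 0)
  counts <- list()
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    cc <- tryCatch({
      det <- detect_bedrest(rec$series, params, labels = rec$labels,
                            signal = signal)
      confusion(det$labels, rec$reference)
    }, error = function(e) {
      warning(sprintf("recording %d excluded from objective: %s",
                      i, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(cc)) counts[[length(counts) + 1L]] <- cc
  }
  if (length(counts) == 0) stop("no recording could be evaluated", call. = FALSE)
  if (mode == "pooled") {
    tp <- sum(vapply(counts, `[[`, numeric(1), "tp"))
    tn <- sum(vapply(counts, `[[`, numeric(1), "tn"))
    fp <- sum(vapply(counts, `[[`, numeric(1), "fp"))
    fn <- sum(vapply(counts, `[[`, numeric(1), "fn"))
    (tp + tn) / (tp + tn + fp + fn)
  } else {
    mean(vapply(counts, function(cc) performance(cc)[["accuracy"]], numeric(1)))
  }
}

# default starting simplex: the published preschool optimum plus one
# +50% perturbation per coordinate
default_dt_vertices <- function() {
  base <- c(36, 230, 305, 1129)
  v <- rbind(base,
             replace(base, 1, 54),
             replace(base, 2, 345),
             replace(base, 3, 458),
             replace(base, 4, 1694))
  dimnames(v) <- list(NULL, c("block_length", "threshold",
                              "bedrest_start_trigger", "bedrest_end_trigger"))
  v
}

# continuous simplex point -> valid integer-granular dt_params
round_dt_vector <- function(p, min_bedrest_min = 30) {
  dt_params(block_length = max(2, round(p[1])),
            threshold = max(0, round(p[2])),
            bedrest_start_trigger = max(0, round(p[3])),
            bedrest_end_trigger = max(0, round(p[4])),
            min_bedrest_min = min_bedrest_min)
}

#' Optimise decision-tree parameters against reference labels
#'
#' Nelder-Mead search over `(block_length, threshold,
#' bedrest_start_trigger, bedrest_end_trigger)` maximising detection
#' accuracy ([dt_objective()]) on a development set. The simplex moves in
#' continuous space; each vertex is rounded to integer counts (with
#' `block_length >= 2` enforced) when evaluated, matching the epoch-granular
#' meaning of the parameters. The default initial simplex is the published
#' preschool parameter set plus four single-coordinate perturbations, so the
#' search never returns a vertex worse than those defaults on the
#' development set. The minimum bedrest duration is held fixed, not
#' searched.
#'
#' @inheritParams dt_objective
#' @param config A [simplex_config()]; supply `initial_vertices` (5 rows, 4
#'   columns) to override the default simplex.
#' @param min_bedrest_min Fixed minimum bedrest duration in minutes.
#' @return A list with `params` (the best [dt_params()]), `accuracy`,
#'   `trace` (per-iteration tibble; `best_so_far` is the best accuracy,
#'   non-decreasing) and `n_evaluations`.
#' @export
optimize_dt_params <- function(dataset, config = simplex_config(),
                               mode = c("pooled", "per_recording_mean"),
                               signal = "vm", min_bedrest_min = 30) {
  mode <- match.arg(mode)
  vertices <- config$initial_vertices
  if (is.null(vertices)) vertices <- default_dt_vertices()
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != 5L || ncol(vertices) != 4L) {
    stop("the 4-parameter search needs 5 initial vertices of 4 values each",
         call. = FALSE)
  }
  fn <- function(p) {
    -dt_objective(round_dt_vector(p, min_bedrest_min), dataset,
                  mode = mode, signal = signal)
  }
  fit <- nelder_mead(fn, vertices, config)
  trace <- fit$trace
  trace$current_best <- -trace$current_best
  trace$best_so_far <- -trace$best_so_far
  list(params = round_dt_vector(fit$par, min_bedrest_min),
       accuracy = -fit$value,
       trace = trace,
       n_evaluations = fit$n_evaluations)
}
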