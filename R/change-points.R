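# Default detection thresholds, calibrated by Monte-Carlo so that white
# noise of length 95 triggers a false detection in <= 10% of runs: the
# 95th percentile (i.e., a conservative 5% false-positive rate, inside
# the <= 10% contract) of the best-split improvement over 2000
# standard-normal series (seed 20200812;
# data-raw/calibrate-threshold.R regenerates).
# The variance threshold is scale-free (log-likelihood units); the mean
# threshold is in sum-of-squares units of a unit-variance series and is
# rescaled internally by the series variance.

#' Single change-point detection by exhaustive split search
#'
#' A series contains a change point if it can be split into two segments
#' whose summed cost is smaller (by more than `threshold`) than the cost
#' of the whole series.  Two cost functions are available:
#'
#' * `cost_kind = "mean"` — the least-squares cost
#'   \eqn{C(x) = \sum(x-\bar x)^2 = N \cdot var_{pop}(x)}: sensitive to
#'   mean shifts, blind to a pure variance change with equal means.
#' * `cost_kind = "variance"` — the Gaussian variance-change cost
#'   \eqn{C(x) = N \log(\max(var_{pop}(x), \epsilon))} with
#'   \eqn{\epsilon = 10^{-12}}: the likelihood criterion for a changing
#'   variance, the criterion used for phase-transition detection here.
#'
#' The search is exhaustive over all splits leaving at least 2 points in
#' each segment; the returned `index` is 1-based and names the first
#' point of the second segment.  When no split improves the cost by more
#' than the threshold, `index` is `NA` (no change).  The default
#' thresholds are calibrated so white noise of length 95 yields a false
#' positive in at most 10% of runs; for the mean cost the calibrated
#' constant is rescaled by the sample variance of the input so the
#' false-positive contract is scale-free too.
#'
#' @param x Numeric series, length >= 4.
#' @param cost_kind `"variance"` (default) or `"mean"`.
#' @param threshold Minimal cost improvement to accept a change;
#'   `NULL` for the calibrated default.
#' @return A `change_point`: list with `index` (or `NA`), `cost_full`,
#'   `cost_split`, `improvement`, `cost_kind`, `threshold`.
#' @export
detect_change <- function(x, cost_kind = c("variance", "mean"),
                          threshold = NULL) {
  cost_kind <- match.arg(cost_kind)
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 4L, all(is.finite(x)))
  if (is.null(threshold)) {
    threshold <- default_cpa_threshold(cost_kind, x)
  }
  stopifnot(threshold >= 0)

  eps <- 1e-12
  cs1 <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse_full <- cs2[n] - cs1[n]^2 / n
  ks <- 3:(n - 1L)                       # first index of second segment
  n1 <- ks - 1L
  n2 <- n - n1
  sse1 <- cs2[n1] - cs1[n1]^2 / n1
  sse2 <- (cs2[n] - cs2[n1]) - (cs1[n] - cs1[n1])^2 / n2
  sse1 <- pmax(sse1, 0)                  # guard FP cancellation
  sse2 <- pmax(sse2, 0)

  if (cost_kind == "mean") {
    cost_full <- sse_full
    cost_split <- sse1 + sse2
  } else {
    cost_full <- n * log(max(sse_full / n, eps))
    cost_split <- n1 * log(pmax(sse1 / n1, eps)) +
      n2 * log(pmax(sse2 / n2, eps))
  }
  best <- which.min(cost_split)
  improvement <- cost_full - cost_split[best]
  found <- improvement > threshold
  structure(list(
    index = if (found) ks[best] else NA_integer_,
    cost_full = cost_full,
    cost_split = cost_split[best],
    improvement = max(improvement, 0),
    cost_kind = cost_kind,
    threshold = threshold
  ), class = "change_point")
}

# Calibrated default thresholds (see data-raw/calibrate-threshold.R).
# variance: 95th percentile of improvement, white noise N = 95.
# mean: same, per unit variance; rescaled by the sample variance of x.
default_cpa_threshold <- function(cost_kind, x) {
  if (cost_kind == "variance") {
    16.501510
  } else {
    9.439596 * max(stats::var(x), .Machine$double.eps)
  }
}

#' Change-point analysis of every line of a matrix
#'
#' Runs [detect_change()] on each row and/or column of a matrix (a
#' recurrence-distance matrix or a time-frequency amplitude matrix) and
#' aggregates the detected indices into one change location: the
#' statistical mode of the per-line indices, with ties resolved by the
#' median rounded half-up.  Lines with no detected change are skipped;
#' if no line detects one, the aggregate is `NA`.
#'
#' Constant lines (zero variance everywhere) are silently undetectable
#' under the variance cost's epsilon guard, which is the desired
#' behaviour for e.g. the diagonal neighbourhood of a recurrence matrix.
#'
#' @param mat Numeric matrix, at least 4 x 4.
#' @param orientation `"both"` (default), `"rows"`, or `"cols"`.
#' @inheritParams detect_change
#' @return List with `index` (aggregate, `NA` if none), `per_line`
#'   (data.frame: line, orientation, index), `n_detected`.
#' @export
cpa_matrix <- function(mat, orientation = c("both", "rows", "cols"),
                       cost_kind = c("variance", "mean"),
                       threshold = NULL) {
  orientation <- match.arg(orientation)
  cost_kind <- match.arg(cost_kind)
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 4L, ncol(mat) >= 4L)

  run_lines <- function(m, tag) {
    idx <- vapply(seq_len(nrow(m)), function(i) {
      r <- detect_change(m[i, ], cost_kind = cost_kind,
                         threshold = threshold)
      if (is.na(r$index)) NA_integer_ else as.integer(r$index)
    }, integer(1))
    data.frame(line = seq_len(nrow(m)), orientation = tag, index = idx)
  }
  per <- do.call(rbind, c(
    if (orientation %in% c("both", "rows")) list(run_lines(mat, "row")),
    if (orientation %in% c("both", "cols")) list(run_lines(t(mat), "col"))
  ))
  detected <- per$index[!is.na(per$index)]
  list(index = if (length(detected)) mode_or_median(detected) else NA_integer_,
       per_line = per, n_detected = length(detected))
}

#' Ensemble transition index across representations
#'
#' Averages the change points found in the different representations of
#' the same process (charge series, dynamic complexity, recurrence plot,
#' time-frequency distribution) into one transition estimate: the
#' arithmetic mean of the member indices, rounded half-up.  Members with
#' no detected change are excluded and recorded.
#'
#' @param members Named list or named numeric vector of change indices
#'   (`NA` = representation detected nothing).
#' @return An `ensemble_transition`: list with `members` (data.frame
#'   name/index), `mean_index`, `transition_index`, `excluded`.
#' @export
ensemble_transition <- function(members) {
  v <- unlist(members)
  if (is.null(names(v))) names(v) <- paste0("rep", seq_along(v))
  ok <- !is.na(v)
  if (!any(ok)) stop("no transition detected in any representation")
  structure(list(
    members = data.frame(name = names(v)[ok], index = as.numeric(v[ok]),
                         stringsAsFactors = FALSE),
    excluded = names(v)[!ok],
    mean_index = mean(v[ok]),
    transition_index = as.integer(round_half_up(mean(v[ok])))
  ), class = "ensemble_transition")
}

#' @export
print.ensemble_transition <- function(x, ...) {
  cat(sprintf("ensemble transition at index %d (mean %.2f of %d member(s))\n",
              x$transition_index, x$mean_index, nrow(x$members)))
  invisible(x)
}
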