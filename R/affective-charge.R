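#' Euclidean-distance affective charge of each document
#'
#' The charge of document i is the literal Euclidean norm of its
#' squared-cosine vector, \eqn{ed_i = \sqrt{\sum_k (cos^2_{ik})^2}}: the
#' distance of the document from the origin of the factor space.  High
#' values mean the document loads strongly onto one or a few factors
#' (polarized, affect-laden meaning); low values mean its representation
#' is spread thinly over many axes.
#'
#' @param vectors N x K matrix of squared cosines, all components in
#'   \[0, 1\].
#' @return Numeric vector of N distances (>= 0).
#' @export
euclidean_charge <- function(vectors) {
  v <- as.matrix(vectors)
  stopifnot(is.numeric(v), all(is.finite(v)),
            all(v >= -1e-12), all(v <= 1 + 1e-12))
  sqrt(rowSums(v^2))
}

#' Classify documents against the centroid of the charge series
#'
#' The centroid radius is the arithmetic mean of all Euclidean
#' distances.  Documents with a distance strictly greater than the mean
#' lie outside the centroid (label 2, highly charged); all others,
#' including exact ties, lie inside (label 1).  Equality is "not
#' greater", so ties are inside.
#'
#' @param ed Numeric vector of Euclidean distances, length >= 2.
#' @return A `charge_series`: list with `ed`, `centroid_radius`,
#'   `labels` (1 = inside, 2 = outside), `time_index`, `n_inside`,
#'   `n_outside`, `pct_inside`, `pct_outside`.
#' @export
centroid_classify <- function(ed) {
  ed <- as.numeric(ed)
  stopifnot(length(ed) >= 2L, all(is.finite(ed)), all(ed >= 0))
  radius <- mean(ed)
  if (all(ed == ed[1])) {
    warning("all distances identical: degenerate threshold, all inside")
  }
  labels <- ifelse(ed > radius, 2L, 1L)
  n <- length(ed)
  structure(list(
    ed = ed,
    centroid_radius = radius,
    labels = labels,
    time_index = seq_len(n),
    n_inside = sum(labels == 1L),
    n_outside = sum(labels == 2L),
    pct_inside = 100 * sum(labels == 1L) / n,
    pct_outside = 100 * sum(labels == 2L) / n
  ), class = "charge_series")
}

#' @export
print.charge_series <- function(x, ...) {
  cat(sprintf(
    "charge_series: n = %d, centroid radius = %.4f\n  inside: %d (%.1f%%)  outside: %d (%.1f%%)\n",
    length(x$ed), x$centroid_radius,
    x$n_inside, x$pct_inside, x$n_outside, x$pct_outside))
  invisible(x)
}

#' Write a charge series as TSV plus a JSON summary
#' @param cs A `charge_series`.
#' @param prefix Path prefix (files `<prefix>.tsv`, `<prefix>.json`).
#' @export
write_charge_series <- function(cs, prefix) {
  utils::write.table(
    data.frame(index = cs$time_index, ed = cs$ed, label = cs$labels),
    paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(centroid_radius = cs$centroid_radius,
         n_inside = cs$n_inside, n_outside = cs$n_outside,
         pct_inside = cs$pct_inside, pct_outside = cs$pct_outside),
    paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}
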