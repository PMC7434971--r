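#' Windowed dynamic complexity of a time series
#'
#' Dynamic complexity is the product C = F * D computed in a moving
#' window (width 7, step 1 by default) over a series with a known scale
#' range \[`scale_min`, `scale_max`\].
#'
#' The fluctuation measure F sums the absolute amplitudes between
#' successive direction-change points of the window (its first and last
#' points plus every interior local extremum) and normalizes by the
#' maximal possible per-step excursion, `s * (m - 1)` with
#' `s = scale_max - scale_min`.  F is 1 for a full-range alternation and
#' 0 for a constant window.
#'
#' The distribution measure D compares the ascending-sorted window
#' values against an ideal uniform spread over the scale: with ideal gap
#' `I = s/(m - 1)`, \eqn{D = 1 - \sum_{i<j}\max(0, (j-i)I -
#' (y_{(j)}-y_{(i)})) / \sum_{i<j}(j-i)I}.  D is 1 when the values are
#' exactly evenly spread over the range and 0 for a constant window.
#'
#' Each window's value is attributed to the window's *last* index, so a
#' complexity rise never anticipates the data that caused it.
#'
#' @param x Numeric series, all values inside the scale range.
#' @param window Window width m (default 7, minimum 4).
#' @param scale Numeric length-2 range; defaults to the observed
#'   `range(x)` (logged in the result) because affective-charge series
#'   have no a-priori instrument range.
#' @return A `dc_profile`: list with `fluctuation`, `distribution`,
#'   `complexity` (each length `N - window + 1`), `positions` (original
#'   indices of window ends), `window`, `scale`.
#' @export
dynamic_complexity <- function(x, window = 7L, scale = range(x)) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= window, window >= 4L, length(scale) == 2L)
  s <- scale[2] - scale[1]
  if (s <= 0) stop("scale range must have positive width")
  bad <- which(x < scale[1] - 1e-12 | x > scale[2] + 1e-12)
  if (length(bad)) stop("value(s) outside scale range at index ", bad[1])

  m <- as.integer(window)
  n_win <- n - m + 1L
  Fv <- Dv <- numeric(n_win)
  ideal <- s / (m - 1)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  gap_steps <- pairs[, 2] - pairs[, 1]
  denomD <- sum(gap_steps) * ideal
  for (w in seq_len(n_win)) {
    win <- x[w:(w + m - 1L)]
    Fv[w] <- sum(abs(diff(win[turning_points(win)]))) / (s * (m - 1))
    y <- sort(win)
    short <- pmax(0, gap_steps * ideal - (y[pairs[, 2]] - y[pairs[, 1]]))
    Dv[w] <- 1 - sum(short) / denomD
  }
  structure(list(
    fluctuation = Fv, distribution = Dv, complexity = Fv * Dv,
    positions = seq.int(m, n), window = m, scale = scale
  ), class = "dc_profile")
}

# Indices of the direction-change points of a window: first, last, and
# every interior local extremum.  Plateaus are handled by looking at the
# sign pattern of the nonzero successive differences; either plateau
# endpoint yields the same amplitude sum, we take the later one.
turning_points <- function(w) {
  dx <- diff(w)
  nz <- which(dx != 0)
  if (length(nz) < 2L) return(c(1L, length(w)))
  sgn <- sign(dx[nz])
  turn <- nz[which(diff(sgn) != 0)] + 1L
  unique(c(1L, turn, length(w)))
}

#' Unthresholded recurrence (distance) matrix of a delay embedding
#'
#' Snippets of the series are embedded as time-delay vectors
#' \eqn{v_t = (x_t, x_{t+\tau}, \ldots, x_{t+(m-1)\tau})}; the matrix
#' holds the Euclidean distances between all pairs of snippet vectors.
#' Recurrent epochs appear as low-distance blocks, transients as
#' high-distance bands; no recurrence threshold is applied.
#'
#' @param x Numeric series with `length(x) >= (m - 1) * tau + 2`.
#' @param m Embedding dimension (snippet length, default 3).
#' @param tau Time delay (default 1, the first ACF zero crossing /
#'   minimum in the motivating application).
#' @return A `recurrence_matrix`: list with `dist` (T x T, symmetric,
#'   zero diagonal, T = N - (m-1) tau), `m`, `tau`.
#' @export
recurrence_matrix <- function(x, m = 3L, tau = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(m >= 1L, tau >= 1L)
  TT <- n - (m - 1L) * tau
  if (TT < 2L) stop("series too short for embedding: need N >= (m-1)*tau + 2")
  V <- vapply(0:(m - 1L), function(j) x[(1:TT) + j * tau], numeric(TT))
  V <- matrix(V, nrow = TT)
  D <- as.matrix(stats::dist(V))
  dimnames(D) <- NULL
  structure(list(dist = D, m = as.integer(m), tau = as.integer(tau)),
            class = "recurrence_matrix")
}

#' Discrete Stockwell (S-) transform time-frequency distribution
#'
#' Frequency-domain implementation: for voice n > 0 the transform is the
#' inverse FFT of the spectrum shifted by n and multiplied by a sampled
#' Gaussian \eqn{\exp(-2\pi^2 m^2/n^2)}; the zero-frequency voice is the
#' signal mean at all times.  The window width scales inversely with
#' frequency, combining the short-time Fourier transform's phase
#' retention with the wavelet transform's variable resolution.  Only
#' non-negative frequencies are returned (real input).
#'
#' The time average of each complex voice equals the (1/N-normalized)
#' DFT coefficient at that frequency; this identity is the module's
#' internal consistency check.
#'
#' @param x Real numeric series, `length(x) >= 8`.
#' @param demean If `TRUE`, remove the series mean first (display
#'   variant); the default keeps it so the zero-voice contract holds.
#' @return A `tfd_matrix`: list with `amplitude`
#'   (`(floor(N/2)+1) x N`, non-negative), `voices` (same shape,
#'   complex), `freq_bins` (0..floor(N/2)).
#' @export
stockwell_tfd <- function(x, demean = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 8L, all(is.finite(x)))
  if (demean) x <- x - mean(x)
  H <- stats::fft(x)
  n_voice <- floor(n / 2) + 1L
  S <- matrix(0 + 0i, n_voice, n)
  S[1, ] <- mean(x)
  # wrapped frequency offsets for the Gaussian localizing window
  m_off <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  for (f in seq_len(n_voice - 1L)) {
    Hs <- H[((f + 0:(n - 1L)) %% n) + 1L]
    G <- exp(-2 * pi^2 * m_off^2 / f^2)
    S[f + 1L, ] <- stats::fft(Hs * G, inverse = TRUE) / n
  }
  structure(list(amplitude = Mod(S), voices = S,
                 freq_bins = 0:(n_voice - 1L)),
            class = "tfd_matrix")
}
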