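# Sliding-window parabola regression: fit y'(j) = a (i - j)^2 + v on the
# window j in [i - w, i + w] and score the fit by the quadratic-mean error
#   eps(i) = mean_j (y(j) - y'(j))^2 .
# Substituting x = (i - j)^2 turns the fit into simple linear regression of
# y on x; a and v come from the closed-form slope/intercept solution. The
# regressor depends only on the offset d = j - i, so the sums Sx = sum d^2
# and Sxx = sum d^4 are window constants and the profile over all centres
# reduces to moving sums of y, y^2 and d^2 * y.

#' Round half away from zero
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Analysis half-widths for R-peak and P/Q/S/T detection
#'
#' The wide window is sized to the R apex (half-width `0.030 * fs` samples);
#' the narrow window to the smallest wave, Q (`0.012 * fs`). Non-integer
#' values are rounded half away from zero, with a floor of 1 sample. At
#' `fs = 500` these give half-widths 15 and 6, i.e. window lengths 31 and 13.
#'
#' @param fs Sampling frequency in Hz.
#' @return Integer half-width `w`; the full window length is `2 * w + 1`.
#' @examples
#' r_window_halfwidth(500)      # 15
#' pqrst_window_halfwidth(500)  # 6
#' @export
r_window_halfwidth <- function(fs) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  max(1L, as.integer(round_half_away(0.030 * fs)))
}

#' @rdname r_window_halfwidth
#' @export
pqrst_window_halfwidth <- function(fs) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  max(1L, as.integer(round_half_away(0.012 * fs)))
}

#' Fit a vertex-centred parabola to one window
#'
#' Least-squares fit of `y'(j) = a * (center - j)^2 + v` to the samples on
#' `[center - w, center + w]`. With the substitution `x = (center - j)^2`
#' this is simple linear regression; `a` (the opening coefficient,
#' mV/sample^2) and `v` (the vertex amplitude, mV) are the closed-form
#' slope and intercept. `epsilon` is the mean squared residual over the
#' `2w + 1` window samples (mV^2).
#'
#' Sign convention: because `x >= 0` grows away from the centre, an upward
#' peak centred in the window yields `a < 0` and a downward peak `a > 0`;
#' line-like stretches give `|a|` near zero.
#'
#' @param signal An [ecg_signal()].
#' @param center 0-based centre index `i`; must satisfy
#'   `w <= center <= N - w - 1`.
#' @param w Half-width in samples (`>= 1`, `2w + 1 < N`).
#' @return A list of class `window_fit` with elements `center`, `a`, `v`,
#'   `epsilon`.
#' @seealso [error_profile()] for the vectorised sweep over all centres.
#' @export
fit_parabola_window <- function(signal, center, w) {
  signal <- as_ecg_signal(signal, fs = NA)
  n <- length(signal$samples)
  w <- as.integer(w)
  if (w < 1L) stop("`w` must be >= 1", call. = FALSE)
  if (2L * w + 1L >= n) stop("window length 2w+1 must be < signal length", call. = FALSE)
  if (center < w || center > n - w - 1L)
    stop("`center` must lie in [w, N-w-1]; window exceeds signal bounds", call. = FALSE)
  d <- seq.int(-w, w)
  x <- as.numeric(d)^2
  y <- signal$samples[center + d + 1L]
  m <- 2 * w + 1
  sx <- sum(x); sxx <- sum(x^2)
  sy <- sum(y); sxy <- sum(x * y)
  den <- m * sxx - sx^2
  a <- (m * sxy - sx * sy) / den
  v <- (sxx * sy - sxy * sx) / den
  eps <- mean((y - (a * x + v))^2)
  structure(list(center = as.integer(center), a = a, v = v, epsilon = eps),
            class = "window_fit")
}

#' Parabola-fit error profile over all admissible centres
#'
#' Sweeps the `2w + 1` window across the whole signal and returns, for each
#' centre `i` in `w, ..., N - w - 1`, the fitted opening coefficient `a`,
#' vertex amplitude `v` and quadratic-mean fit error `epsilon`. Low values
#' of `epsilon` mark centres where the signal is locally parabolic -- wave
#' apices, but also straight-line stretches, which are told apart by the
#' magnitude of `a`.
#'
#' The sweep is computed with moving sums and is numerically identical (to
#' well below 1e-12 relative) to calling [fit_parabola_window()] at every
#' centre.
#'
#' @param signal An [ecg_signal()].
#' @param w Half-width in samples.
#' @return An object of class `fit_profile`: a list with `center`
#'   (0-based integer vector), `a`, `v`, `epsilon` (numeric vectors of
#'   length `N - 2w`), plus `w` and `fs`.
#' @export
error_profile <- function(signal, w) {
  stopifnot(inherits(signal, "ecg_signal"))
  y <- signal$samples
  n <- length(y)
  w <- as.integer(w)
  if (w < 1L) stop("`w` must be >= 1", call. = FALSE)
  m <- 2L * w + 1L
  if (m >= n) stop("signal too short for window of length ", m, call. = FALSE)

  d <- as.numeric(seq.int(-w, w))
  x <- d^2
  sx <- sum(x); sxx <- sum(x^2)
  den <- (m * sxx - sx^2)

  # rows of Y are the windows, columns the offsets -w..w
  Y <- stats::embed(y, m)[, m:1, drop = FALSE]
  sy <- Y %*% rep(1, m)
  sxy <- Y %*% x
  a <- as.numeric(m * sxy - sx * sy) / den
  v <- as.numeric(sxx * sy - sxy * sx) / den
  resid <- Y - outer(a, x) - v
  eps <- rowMeans(resid^2)

  structure(list(center = seq.int(w, n - w - 1L), a = a, v = v,
                 epsilon = eps, w = w, fs = signal$fs),
            class = "fit_profile")
}

#' @export
print.fit_profile <- function(x, ...) {
  cat(sprintf("<fit_profile> %d centres (w = %d, window %d samples), eps in [%.3g, %.3g] mV^2\n",
              length(x$center), x$w, 2 * x$w + 1,
              min(x$epsilon), max(x$epsilon)))
  invisible(x)
}
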