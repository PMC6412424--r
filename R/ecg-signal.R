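#' Construct an ECG signal object
#'
#' A uniformly sampled single-lead voltage sequence. Sample indices are
#' 0-based throughout the package, so the time of sample `i` is `i / fs`
#' seconds.
#'
#' @param samples Numeric vector of voltages in millivolts; all finite,
#'   length at least 2.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param record_id Free-text label carried through to annotations.
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs` and `record_id`.
#' @examples
#' sig <- ecg_signal(sin(seq(0, 2 * pi, length.out = 500)), fs = 500)
#' sig
#' @export
ecg_signal <- function(samples, fs, record_id = "ecg") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("an ECG signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("ECG samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)", call. = FALSE)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         record_id = as.character(record_id)[1L]),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<ecg_signal> '%s': %d samples @ %g Hz (%.3f s), range [%.3f, %.3f] mV\n",
              x$record_id, n, x$fs, n / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Extract a window of an ECG signal
#'
#' Returns the samples on the closed 0-based index range `[from, to]` as a
#' new `ecg_signal` with the same sampling frequency. Out-of-range portions
#' are zero-padded when `pad = TRUE`, otherwise an error is raised.
#'
#' @param signal An [ecg_signal()].
#' @param from,to 0-based first and last sample index of the window.
#' @param pad Zero-pad out-of-range samples instead of erroring.
#' @return `ecg_signal` of length `to - from + 1`, with attribute `padded`
#'   (logical) when padding occurred.
#' @keywords internal
ecg_window <- function(signal, from, to, pad = FALSE) {
  n <- length(signal$samples)
  if (from > to) stop("empty window", call. = FALSE)
  inside <- from >= 0L && to <= n - 1L
  if (!inside && !pad)
    stop("window [", from, ", ", to, "] exceeds signal bounds", call. = FALSE)
  idx <- seq.int(from, to)
  out <- numeric(length(idx))
  keep <- idx >= 0L & idx <= n - 1L
  out[keep] <- signal$samples[idx[keep] + 1L]
  w <- ecg_signal(out, signal$fs, signal$record_id)
  attr(w, "padded") <- !inside
  w
}

as_ecg_signal <- function(x, fs, record_id = "ecg") {
  if (inherits(x, "ecg_signal")) return(x)
  ecg_signal(x, fs, record_id)
}
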