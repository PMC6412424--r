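# Preprocessing: Butterworth low-pass (default order 10, 100 Hz cut-off)
# and baseline-wander removal by subtracting an order-8 least-squares
# polynomial fitted over the whole record.

#' Low-pass filter specification
#'
#' @param order Filter order (default 10).
#' @param cutoff_hz Cut-off frequency in Hz (default 100); must be below
#'   the Nyquist frequency of the signal it is applied to.
#' @param zero_phase Apply forward-backward (zero-phase) filtering so that
#'   peak positions are not shifted. Default `TRUE`; causal filtering would
#'   delay every fiducial point by the filter's group delay.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(order = 10L, cutoff_hz = 100, zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = as.numeric(cutoff_hz),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Butterworth low-pass filtering
#'
#' Applies a Butterworth low-pass filter (default: order 10, cut-off
#' 100 Hz, the upper edge of the diagnostic ECG band). Zero-phase
#' forward-backward filtering is the default so peaks are attenuated but
#' never displaced. The signal is reflect-padded at both ends (ten
#' nominal filter lengths, enough for the order-10 startup transient to
#' decay below 1e-9) before filtering; the padding is then stripped.
#'
#' @param signal An [ecg_signal()].
#' @param spec A [filter_spec()].
#' @return Filtered `ecg_signal`, same length and sampling frequency.
#' @export
lowpass_filter <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(spec, "filter_spec"))
  nyq <- signal$fs / 2
  if (spec$cutoff_hz >= nyq)
    stop("cutoff (", spec$cutoff_hz, " Hz) must be below Nyquist (", nyq, " Hz)",
         call. = FALSE)
  y <- signal$samples
  n <- length(y)
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  np <- min(n - 1L, max(100L, 10L * (spec$order + 1L)))
  # reflect about the end points: x[np+1], ..., x[2], x[1..n], x[n-1], ...
  padded <- c(y[(np + 1L):2L], y, y[(n - 1L):(n - np)])
  if (spec$zero_phase) {
    f <- as.numeric(signal::filter(bf, padded))
    f <- rev(as.numeric(signal::filter(bf, rev(f))))
  } else {
    f <- as.numeric(signal::filter(bf, padded))
  }
  out <- f[(np + 1L):(np + n)]
  ecg_signal(out, signal$fs, signal$record_id)
}

#' Fit a polynomial baseline model
#'
#' Least-squares polynomial of the given order (default 8) fitted to the
#' samples as a function of the sample index. Internally the index is
#' normalised to `[0, 1]` (index / (N - 1)) before building the Vandermonde
#' basis: a raw-index basis at order 8 over 1e4 samples is numerically
#' singular. Coefficients are reported in that normalised basis, in
#' descending order of power, and [remove_baseline()] evaluates them the
#' same way, so round-tripping is exact.
#'
#' @param signal An [ecg_signal()].
#' @param order Polynomial order (default 8); must satisfy
#'   `order < N - 1`.
#' @return List of class `baseline_model` with `coefficients` (length
#'   `order + 1`, descending powers of the normalised index) and `order`.
#' @export
fit_baseline <- function(signal, order = 8L) {
  stopifnot(inherits(signal, "ecg_signal"))
  order <- as.integer(order)
  n <- length(signal$samples)
  if (order < 0L) stop("`order` must be >= 0", call. = FALSE)
  if (order >= n - 1L)
    stop("`order` must be < N - 1 (N = ", n, ")", call. = FALSE)
  u <- seq.int(0L, n - 1L) / (n - 1)
  X <- outer(u, order:0, `^`)
  fit <- stats::lm.fit(X, signal$samples)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  structure(list(coefficients = coefs, order = order, n = n),
            class = "baseline_model")
}

#' Evaluate a baseline model at every sample index
#' @param model A `baseline_model` from [fit_baseline()].
#' @param n Number of samples of the index domain.
#' @return Numeric vector of length `n`.
#' @keywords internal
eval_baseline <- function(model, n) {
  u <- seq.int(0L, n - 1L) / (n - 1)
  drop(outer(u, model$order:0, `^`) %*% model$coefficients)
}

#' Subtract a fitted baseline from a signal
#'
#' Evaluates the polynomial baseline at every sample index and subtracts
#' it, recentring the trace on its isoelectric line.
#'
#' @param signal An [ecg_signal()].
#' @param model A `baseline_model` fitted on the same index domain
#'   (same `N`).
#' @return Baseline-corrected `ecg_signal`.
#' @export
remove_baseline <- function(signal, model) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(model, "baseline_model"))
  n <- length(signal$samples)
  if (!is.null(model$n) && model$n != n)
    stop("baseline model was fitted on a different index domain (N = ",
         model$n, " vs ", n, ")", call. = FALSE)
  ecg_signal(signal$samples - eval_baseline(model, n), signal$fs,
             signal$record_id)
}

#' Standard preprocessing chain
#'
#' Low-pass filtering followed by polynomial baseline removal, with the
#' package defaults (Butterworth order 10 at 100 Hz, zero-phase; baseline
#' order 8).
#'
#' @param signal An [ecg_signal()].
#' @param spec A [filter_spec()]; `NULL` skips filtering.
#' @param baseline_order Polynomial order for baseline removal; `NULL`
#'   skips the baseline step.
#' @return Preprocessed `ecg_signal`.
#' @export
preprocess_ecg <- function(signal, spec = filter_spec(), baseline_order = 8L) {
  out <- signal
  if (!is.null(spec)) out <- lowpass_filter(out, spec)
  if (!is.null(baseline_order))
    out <- remove_baseline(out, fit_baseline(out, baseline_order))
  out
}
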