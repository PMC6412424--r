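# Beat segmentation: fixed-width windows centred on the interior R peaks.
# The first and last detected R serve only as a reference frame, so a
# record with k detected R waves yields k - 2 beats.

#' Mean R-R interval
#'
#' Arithmetic mean of the distances between consecutive R peaks, in
#' samples.
#'
#' @param r_indices Strictly increasing integer vector of R sample
#'   indices, length at least 2.
#' @return Mean spacing in samples (numeric scalar).
#' @examples
#' mean_rr(c(0, 384, 769))  # 384.5
#' @export
mean_rr <- function(r_indices) {
  r_indices <- as.numeric(r_indices)
  if (length(r_indices) < 2L)
    stop("need at least 2 R peaks to compute a mean R-R interval", call. = FALSE)
  if (any(diff(r_indices) <= 0))
    stop("`r_indices` must be strictly increasing", call. = FALSE)
  mean(diff(r_indices))
}

#' Beat-segmentation window from the mean R-R interval
#'
#' Half the mean spacing, rounded half away from zero, gives the shift
#' applied forward and back from each R; the window length is
#' `2 * half + 1`. A mean spacing of 384.28 samples yields half-width 192
#' and window length 385.
#'
#' @param mean_rr Mean R-R spacing in samples (positive).
#' @return List with `half_width` and `window_length` (integers).
#' @export
segmentation_window <- function(mean_rr) {
  stopifnot(is.numeric(mean_rr), length(mean_rr) == 1L, mean_rr > 0)
  half <- max(1L, as.integer(round_half_away(mean_rr / 2)))
  list(half_width = half, window_length = 2L * half + 1L)
}

#' Segment a record into beat windows
#'
#' Extracts a fixed-width window `[r - half, r + half]` around every
#' interior R peak (the first and last are excluded as the reference
#' frame). Windows that overrun the record edge -- possible with irregular
#' rhythm -- are zero-padded symmetrically and flagged.
#'
#' @param signal An [ecg_signal()].
#' @param r_indices Strictly increasing 0-based R peak indices, length
#'   at least 3.
#' @param half_width Optional half-width override in samples; defaults to
#'   [segmentation_window()] of the mean R-R interval.
#' @return Object of class `beat_matrix`: list with `beats` (numeric
#'   matrix, one beat per row), `window_length`, `half_width`, `r_offset`
#'   (index of R within each window, equal to `half_width`),
#'   `source_r_indices`, `padded` (logical per beat), `fs`, `record_id`.
#' @export
segment_beats <- function(signal, r_indices, half_width = NULL) {
  stopifnot(inherits(signal, "ecg_signal"))
  r_indices <- as.integer(r_indices)
  if (length(r_indices) < 3L)
    stop("need at least 3 R peaks to segment (first and last are the reference frame)",
         call. = FALSE)
  if (is.null(half_width))
    half_width <- segmentation_window(mean_rr(r_indices))$half_width
  half_width <- as.integer(half_width)
  interior <- r_indices[-c(1L, length(r_indices))]
  wl <- 2L * half_width + 1L
  beats <- matrix(0, nrow = length(interior), ncol = wl)
  padded <- logical(length(interior))
  for (k in seq_along(interior)) {
    wdw <- ecg_window(signal, interior[k] - half_width,
                      interior[k] + half_width, pad = TRUE)
    beats[k, ] <- wdw$samples
    padded[k] <- isTRUE(attr(wdw, "padded"))
  }
  structure(list(beats = beats, window_length = wl, half_width = half_width,
                 r_offset = half_width, source_r_indices = interior,
                 padded = padded, fs = signal$fs, record_id = signal$record_id),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix> %d beats x %d samples (half-width %d, R at offset %d)%s\n",
              nrow(x$beats), x$window_length, x$half_width, x$r_offset,
              if (any(x$padded)) sprintf(", %d edge-padded", sum(x$padded)) else ""))
  invisible(x)
}

#' Write a beat matrix as delimited text (one beat per row)
#' @param x A `beat_matrix`.
#' @param path Output file path.
#' @export
write_beat_matrix <- function(x, path) {
  stopifnot(inherits(x, "beat_matrix"))
  utils::write.table(x$beats, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
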