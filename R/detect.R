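# Peak detection from the parabola-fit error profile. Candidate apices are
# strict local minima of eps(i); the opening coefficient a separates waves
# (|a| large) from line-like stretches (|a| small) and its sign separates
# maxima (a < 0) from minima (a > 0).

#' Detector configuration
#'
#' Thresholds for R-peak detection, isoelectric-level estimation and
#' P/Q/S/T delineation. The opening-coefficient thresholds are in
#' mV/sample^2 and therefore depend on gain and sampling rate: the defaults
#' hold for mV-scaled signals at 500 Hz, and scale as `(fs / 500)^2` for
#' other rates (a parabola of fixed physical curvature steepens per-sample
#' as the rate drops).
#'
#' @param a_min_r Minimum `|a|` for an error minimum to count as an R apex
#'   (default 5e-4 mV/sample^2).
#' @param a_max_iso Maximum `|a|` for a centre to count as line-like when
#'   estimating the isoelectric level (default 1e-4); also the magnitude
#'   floor for small-wave candidates.
#' @param eps_max_iso Maximum fit error for isoelectric centres
#'   (default 0.01 mV^2).
#' @param upper_margin,lower_margin Amplitude margins (mV) above/below the
#'   isoelectric level that a positive/negative wave must clear to be kept
#'   (default 0.08 each). Data-dependent: set them just below the smallest
#'   wave of interest.
#' @param min_peak_distance_ms Minimum distance between retained same-polarity
#'   peaks during delineation (default 40 ms); on conflict the peak farther
#'   from the isoelectric level wins.
#' @param r_refractory_ms Minimum R-R distance (default 200 ms, a 300 bpm
#'   ceiling); closer R candidates collapse to the one with largest `|a|`.
#' @param p_search_ms,t_search_ms How far before (after) R the P (T) apex
#'   may lie, in ms (defaults 300 and 400, generous clinical PR / R-to-T
#'   bounds). They condition the delineation distances to both sides of R
#'   so that a beat window overlapping its neighbour never labels the
#'   neighbour's waves.
#' @param sensitivity_tolerance_ms Temporal tolerance used when benchmarking
#'   detections against references (default 10 ms).
#' @return List of class `detector_config`.
#' @export
detector_config <- function(a_min_r = 5e-4,
                            a_max_iso = 1e-4,
                            eps_max_iso = 0.01,
                            upper_margin = 0.08,
                            lower_margin = 0.08,
                            min_peak_distance_ms = 40,
                            r_refractory_ms = 200,
                            p_search_ms = 300,
                            t_search_ms = 400,
                            sensitivity_tolerance_ms = 10) {
  cfg <- list(a_min_r = a_min_r, a_max_iso = a_max_iso,
              eps_max_iso = eps_max_iso,
              upper_margin = upper_margin, lower_margin = lower_margin,
              min_peak_distance_ms = min_peak_distance_ms,
              r_refractory_ms = r_refractory_ms,
              p_search_ms = p_search_ms, t_search_ms = t_search_ms,
              sensitivity_tolerance_ms = sensitivity_tolerance_ms)
  num <- vapply(cfg, function(z) is.numeric(z) && length(z) == 1L && is.finite(z),
                logical(1))
  if (!all(num)) stop("all config fields must be finite scalars", call. = FALSE)
  if (any(unlist(cfg) <= 0)) stop("all thresholds must be > 0", call. = FALSE)
  if (cfg$min_peak_distance_ms >= cfg$r_refractory_ms)
    stop("min_peak_distance_ms must be < r_refractory_ms", call. = FALSE)
  structure(cfg, class = "detector_config")
}

#' Candidate peaks: local minima of the fit-error signal
#'
#' Scans the error profile for strict local minima of `epsilon` (the
#' centre of an `eps[i-2] > eps[i-1] < eps[i]` triplet); plateaus of equal
#' minima report their leftmost centre. Candidates must additionally have
#' `|a|` above `a_magnitude_min`, and a sign matching `sign_filter`
#' (`"max"` keeps `a < 0`, i.e. upward peaks; `"min"` keeps `a > 0`;
#' `"either"` keeps both).
#'
#' @param profile A [error_profile()] result.
#' @param a_magnitude_min Magnitude floor on the opening coefficient.
#' @param sign_filter `"max"`, `"min"` or `"either"`.
#' @return Integer vector of candidate centre indices (0-based, absolute),
#'   possibly empty, sorted increasing.
#' @export
find_error_minima <- function(profile, a_magnitude_min,
                              sign_filter = c("either", "max", "min")) {
  stopifnot(inherits(profile, "fit_profile"))
  sign_filter <- match.arg(sign_filter)
  eps <- profile$epsilon
  if (length(eps) < 3L) return(integer())
  # run-length compression makes the plateau tie-break exact: a run is a
  # local minimum iff both neighbouring runs are higher; report its left end
  r <- rle(eps)
  k <- length(r$values)
  if (k < 3L) return(integer())
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_min <- c(FALSE, r$values[2:(k - 1)] < r$values[1:(k - 2)] &
                     r$values[2:(k - 1)] < r$values[3:k], FALSE)
  pos <- starts[is_min]                      # 1-based offset into profile
  if (!length(pos)) return(integer())
  a <- profile$a[pos]
  keep <- abs(a) > a_magnitude_min
  keep <- keep & switch(sign_filter,
                        max = a < 0, min = a > 0, either = TRUE)
  sort(profile$center[pos[keep]])
}

# collapse candidates closer than min_dist samples; `score` decides the
# survivor (largest wins). Greedy from the best-scoring candidate.
collapse_close_peaks <- function(idx, score, min_dist) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(score, decreasing = TRUE)
  kept <- integer()
  for (k in ord) {
    if (!length(kept) || all(abs(idx[k] - idx[kept]) >= min_dist))
      kept <- c(kept, k)
  }
  sort(idx[kept])
}

#' Detect R peaks
#'
#' Sweeps the wide analysis window (half-width `0.030 * fs`) over a
#' preprocessed signal, takes upward-peak error minima with
#' `|a| > a_min_r`, and collapses candidates closer than the R refractory
#' distance to the one with the steepest parabola.
#'
#' @param signal A preprocessed [ecg_signal()].
#' @param config A [detector_config()].
#' @return A [fiducial_annotations()] table containing only R rows
#'   (possibly zero rows), sorted by index; amplitudes are the fitted
#'   vertex values.
#' @export
detect_r_peaks <- function(signal, config = detector_config()) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(config, "detector_config"))
  w <- r_window_halfwidth(signal$fs)
  prof <- error_profile(signal, w)
  detect_r_peaks_from_profile(prof, signal, config)
}

detect_r_peaks_from_profile <- function(prof, signal, config) {
  cand <- find_error_minima(prof, config$a_min_r, "max")
  if (!length(cand))
    return(fiducial_annotations(fs = signal$fs, record_id = signal$record_id))
  pos <- match(cand, prof$center)
  refr <- config$r_refractory_ms / 1000 * signal$fs
  kept <- collapse_close_peaks(cand, abs(prof$a[pos]), refr)
  kpos <- match(kept, prof$center)
  fiducial_annotations(rep("R", length(kept)), kept, prof$v[kpos],
                       fs = signal$fs, record_id = signal$record_id)
}

#' Estimate the isoelectric level
#'
#' Averages the signal over all centres whose local fit is both flat
#' (`|a| < a_max_iso`) and accurate (`epsilon < eps_max_iso`): the
#' stretches where the parabola degenerates into a horizontal line, i.e.
#' the isoelectric segments between waves. If no centre qualifies the
#' signal median is returned with a warning.
#'
#' @param signal A preprocessed [ecg_signal()].
#' @param config A [detector_config()].
#' @param profile Optional precomputed [error_profile()] at the R
#'   half-width, to avoid recomputation.
#' @return Scalar isoelectric level in mV.
#' @export
estimate_isoelectric_level <- function(signal, config = detector_config(),
                                       profile = NULL) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(config, "detector_config"))
  if (is.null(profile))
    profile <- error_profile(signal, r_window_halfwidth(signal$fs))
  flat <- abs(profile$a) < config$a_max_iso & profile$epsilon < config$eps_max_iso
  if (!any(flat)) {
    warning("no line-like centres found; falling back to the signal median",
            call. = FALSE)
    return(stats::median(signal$samples))
  }
  mean(signal$samples[profile$center[flat] + 1L])
}

#' Delineate P, Q, S, T within one beat
#'
#' Runs the narrow window (half-width `0.012 * fs`, sized to the Q wave)
#' over a single beat, keeps error minima of either polarity whose vertex
#' clears the amplitude margins around the isoelectric level (maxima must
#' exceed `iso + upper_margin`, minima fall below `iso - lower_margin`),
#' enforces the minimum peak distance among same-polarity candidates
#' (the wave farther from the isoelectric level wins), and labels relative
#' to R: Q is the nearest minimum before R, S the nearest after, P the
#' largest-amplitude maximum before Q, T the largest after S. Waves that
#' fail the margins are reported absent rather than mislabelled -- the
#' mechanism behind the known Q-wave failure mode when Q is shallower than
#' the margin.
#'
#' @param beat An [ecg_signal()] holding one beat window.
#' @param r_index_in_beat 0-based index of the R apex within the beat.
#' @param iso_level Isoelectric level (mV) estimated on the full record.
#' @param config A [detector_config()].
#' @return [fiducial_annotations()] with up to five rows (indices relative
#'   to the beat window).
#' @export
detect_pqrst <- function(beat, r_index_in_beat, iso_level,
                         config = detector_config()) {
  stopifnot(inherits(beat, "ecg_signal"), inherits(config, "detector_config"))
  n <- length(beat$samples)
  r0 <- as.integer(r_index_in_beat)
  if (r0 < 0L || r0 > n - 1L)
    stop("`r_index_in_beat` outside the beat window", call. = FALSE)
  fs <- beat$fs
  w <- pqrst_window_halfwidth(fs)
  empty <- fiducial_annotations(fs = fs, record_id = beat$record_id)
  if (2L * w + 1L >= n) return(empty)
  prof <- error_profile(beat, w)
  cand <- find_error_minima(prof, config$a_max_iso, "either")
  if (!length(cand)) {
    return(fiducial_annotations("R", r0, beat$samples[r0 + 1L],
                                fs = fs, record_id = beat$record_id))
  }
  pos <- match(cand, prof$center)
  a <- prof$a[pos]; v <- prof$v[pos]
  is_max <- a < 0
  keep <- (is_max & v > iso_level + config$upper_margin) |
          (!is_max & v < iso_level - config$lower_margin)
  cand <- cand[keep]; v <- v[keep]; is_max <- is_max[keep]

  # same-polarity de-duplication; Q-R and S-R gaps are physiologically
  # shorter than the refractory so polarities are handled separately
  min_dist <- config$min_peak_distance_ms / 1000 * fs
  sel <- logical(length(cand))
  for (pol in c(TRUE, FALSE)) {
    ii <- which(is_max == pol)
    kept <- collapse_close_peaks(cand[ii], abs(v[ii] - iso_level), min_dist)
    sel[ii[cand[ii] %in% kept]] <- TRUE
  }
  cand <- cand[sel]; v <- v[sel]; is_max <- is_max[sel]

  # drop candidates on the R apex itself (within one narrow window) and
  # outside the physiologic search bounds around R, so a window reaching
  # into the neighbouring beat never labels the neighbour's waves
  near_r <- abs(cand - r0) <= w |
    cand < r0 - config$p_search_ms / 1000 * fs |
    cand > r0 + config$t_search_ms / 1000 * fs
  cand <- cand[!near_r]; v <- v[!near_r]; is_max <- is_max[!near_r]

  lab <- character(); idx <- integer(); amp <- numeric()
  add <- function(l, i, a_) { lab <<- c(lab, l); idx <<- c(idx, i); amp <<- c(amp, a_) }
  add("R", r0, beat$samples[r0 + 1L])

  qi <- which(!is_max & cand < r0)
  q_idx <- NA_integer_
  if (length(qi)) {
    k <- qi[which.max(cand[qi])]
    q_idx <- cand[k]; add("Q", q_idx, v[k])
  }
  si <- which(!is_max & cand > r0)
  s_idx <- NA_integer_
  if (length(si)) {
    k <- si[which.min(cand[si])]
    s_idx <- cand[k]; add("S", s_idx, v[k])
  }
  p_bound <- if (!is.na(q_idx)) q_idx else r0
  pi_ <- which(is_max & cand < p_bound)
  if (length(pi_)) {
    k <- pi_[which.max(v[pi_] - iso_level)]
    add("P", cand[k], v[k])
  }
  t_bound <- if (!is.na(s_idx)) s_idx else r0
  ti <- which(is_max & cand > t_bound)
  if (length(ti)) {
    k <- ti[which.max(v[ti] - iso_level)]
    add("T", cand[k], v[k])
  }
  fiducial_annotations(lab, idx, amp, fs = fs, record_id = beat$record_id)
}
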