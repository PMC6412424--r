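#' Full delineation pipeline
#'
#' Runs the complete chain on a raw single-lead recording: preprocessing
#' (low-pass + baseline removal), R-peak detection with the wide window,
#' isoelectric-level estimation, segmentation into beats on the mean R-R
#' interval, and narrow-window P/Q/S/T delineation per interior beat.
#' Beat-local indices are mapped back to absolute sample indices.
#'
#' R annotations cover every detected R peak. P, Q, S and T are only
#' delineated on interior beats: the first and last R serve as the
#' segmentation reference frame and their beats are never extracted.
#'
#' @param signal A raw [ecg_signal()].
#' @param config A [detector_config()].
#' @param preprocess Apply [preprocess_ecg()] first (default `TRUE`); set
#'   `FALSE` if the signal is already filtered and baseline-corrected.
#' @param spec,baseline_order Passed to [preprocess_ecg()].
#' @return Object of class `ecg_delineation`: list with `annotations`
#'   (a [fiducial_annotations()] table, absolute indices), `r_peaks`
#'   (R-only table), `iso_level`, `beat_matrix` (or `NULL` when fewer
#'   than 3 R peaks were found), and `signal` (the preprocessed trace).
#' @examples
#' gen <- generate_ecg(n_beats = 5, seed = 1)
#' res <- delineate_ecg(gen$signal)
#' res$annotations
#' @export
delineate_ecg <- function(signal, config = detector_config(),
                          preprocess = TRUE, spec = filter_spec(),
                          baseline_order = 8L) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(config, "detector_config"))
  pre <- if (preprocess) preprocess_ecg(signal, spec, baseline_order) else signal
  prof <- error_profile(pre, r_window_halfwidth(pre$fs))
  r_ann <- detect_r_peaks_from_profile(prof, pre, config)
  iso <- estimate_isoelectric_level(pre, config, profile = prof)
  out <- list(annotations = r_ann, r_peaks = r_ann, iso_level = iso,
              beat_matrix = NULL, signal = pre)
  if (nrow(r_ann) >= 3L) {
    bm <- segment_beats(pre, r_ann$index)
    per_beat <- lapply(seq_len(nrow(bm$beats)), function(k) {
      beat <- ecg_signal(bm$beats[k, ], pre$fs, pre$record_id)
      ann <- detect_pqrst(beat, bm$r_offset, iso, config)
      ann$index <- ann$index + bm$source_r_indices[k] - bm$half_width
      ann$time_s <- ann$index / pre$fs
      ann
    })
    ann <- do.call(rbind, per_beat)
    # beat-local R rows duplicate the global R detections; keep the global
    # set (it also covers the first and last beat)
    ann <- ann[ann$label != "R", , drop = FALSE]
    ann <- rbind(as.data.frame(r_ann), as.data.frame(ann))
    out$annotations <- fiducial_annotations(ann$label, ann$index,
                                            ann$amplitude, fs = pre$fs,
                                            record_id = pre$record_id)
    out$beat_matrix <- bm
  }
  class(out) <- "ecg_delineation"
  out
}

#' @export
print.ecg_delineation <- function(x, ...) {
  tab <- table(factor(x$annotations$label, levels = FIDUCIAL_LABELS))
  cat(sprintf("<ecg_delineation> '%s': iso level %.4f mV; peaks: %s\n",
              x$signal$record_id, x$iso_level,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}
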