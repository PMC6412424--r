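# Sensitivity of fiducial detection against reference annotations under a
# temporal tolerance (default 10 ms). Matching is per label, greedy
# nearest-first, each detection consuming at most one reference.

#' Match detected to reference annotations
#'
#' For one record: pairs each reference point with a same-label detected
#' point at temporal distance `|Delta index| / fs <= tolerance_ms / 1000`
#' (boundary inclusive). Pairs are formed greedily from the smallest
#' distance up; every detected point consumes at most one reference.
#'
#' @param detected,reference [fiducial_annotations()] tables (or data
#'   frames with the same columns), sorted by index.
#' @param tolerance_ms Temporal tolerance in milliseconds.
#' @param fs Sampling frequency in Hz used to convert index distances to
#'   time.
#' @return Data frame with one row per label present in the reference:
#'   `label`, `matched`, `total`.
#' @export
match_annotations <- function(detected, reference, tolerance_ms = 10, fs) {
  validate_annotations(detected); validate_annotations(reference)
  stopifnot(tolerance_ms >= 0, fs > 0)
  tol_samples <- tolerance_ms / 1000 * fs
  labs <- intersect(FIDUCIAL_LABELS, unique(as.character(reference$label)))
  res <- lapply(labs, function(l) {
    refi <- reference$index[reference$label == l]
    deti <- detected$index[detected$label == l]
    matched <- 0L
    if (length(refi) && length(deti)) {
      dmat <- abs(outer(refi, deti, "-"))
      ok <- which(dmat <= tol_samples, arr.ind = TRUE)
      if (nrow(ok)) {
        ok <- ok[order(dmat[ok]), , drop = FALSE]
        used_r <- logical(length(refi)); used_d <- logical(length(deti))
        for (k in seq_len(nrow(ok))) {
          r <- ok[k, 1L]; d <- ok[k, 2L]
          if (!used_r[r] && !used_d[d]) {
            used_r[r] <- TRUE; used_d[d] <- TRUE; matched <- matched + 1L
          }
        }
      }
    }
    data.frame(label = l, matched = matched, total = length(refi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Detection sensitivity under a temporal tolerance
#'
#' Per-label sensitivity, as a percentage, of detected fiducial points
#' against reference annotations: `100 * matched / total`. With
#' `level = "point"` (the primary mode) counts are pooled over all
#' records; `level = "record"` instead reports the percentage of records
#' whose reference points for that label were all matched. Labels with no
#' reference points are reported as `NA`, not 0.
#'
#' @param detected,reference Annotation tables covering one or more
#'   records (`record_id` distinguishes them), or lists of per-record
#'   tables.
#' @param tolerance_ms Temporal tolerance in milliseconds (default 10).
#' @param fs Sampling frequency in Hz.
#' @param level `"point"` (pooled counts) or `"record"`.
#' @return Object of class `sensitivity_report`: list with `per_label`
#'   (named numeric, percent), `counts` (data frame label/matched/total),
#'   `tolerance_ms`, `n_records`, `level`, and `average` (mean over labels
#'   with references).
#' @export
sensitivity <- function(detected, reference, tolerance_ms = 10, fs,
                        level = c("point", "record")) {
  level <- match.arg(level)
  if (!is.data.frame(detected)) detected <- do.call(rbind, lapply(detected, as.data.frame))
  if (!is.data.frame(reference)) reference <- do.call(rbind, lapply(reference, as.data.frame))
  validate_annotations(detected); validate_annotations(reference)
  if (nrow(reference) == 0L)
    stop("reference annotations are empty", call. = FALSE)
  recs <- unique(as.character(reference$record_id))
  det_recs <- unique(as.character(detected$record_id))
  if (length(recs) == 1L && length(det_recs) == 1L && det_recs != recs) {
    # single-record comparison: align despite differing labels (e.g. a
    # detection file named after its signal file)
    message("aligning single records '", det_recs, "' and '", recs, "'")
    detected$record_id <- recs
  }
  per_rec <- lapply(recs, function(r) {
    match_annotations(detected[detected$record_id == r, , drop = FALSE],
                      reference[reference$record_id == r, , drop = FALSE],
                      tolerance_ms, fs)
  })
  labs <- intersect(FIDUCIAL_LABELS, unique(as.character(reference$label)))
  if (level == "point") {
    pooled <- do.call(rbind, per_rec)
    counts <- do.call(rbind, lapply(labs, function(l) {
      sub <- pooled[pooled$label == l, , drop = FALSE]
      data.frame(label = l, matched = sum(sub$matched), total = sum(sub$total))
    }))
  } else {
    counts <- do.call(rbind, lapply(labs, function(l) {
      per <- vapply(per_rec, function(m) {
        sub <- m[m$label == l, , drop = FALSE]
        if (!nrow(sub) || sub$total == 0L) NA else as.integer(sub$matched == sub$total)
      }, integer(1))
      data.frame(label = l, matched = sum(per, na.rm = TRUE),
                 total = sum(!is.na(per)))
    }))
  }
  sens <- ifelse(counts$total > 0, 100 * counts$matched / counts$total, NA_real_)
  names(sens) <- counts$label
  structure(list(per_label = sens, counts = counts,
                 tolerance_ms = tolerance_ms, n_records = length(recs),
                 level = level, average = mean(sens, na.rm = TRUE)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d record(s), tolerance %g ms, %s-level\n",
              x$n_records, x$tolerance_ms, x$level))
  for (l in names(x$per_label)) {
    cnt <- x$counts[x$counts$label == l, ]
    cat(sprintf("  %s: %s (%d/%d)\n", l,
                if (is.na(x$per_label[[l]])) "undefined"
                else sprintf("%.1f%%", x$per_label[[l]]),
                cnt$matched, cnt$total))
  }
  cat(sprintf("  average: %.1f%%\n", x$average))
  invisible(x)
}
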