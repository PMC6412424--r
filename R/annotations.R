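FIDUCIAL_LABELS <- c("P", "Q", "R", "S", "T")

#' Build a fiducial annotation table
#'
#' Annotations are plain data frames with one row per labelled peak:
#' `record_id`, `label` (one of P, Q, R, S, T), `index` (0-based sample
#' index), `time_s` (`index / fs`) and `amplitude` (mV; the fitted vertex
#' value at detection). Rows are sorted by `index`.
#'
#' @param label Character vector of labels in P, Q, R, S, T.
#' @param index Integer vector of 0-based sample indices.
#' @param amplitude Numeric vector of amplitudes (mV).
#' @param fs Sampling frequency used to derive `time_s`.
#' @param record_id Record label, recycled.
#' @return A `data.frame` with class `c("fiducial_annotations", "data.frame")`.
#' @export
fiducial_annotations <- function(label = character(), index = integer(),
                                 amplitude = numeric(), fs = 1,
                                 record_id = "ecg") {
  label <- as.character(label)
  bad <- setdiff(unique(label), FIDUCIAL_LABELS)
  if (length(bad))
    stop("unknown fiducial labels: ", paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(record_id = rep_len(as.character(record_id), length(label)),
                   label = label,
                   index = as.integer(index),
                   time_s = as.numeric(index) / fs,
                   amplitude = as.numeric(amplitude),
                   stringsAsFactors = FALSE)
  df <- df[order(df$index, df$label), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("record_id", "label", "index")]))
    stop("duplicate (record_id, label, index) annotation", call. = FALSE)
  class(df) <- c("fiducial_annotations", "data.frame")
  df
}

validate_annotations <- function(x) {
  need <- c("record_id", "label", "index", "time_s", "amplitude")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(as.character(x$label)), FIDUCIAL_LABELS)
  if (length(bad))
    stop("unknown fiducial labels: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}
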