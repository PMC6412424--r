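# Readers and writers: WFDB header/signal pairs (format 16, the encoding
# the PhysioNet ECG-ID records use), delimited-text signals, and
# annotation tables. Delimited dialect: comma separator, "." decimal,
# optional single header line auto-detected.

#' Read a WFDB record
#'
#' Parses a WFDB `.hea`/`.dat` pair and returns one channel as an
#' [ecg_signal()] in physical units (mV). Supports signal format 16
#' (16-bit little-endian two's complement, channels interleaved), the
#' format used by the PhysioNet ECG-ID recordings (500 Hz, 12-bit,
#' nominal +/- 10 mV). Physical values are `(adc - baseline) / gain`.
#'
#' @param path Record path with or without the `.hea` extension.
#' @param channel 0-based channel index (default 0, the raw lead).
#' @return An [ecg_signal()]; `record_id` is the record name from the
#'   header.
#' @export
read_wfdb_record <- function(path, channel = 0L) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea, call. = FALSE)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3L)
    stop("malformed WFDB record line: ", lines[1], call. = FALSE)
  record_name <- sub("/.*$", "", rec[1])
  nsig <- suppressWarnings(as.integer(rec[2]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", rec[3])))
  nsamp <- if (length(rec) >= 4L) suppressWarnings(as.numeric(rec[4])) else NA
  if (is.na(nsig) || is.na(fs))
    stop("malformed WFDB record line: ", lines[1], call. = FALSE)
  if (length(lines) < 1L + nsig)
    stop("WFDB header declares ", nsig, " signals but has ",
         length(lines) - 1L, " signal lines", call. = FALSE)
  channel <- as.integer(channel)
  if (channel < 0L || channel >= nsig)
    stop("channel ", channel, " out of range (record has ", nsig, " signals)",
         call. = FALSE)

  sig <- strsplit(trimws(lines[2L + channel]), "\\s+")[[1]]
  dat_file <- sig[1]
  fmt <- sub("x.*$|:.*$|\\+.*$", "", sig[2])
  if (fmt != "16")
    stop("unsupported WFDB signal format '", sig[2], "' (only format 16)",
         call. = FALSE)
  gain_spec <- if (length(sig) >= 3L) sig[3] else "200"
  gain <- suppressWarnings(as.numeric(sub("\\(.*$|/.*$", "", gain_spec)))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_spec))
    as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_spec)) else NA
  adczero <- if (length(sig) >= 5L) suppressWarnings(as.numeric(sig[5])) else 0
  if (is.na(baseline)) baseline <- if (is.na(adczero)) 0 else adczero

  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat, call. = FALSE)
  raw_n <- file.info(dat)$size / 2L
  adc <- readBin(dat, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  per_chan <- length(adc) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) per_chan <- min(per_chan, nsamp)
  idx <- channel + 1L + nsig * seq.int(0L, per_chan - 1L)
  ecg_signal((adc[idx] - baseline) / gain, fs, record_name)
}

#' Write a WFDB record (format 16)
#'
#' Quantises a signal to ADC units (`round(mv * gain) + baseline`,
#' clamped to the 16-bit range) and writes a single-channel
#' `.hea`/`.dat` pair. Mainly for building test fixtures and exchanging
#' data with WFDB tooling; quantisation error is at most `0.5 / gain` mV.
#'
#' @param signal An [ecg_signal()].
#' @param dir Output directory.
#' @param record_name Record name (default the signal's `record_id`).
#' @param gain ADC units per mV (default 200).
#' @param baseline ADC value of 0 mV (default 0).
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(signal, dir, record_name = signal$record_id,
                              gain = 200, baseline = 0) {
  stopifnot(inherits(signal, "ecg_signal"))
  adc <- as.integer(pmin(pmax(round(signal$samples * gain) + baseline,
                              -32768), 32767))
  n <- length(adc)
  dat_name <- paste0(record_name, ".dat")
  hea <- file.path(dir, paste0(record_name, ".hea"))
  writeLines(c(sprintf("%s 1 %g %d", record_name, signal$fs, n),
               sprintf("%s 16 %g(%g)/mV 16 0 %d 0 0 ECG", dat_name, gain,
                       baseline, adc[1])),
             hea)
  writeBin(adc, file.path(dir, dat_name), size = 2L, endian = "little")
  invisible(hea)
}

parse_numeric_rows <- function(lines, path, skip = 0L) {
  rows <- strsplit(trimws(lines), ",")
  ncol <- lengths(rows)
  if (length(unique(ncol)) != 1L)
    stop("inconsistent column count in ", path, call. = FALSE)
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop("non-numeric row at line ", bad[1] + skip, " of ", path, call. = FALSE)
  do.call(rbind, vals)
}

#' Read a delimited-text ECG signal
#'
#' Reads a one-column (voltage) or two-column (time, voltage) comma-
#' separated file; a single non-numeric header line is auto-detected and
#' skipped. With a time column, the sampling frequency is the reciprocal
#' of the median sample spacing, and spacing deviating from the median by
#' more than 1% is rejected as non-uniform. A one-column file requires an
#' explicit `fs`.
#'
#' @param path Input file.
#' @param fs Sampling frequency in Hz; `NULL` means "infer from the time
#'   column".
#' @param record_id Record label (default: file name without extension).
#' @return An [ecg_signal()].
#' @export
read_delimited <- function(path, fs = NULL, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  first <- strsplit(trimws(lines[1]), ",")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  skip <- as.integer(has_header)
  body <- lines[(skip + 1L):length(lines)]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  m <- parse_numeric_rows(body, path, skip = skip)
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  if (ncol(m) == 1L) {
    if (is.null(fs))
      stop("`fs` is required for a single-column (voltage-only) file",
           call. = FALSE)
    return(ecg_signal(m[, 1L], fs, record_id))
  }
  if (ncol(m) != 2L)
    stop("expected 1 or 2 columns, got ", ncol(m), " in ", path, call. = FALSE)
  tms <- m[, 1L]; volts <- m[, 2L]
  if (is.null(fs)) {
    dt <- diff(tms)
    if (any(dt <= 0)) stop("time column not strictly increasing", call. = FALSE)
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("non-uniform sampling: spacing deviates from the median by > 1%",
           call. = FALSE)
    fs <- 1 / med
  }
  ecg_signal(volts, fs, record_id)
}

#' Write an ECG signal as delimited text
#'
#' Two columns (`time_s`, `voltage_mv`) with a header line, full double
#' precision, so `read_delimited()` round-trips losslessly.
#'
#' @param signal An [ecg_signal()].
#' @param path Output file.
#' @export
write_delimited <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  n <- length(signal$samples)
  t <- seq.int(0L, n - 1L) / signal$fs
  writeLines(c("time_s,voltage_mv",
               sprintf("%.17g,%.17g", t, signal$samples)),
             path)
  invisible(path)
}

#' Write fiducial annotations as delimited text
#'
#' Columns `record_id,label,sample_index,time_s,amplitude_mV`, full
#' double precision; an empty table writes a header-only file.
#'
#' @param annotations A [fiducial_annotations()] table, sorted by index.
#' @param path Output file.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  if (nrow(annotations) && is.unsorted(annotations$index))
    stop("annotations must be sorted by sample index", call. = FALSE)
  if (anyDuplicated(annotations[c("record_id", "label", "index")]))
    stop("duplicate (record_id, label, index) annotation", call. = FALSE)
  writeLines(c("record_id,label,sample_index,time_s,amplitude_mV",
               sprintf("%s,%s,%d,%.17g,%.17g", annotations$record_id,
                       annotations$label, annotations$index,
                       annotations$time_s, annotations$amplitude)),
             path)
  invisible(path)
}

#' Read fiducial annotations from delimited text
#'
#' @param path A file written by [write_annotations()] (or matching its
#'   column layout).
#' @return A [fiducial_annotations()] table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "label", "sample_index", "time_s", "amplitude_mV")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(record_id = as.character(df$record_id),
                    label = as.character(df$label),
                    index = as.integer(df$sample_index),
                    time_s = as.numeric(df$time_s),
                    amplitude = as.numeric(df$amplitude_mV),
                    stringsAsFactors = FALSE)
  validate_annotations(out)
  out <- out[order(out$index, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fiducial_annotations", "data.frame")
  out
}
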