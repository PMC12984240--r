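#' Multichannel EEG recording
#'
#' Container for a multichannel EEG signal in time-by-channel orientation:
#' rows are consecutive time samples, columns are montage channels. Amplitudes
#' are microvolt-scale but treated as unitless by the downstream feature
#' extractor, which is invariant to global scaling and offset.
#'
#' @param samples Numeric matrix, `L x Nc` (time samples by channels).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of `Nc` unique montage labels
#'   (10-20 naming, e.g. `"F3"`, `"Cz"`, `"PO10"`).
#' @param label Optional class identifier for the recording.
#' @return An object of class `eeg_recording` with fields `samples`, `fs`,
#'   `channel_names` and `label`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(64 * 4), 64, 4), fs = 32,
#'                      channel_names = c("F3", "F4", "O1", "O2"))
#' dim(rec$samples)
eeg_recording <- function(samples, fs, channel_names, label = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("'samples' must be a numeric matrix")
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("'samples' must have at least one row and one column")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive scalar sampling rate in Hz")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(samples))
    stop(sprintf("number of channel names (%d) does not match number of columns (%d)",
                 length(channel_names), ncol(samples)))
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  dimnames(samples) <- list(NULL, channel_names)
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.2f s)%s\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs,
              if (is.null(x$label)) "" else sprintf(", label = %s", x$label)))
  invisible(x)
}

#' Set of equally shaped EEG segments
#'
#' @param segments List of [eeg_recording] objects sharing length, sampling
#'   rate and montage.
#' @param labels Class identifier per segment (defaults to each segment's
#'   `label` field).
#' @return An object of class `segment_set` with fields `segments`, `labels`
#'   and `Ns`.
#' @export
segment_set <- function(segments, labels = NULL) {
  if (!is.list(segments))
    stop("'segments' must be a list of eeg_recording objects")
  if (length(segments) > 0L) {
    if (!all(vapply(segments, inherits, logical(1L), "eeg_recording")))
      stop("every segment must be an eeg_recording")
    dims <- vapply(segments, function(s) dim(s$samples), integer(2L))
    if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
      stop("all segments must share the same L x Nc shape")
    fss <- vapply(segments, `[[`, numeric(1L), "fs")
    if (any(fss != fss[1L]))
      stop("all segments must share the same sampling rate")
  }
  if (is.null(labels))
    labels <- vapply(segments, function(s)
      if (is.null(s$label)) NA_character_ else as.character(s$label),
      character(1L))
  if (length(labels) != length(segments))
    stop("'labels' must have one entry per segment")
  structure(list(segments = segments, labels = labels,
                 Ns = length(segments)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  if (x$Ns == 0L) {
    cat("<segment_set> empty\n")
  } else {
    d <- dim(x$segments[[1L]]$samples)
    cat(sprintf("<segment_set> %d segments of %d x %d @ %g Hz\n",
                x$Ns, d[1L], d[2L], x$segments[[1L]]$fs))
    print(table(x$labels, dnn = NULL))
  }
  invisible(x)
}

# Auto-detect comma vs tab delimiter from the first non-empty line.
detect_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a multichannel recording from a delimited text file
#'
#' Reads a numeric table (comma- or tab-separated, auto-detected; decimal
#' point only) in time-by-channel orientation. An optional header row may
#' supply the channel names. No filtering or rescaling is applied.
#'
#' @param path Path to the delimited file.
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels, one per column. If `NULL`, the file
#'   must carry a header row of names.
#' @param label Optional class identifier.
#' @return An [eeg_recording].
#' @export
read_csv_recording <- function(path, fs, channel_names = NULL, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("parse error: '%s' contains no data", path))
  delim <- detect_delim(lines[[1L]])
  first <- trimws(strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]])
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (has_header) {
    if (is.null(channel_names)) channel_names <- first
    lines <- lines[-1L]
    if (length(lines) == 0L)
      stop(sprintf("parse error: '%s' has a header but no data rows", path))
  }
  if (is.null(channel_names))
    stop("'channel_names' must be given when the file has no header row")
  cells <- strsplit(lines, delim, fixed = TRUE)
  ncol_file <- length(cells[[1L]])
  widths <- lengths(cells)
  if (any(widths != ncol_file))
    stop(sprintf("parse error: row %d has %d columns, expected %d",
                 which(widths != ncol_file)[1L], widths[widths != ncol_file][1L],
                 ncol_file))
  if (ncol_file != length(channel_names))
    stop(sprintf("shape error: file has %d columns but %d channel names were supplied",
                 ncol_file, length(channel_names)))
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells, use.names = FALSE))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("parse error: non-numeric cell at row %d, column %d",
                 (bad - 1L) %/% ncol_file + 1L, (bad - 1L) %% ncol_file + 1L))
  }
  samples <- matrix(vals, nrow = length(cells), ncol = ncol_file, byrow = TRUE)
  eeg_recording(samples, fs = fs, channel_names = channel_names, label = label)
}

#' Write a recording to a delimited text file
#'
#' Inverse of [read_csv_recording()]: one row per time sample, one column per
#' channel, with a header row of channel names.
#'
#' @param rec An [eeg_recording].
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_csv_recording <- function(rec, path, delim = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$samples, path, sep = delim, row.names = FALSE,
                     col.names = rec$channel_names, quote = FALSE)
  invisible(path)
}

# --- Minimal EDF/EDF+C support ------------------------------------------------
#
# EDF stores a 256-byte fixed header, 256 bytes of per-signal header fields,
# and data records of 16-bit little-endian integers, per signal in turn.
# Only continuous recordings with one common sampling rate are supported,
# which is what the segmentation pipeline requires.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF/EDF+ recording
#'
#' Supports continuous EDF/EDF+C files whose signals all share one sampling
#' rate; annotation channels are not supported. Samples are rescaled from
#' digital to physical units and returned in time-by-channel orientation.
#'
#' @param path Path to the EDF file.
#' @param label Optional class identifier.
#' @return An [eeg_recording].
#' @export
read_edf_recording <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop(sprintf("format error: '%s' is truncated", path))
    rawToChar(raw)
  }
  version <- trimws(rd(8L))
  if (version != "0")
    stop(sprintf("format error: '%s' is not an EDF file (version field '%s')",
                 path, version))
  rd(80L); rd(80L); rd(8L); rd(8L)              # patient, recording, date, time
  rd(8L)                                        # header byte count
  rd(44L)                                       # reserved
  n_records <- as.integer(trimws(rd(8L)))
  rec_dur <- as.numeric(trimws(rd(8L)))
  ns <- as.integer(trimws(rd(4L)))
  if (is.na(ns) || ns < 1L)
    stop(sprintf("format error: '%s' declares no signals", path))
  field <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)),
                                  character(1L))
  labels <- field(16L)
  field(80L)                                    # transducer
  field(8L)                                     # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                                    # prefiltering
  spr <- as.integer(field(8L))                  # samples per record
  field(32L)                                    # reserved
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))))
    stop(sprintf("format error: unreadable signal header in '%s'", path))
  fs_all <- spr / rec_dur
  if (length(unique(fs_all)) != 1L)
    stop(sprintf("unsupported format: '%s' mixes sampling rates (%s)",
                 path, paste(unique(fs_all), collapse = ", ")))
  out <- matrix(0, nrow = n_records * spr[1L], ncol = ns)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[s])
        stop(sprintf("format error: '%s' data section is truncated", path))
      scale <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      out[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <-
        (dig - dig_min[s]) * scale + phys_min[s]
    }
  }
  eeg_recording(out, fs = fs_all[1L], channel_names = labels, label = label)
}

#' Write a recording as EDF
#'
#' Writes a continuous EDF file with 16-bit quantization over each channel's
#' physical range, one-second data records (the sampling rate must be a
#' positive integer and the length a whole number of seconds; a trailing
#' remainder is dropped with a warning). Used for round-trip fixtures and
#' interchange; quantization limits reconstruction accuracy to the 16-bit
#' grid.
#'
#' @param rec An [eeg_recording] with integer `fs`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_records <- nrow(rec$samples) %/% fs
  if (n_records < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (n_records * fs != nrow(rec$samples))
    warning("trailing partial second dropped when writing EDF")
  x <- rec$samples[seq_len(n_records * fs), , drop = FALSE]
  ns <- ncol(x)
  phys_min <- apply(x, 2L, min)
  phys_max <- apply(x, 2L, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(paste0(edf_pad(x, width),
                                                     collapse = "")), con)
  wr("0", 8L)
  wr("synthetic", 80L); wr("synthetic", 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(256L + 256L * ns, 8L)
  wr("", 44L)
  wr(n_records, 8L)
  wr(1, 8L)
  wr(ns, 4L)
  wrv <- function(v, width) wr(vapply(v, edf_pad, character(1L), width), width)
  wrv(rec$channel_names, 16L)
  wrv(rep("", ns), 80L)
  wrv(rep("uV", ns), 8L)
  wrv(format(phys_min, digits = 6L), 8L)
  wrv(format(phys_max, digits = 6L), 8L)
  wrv(rep(dig_min, ns), 8L)
  wrv(rep(dig_max, ns), 8L)
  wrv(rep("", ns), 80L)
  wrv(rep(fs, ns), 8L)
  wrv(rep("", ns), 32L)
  for (r in seq_len(n_records)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[rows, s] - phys_min[s]) /
                     (phys_max[s] - phys_min[s]) * (dig_max - dig_min) + dig_min)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Split a recording into fixed-length segments
#'
#' Cuts consecutive, non-overlapping windows of `seg_seconds * fs` samples.
#' A trailing remainder shorter than one window is discarded, never padded.
#' Each segment inherits the sampling rate, montage and label.
#'
#' @param rec An [eeg_recording].
#' @param seg_seconds Window length in seconds; `seg_seconds * fs` must be a
#'   positive integer.
#' @return A [segment_set] (possibly empty when the recording is shorter than
#'   one window).
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(256 * 60 * 2), ncol = 2), fs = 256,
#'                      channel_names = c("C3", "C4"))
#' seg <- segment_recording(rec, 15)   # 4 segments of 3840 samples
#' seg$Ns
segment_recording <- function(rec, seg_seconds) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- seg_seconds * rec$fs
  if (!is.finite(L) || L <= 0 || abs(L - round(L)) > 1e-9)
    stop(sprintf("parameter error: seg_seconds * fs = %g is not a positive integer", L))
  L <- as.integer(round(L))
  n_seg <- nrow(rec$samples) %/% L
  segs <- lapply(seq_len(n_seg), function(i)
    eeg_recording(rec$samples[((i - 1L) * L + 1L):(i * L), , drop = FALSE],
                  fs = rec$fs, channel_names = rec$channel_names,
                  label = rec$label))
  segment_set(segs)
}
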