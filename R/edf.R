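# Minimal European Data Format (EDF) support: the continuous-recording
# subset (one uniform sampling rate, 16-bit samples, no annotations
# channel).  Layout: 256-byte ASCII header, ns * 256 bytes of per-signal
# headers, then data records of int16 little-endian samples.

.edf_field <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF file
#'
#' Parses the EDF header and data records and returns the physically scaled
#' signals.  All signals must share one sampling rate (records with an
#' 'EDF Annotations' signal are rejected); digital values are mapped to
#' physical units with the per-signal linear calibration from the header.
#'
#' @param path path to the .edf file.
#' @return A list with `data` (signals x samples matrix, physical units),
#'   `sampling_rate_hz` and `labels`.
#' @keywords internal
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_field(con, 8L)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(readBin(con, "raw", 80L + 80L + 8L + 8L))  # patient, recording, date, time
  header_bytes <- as.integer(.edf_field(con, 8L))
  invisible(readBin(con, "raw", 44L))                  # reserved
  n_records <- as.integer(.edf_field(con, 8L))
  record_s <- as.numeric(.edf_field(con, 8L))
  ns <- as.integer(.edf_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count")
  rd <- function(width) vapply(seq_len(ns), function(i) .edf_field(con, width),
                               character(1L))
  labels <- rd(16L)
  invisible(rd(80L))                                   # transducer
  invisible(rd(8L))                                    # physical dimension
  phys_min <- as.numeric(rd(8L))
  phys_max <- as.numeric(rd(8L))
  dig_min <- as.numeric(rd(8L))
  dig_max <- as.numeric(rd(8L))
  invisible(rd(80L))                                   # prefiltering
  nr <- as.integer(rd(8L))
  invisible(rd(32L))                                   # reserved
  if (any(grepl("EDF Annotations", labels, fixed = TRUE)))
    stop("EDF+ annotation signals are not supported")
  if (length(unique(nr)) != 1L)
    stop("signals with different samples-per-record are not supported")
  if (header_bytes != 256L + 256L * ns)
    stop("corrupt EDF header: inconsistent header size")
  if (record_s <= 0) stop("corrupt EDF header: non-positive record duration")
  nr <- nr[1L]
  rate <- nr / record_s
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  if (any(!is.finite(gain)))
    stop("corrupt EDF header: degenerate digital calibration range")
  data <- matrix(0, nrow = ns, ncol = n_records * nr)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * nr, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < ns * nr) stop("truncated EDF data record ", r)
    block <- matrix(block, nrow = nr, ncol = ns)   # per record: signal-major
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    data[, cols] <- t(block)
  }
  data <- phys_min + (data - dig_min) * gain
  list(data = data, sampling_rate_hz = rate, labels = labels)
}

#' Write a recording as an EDF file
#'
#' Serialises a [recording] into a minimal EDF file (one data record per
#' second, 16-bit samples, linear calibration spanning the observed
#' amplitude range per channel).  Trailing samples that do not fill a whole
#' record are dropped; quantisation to the 16-bit digital range makes the
#' round trip approximate, not bit-exact.
#'
#' @param x a [recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @keywords internal
write_edf <- function(x, path) {
  stopifnot(inherits(x, "recording"))
  ns <- nrow(x$data)
  nr <- as.integer(round(x$sampling_rate_hz))
  if (nr < 1L || abs(nr - x$sampling_rate_hz) > 1e-9)
    stop("EDF writer needs an integer sampling rate")
  n_records <- ncol(x$data) %/% nr
  if (n_records < 1L) stop("recording shorter than one 1-second EDF record")
  used <- x$data[, seq_len(n_records * nr), drop = FALSE]
  phys_min <- apply(used, 1L, min)
  phys_max <- apply(used, 1L, max)
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  pad <- function(s, w) formatC(substr(s, 1L, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8L); wr("X", 80L); wr("X", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L)
  wr(as.character(256L + 256L * ns), 8L)
  wr("", 44L)
  wr(as.character(n_records), 8L)
  wr("1", 8L)
  wr(as.character(ns), 4L)
  wrv <- function(vals, w) for (v in vals) wr(as.character(v), w)
  wrv(x$channel_labels, 16L)
  wrv(rep("", ns), 80L)
  wrv(rep("uV", ns), 8L)
  wrv(formatC(phys_min, digits = 6, format = "g"), 8L)
  wrv(formatC(phys_max, digits = 6, format = "g"), 8L)
  wrv(rep(dig_min, ns), 8L)
  wrv(rep(dig_max, ns), 8L)
  wrv(rep("", ns), 80L)
  wrv(rep(nr, ns), 8L)
  wrv(rep("", ns), 32L)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    dig <- round((used[, cols, drop = FALSE] - phys_min) / gain + dig_min)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}
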