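#' Multichannel recording objects
#'
#' A `recording` is the canonical in-memory representation of one subject's
#' multichannel time series: a numeric matrix with channels as rows and
#' samples as columns, together with the sampling rate and channel labels.
#' All downstream link and node identities are defined on the channel order
#' of this matrix.
#'
#' @param data numeric matrix, N channels x l samples.  Signal amplitudes in
#'   arbitrary units; they are never filtered or re-referenced by this
#'   package.
#' @param sampling_rate_hz positive number, samples per second.
#' @param channel_labels character vector of length N; unique.  Defaults to
#'   `"ch1"..."chN"`.
#' @param subject_id character scalar identifying the subject.
#' @param condition_tag optional character scalar (e.g. an eyes-open /
#'   eyes-closed segment name).
#'
#' @return An object of class `recording`: a list with elements `subject_id`,
#'   `data`, `sampling_rate_hz`, `channel_labels`, `condition_tag`.
#'
#' @details Validation requires at least 3 channels, at least 2 samples,
#'   no missing or non-finite values, and unique channel labels.  A
#'   validation failure names the offending channel and sample index.
#' @export
recording <- function(data, sampling_rate_hz, channel_labels = NULL,
                      subject_id = "subject", condition_tag = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix (channels x samples)")
  n <- nrow(data)
  l <- ncol(data)
  if (n < 3L) stop("a recording needs at least 3 channels, got ", n)
  if (l < 2L) stop("a recording needs at least 2 samples, got ", l)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be a positive number")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n)
    stop("need ", n, " channel labels, got ", length(channel_labels))
  if (anyDuplicated(channel_labels))
    stop("duplicated channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  bad <- which(!is.finite(data))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(data))
    stop("non-finite value in channel '", channel_labels[i[1L]],
         "' (row ", i[1L], ") at sample ", i[2L])
  }
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id)[1L],
         data = data,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_labels = channel_labels,
         condition_tag = condition_tag),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> subject '", x$subject_id, "'",
      if (!is.null(x$condition_tag)) paste0(" [", x$condition_tag, "]"),
      "\n", sep = "")
  cat("  ", nrow(x$data), " channels x ", ncol(x$data), " samples @ ",
      x$sampling_rate_hz, " Hz (",
      round(ncol(x$data) / x$sampling_rate_hz, 2), " s)\n", sep = "")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Read a multichannel recording from disk
#'
#' Reads either a European Data Format (EDF) file or a delimited text matrix
#' (comma or tab separated) into a [recording].  Delimited files are
#' rows-as-channels with a mandatory header row of channel labels and an
#' optional comment line `# sampling_rate_hz=<x>`; if that line is absent the
#' rate must be supplied via `sampling_rate_hz`.  Amplitudes are read back
#' unmodified: no detrending, filtering or re-referencing is performed.
#'
#' @param path path to the file.
#' @param format `"edf"` or `"delimited"`; guessed from the file extension
#'   when `NULL`.
#' @param sampling_rate_hz sampling rate override (required for delimited
#'   files that carry no rate comment; ignored for EDF, whose header defines
#'   the rate).
#' @param subject_id subject identifier; defaults to the file base name.
#' @param sample_range optional integer pair `c(first, last)` restricting the
#'   recording to a sample window (1-based, inclusive), e.g. to select an
#'   eyes-open or eyes-closed segment.  Default: the full recording.
#' @param condition_tag optional condition label stored on the result.
#' @return A [recording].
#' @seealso [write_recording()] for the delimited writer.
#' @export
read_recording <- function(path, format = NULL, sampling_rate_hz = NULL,
                           subject_id = NULL, sample_range = NULL,
                           condition_tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  format <- match.arg(format, c("edf", "delimited"))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "edf") {
    ed <- read_edf(path)
    data <- ed$data
    rate <- ed$sampling_rate_hz
    labels <- ed$labels
  } else {
    lines <- readLines(path, warn = FALSE)
    rate <- sampling_rate_hz
    m <- grep("^#\\s*sampling_rate_hz\\s*=", lines)
    if (length(m)) {
      rate_file <- as.numeric(sub("^#\\s*sampling_rate_hz\\s*=\\s*", "", lines[m[1L]]))
      if (is.null(rate)) rate <- rate_file
    }
    if (is.null(rate))
      stop("no sampling rate: supply 'sampling_rate_hz' or a ",
           "'# sampling_rate_hz=<x>' line")
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) < 2L) stop("delimited recording needs a header and data rows")
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
    labels <- trimws(strsplit(lines[1L], sep, fixed = TRUE)[[1L]])
    rows <- strsplit(lines[-1L], sep, fixed = TRUE)
    if (length(rows) != length(labels))
      stop("header declares ", length(labels), " channels but the file has ",
           length(rows), " data rows")
    if (length(unique(lengths(rows))) != 1L)
      stop("data rows differ in length")
    data <- matrix(0, nrow = length(rows), ncol = lengths(rows)[1L])
    for (r in seq_along(rows)) {
      suppressWarnings(v <- as.numeric(rows[[r]]))
      if (anyNA(v))
        stop("non-numeric cell in channel '", labels[r], "' (row ", r,
             ") at sample ", which(is.na(v))[1L])
      data[r, ] <- v
    }
  }
  if (!is.null(sample_range)) {
    stopifnot(length(sample_range) == 2L, sample_range[1L] >= 1,
              sample_range[2L] <= ncol(data),
              sample_range[1L] <= sample_range[2L])
    data <- data[, sample_range[1L]:sample_range[2L], drop = FALSE]
  }
  recording(data, sampling_rate_hz = rate, channel_labels = labels,
            subject_id = subject_id, condition_tag = condition_tag)
}

#' Write a recording as delimited text
#'
#' Writes the rows-as-channels layout read by [read_recording()]: one
#' `# sampling_rate_hz=<x>` comment line, a header row of channel labels and
#' one row per channel.  Amplitudes are serialised with full double
#' precision so that a write/read round trip is bit-exact.
#'
#' @param x a [recording].
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%s",
                     format(x$sampling_rate_hz, digits = 17)), con)
  writeLines(paste(x$channel_labels, collapse = sep), con)
  apply_fmt <- function(row) paste(sprintf("%.17g", row), collapse = sep)
  writeLines(vapply(seq_len(nrow(x$data)),
                    function(i) apply_fmt(x$data[i, ]), character(1L)), con)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Parses a delimited table (comma or tab) with mandatory `subject_id` and
#' `group` columns and optional `age` and `education` columns.  Any further
#' numeric column is treated as a cognitive score (e.g. MMSE, GDS, OVMPT,
#' fluencies, language) and preserved under its own name; missing scores are
#' allowed and stay `NA`.
#'
#' @param path path to the table.
#' @param groups optional character vector declaring the admissible group
#'   labels; rows with other labels raise an error.
#' @return A `data.frame` with one row per subject: columns `subject_id`,
#'   `group` (factor), `age`, `education`, plus one column per score.
#' @export
read_metadata <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (!"subject_id" %in% names(tab)) stop("metadata needs a 'subject_id' column")
  if (!"group" %in% names(tab)) stop("metadata needs a 'group' column")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  if (any(is.na(tab$group) | tab$group == ""))
    stop("missing group label for subject(s): ",
         paste(tab$subject_id[is.na(tab$group) | tab$group == ""], collapse = ", "))
  if (!is.null(groups)) {
    bad <- setdiff(unique(tab$group), groups)
    if (length(bad)) stop("group label(s) outside the declared set: ",
                          paste(bad, collapse = ", "))
    tab$group <- factor(tab$group, levels = groups)
  } else {
    tab$group <- factor(tab$group)
  }
  for (nm in setdiff(names(tab), c("subject_id", "group")))
    tab[[nm]] <- suppressWarnings(as.numeric(tab[[nm]]))
  tab
}

#' Names of the cognitive-score columns in a metadata table
#' @param metadata a data frame from [read_metadata()].
#' @return Character vector of score column names (everything beyond
#'   subject_id, group, age, education).
#' @export
score_columns <- function(metadata) {
  setdiff(names(metadata), c("subject_id", "group", "age", "education"))
}
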