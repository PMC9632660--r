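#' Multichannel recording container
#'
#' Wraps a samples-by-channels numeric matrix together with its sampling rate
#' and channel labels.  This is the common currency of the package: the
#' synthetic generators produce it, [segment_recording()] cuts it into
#' windows, and every connectivity estimator consumes it.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Character vector of unique channel labels; defaults to the
#'   matrix column names, or `"ch1"`, `"ch2"`, ... when absent.
#'
#' @return An object of class `mc_recording`: the data matrix with attributes
#'   `fs` and `labels` (also mirrored into `colnames`).
#' @export
#'
#' @examples
#' rec <- mc_recording(matrix(rnorm(2000), ncol = 2), fs = 500)
#' n_channels(rec)
#' duration(rec)
mc_recording <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L) {
    abort("a recording needs at least 2 channels", class = "epitarget_invalid")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive scalar (Hz)", class = "epitarget_invalid")
  }
  if (anyNA(data) || !all(is.finite(data))) {
    abort("recording contains non-finite samples", class = "epitarget_invalid")
  }
  labels <- labels %||% colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  labels <- as.character(labels)
  if (length(labels) != ncol(data) || anyDuplicated(labels)) {
    abort("`labels` must be unique and match the number of channels",
          class = "epitarget_invalid")
  }
  colnames(data) <- labels
  structure(data, fs = as.numeric(fs), labels = labels,
            class = c("mc_recording", "matrix", "array"))
}

#' @rdname mc_recording
#' @param x,rec An `mc_recording`.
#' @export
is_mc_recording <- function(x) inherits(x, "mc_recording")

#' @rdname mc_recording
#' @export
n_channels <- function(rec) ncol(rec)

#' @rdname mc_recording
#' @export
sampling_rate <- function(rec) attr(rec, "fs")

#' @rdname mc_recording
#' @export
channel_labels <- function(rec) attr(rec, "labels")

#' @rdname mc_recording
#' @export
duration <- function(rec) nrow(rec) / attr(rec, "fs")

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d samples x %d channels @ %g Hz (%.3g s)\n",
              nrow(x), ncol(x), attr(x, "fs"), duration(x)))
  cat("channels:", paste(head(attr(x, "labels"), 8L), collapse = ", "),
      if (ncol(x) > 8L) "..." else "", "\n")
  invisible(x)
}

# Keep class & attributes when subsetting channels (columns).
subset_channels <- function(rec, keep) {
  mc_recording(unclass(rec)[, keep, drop = FALSE], fs = attr(rec, "fs"),
               labels = attr(rec, "labels")[keep])
}

#' Segment a recording into overlapping windows
#'
#' Cuts the recording into windows of `win_s` seconds advancing by
#' `win_s - overlap_s` seconds (default 1 s windows with 0.5 s overlap, the
#' segmentation used throughout the pipeline).  Windows are half-open sample
#' ranges; a trailing partial window is dropped.
#'
#' @param rec An [mc_recording()].
#' @param win_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (must be smaller than `win_s`).
#'
#' @return A list of `mc_recording` segments.
#' @export
#'
#' @examples
#' rec <- mc_recording(matrix(rnorm(10000), ncol = 2), fs = 500)
#' length(segment_recording(rec))   # (10 - 1)/0.5 + 1 = 19
segment_recording <- function(rec, win_s = 1.0, overlap_s = 0.5) {
  stopifnot(is_mc_recording(rec))
  fs <- sampling_rate(rec)
  win <- round(win_s * fs)
  step <- round((win_s - overlap_s) * fs)
  if (win < 2L) abort("window shorter than 2 samples", class = "epitarget_invalid")
  if (overlap_s >= win_s || step < 1L) {
    abort("`overlap_s` must be smaller than `win_s`", class = "epitarget_invalid")
  }
  n <- nrow(rec)
  if (n < win) {
    abort("recording shorter than one window", class = "epitarget_invalid")
  }
  starts <- seq.int(0L, n - win, by = step)
  lapply(starts, function(s0) {
    mc_recording(unclass(rec)[(s0 + 1L):(s0 + win), , drop = FALSE],
                 fs = fs, labels = channel_labels(rec))
  })
}

#' Read and write recordings as headered CSV
#'
#' The on-disk format is a plain CSV with one column per channel and the
#' channel labels in the header row.  The sampling rate is carried in a
#' `# fs: <Hz>` comment line above the header and can be overridden on read.
#'
#' @param rec An [mc_recording()].
#' @param path File path.
#' @param fs Sampling rate override in Hz; when `NULL`, taken from the
#'   `# fs:` comment line, falling back to 500 Hz.
#' @return `read_recording()` returns an [mc_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(is_mc_recording(rec))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", sampling_rate(rec)), con)
  write.csv(as.data.frame(unclass(rec)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(fs)) {
    fs <- if (grepl("^#\\s*fs:", first)) {
      as.numeric(sub("^#\\s*fs:\\s*", "", first))
    } else 500
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  mc_recording(as.matrix(df), fs = fs, labels = names(df))
}
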