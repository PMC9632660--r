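#' Connectivity matrix container
#'
#' An N-by-N nonnegative weight matrix (row = receiver, column = sender for
#' directed methods) with zero diagonal and method/band metadata.
#'
#' @param weights Square nonnegative numeric matrix; the diagonal is forced
#'   to zero.
#' @param method Method token: one of `"pcc"`, `"dtf"`, `"dtf_sa"`,
#'   `"pdc"`, `"pdc_sa"`, `"icoh"`, `"icoh_sa"`, `"wpli"`, `"kldiv"`.
#' @param band Two-element Hz interval, or `NULL` for broadband methods.
#' @param labels Channel labels.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(weights, method, band = NULL, labels = NULL) {
  weights <- as.matrix(weights)
  method <- canon_method(method)
  stopifnot(nrow(weights) == ncol(weights), all(is.finite(weights)),
            all(weights >= 0))
  diag(weights) <- 0
  labels <- labels %||% colnames(weights) %||%
    paste0("ch", seq_len(ncol(weights)))
  dimnames(weights) <- list(labels, labels)
  directed <- !method_undirected(method)
  if (!directed && !isTRUE(all.equal(weights, t(weights)))) {
    abort("undirected method produced an asymmetric matrix",
          class = "epitarget_invalid")
  }
  structure(weights, method = method, band = band, directed = directed,
            labels = labels, class = c("conn_matrix", "matrix", "array"))
}

METHODS <- c("pcc", "dtf", "dtf_sa", "pdc", "pdc_sa",
             "icoh", "icoh_sa", "wpli", "kldiv")

canon_method <- function(method) {
  m <- gsub("-", "_", tolower(method))
  if (!m %in% METHODS) {
    abort(paste0("unknown method '", method, "'; use one of: ",
                 paste(method_label(METHODS), collapse = ", ")),
          class = "epitarget_invalid")
  }
  m
}

method_label <- function(method) {
  toupper(gsub("_sa$", "-SA", gsub("icoh", "iCoh", gsub("wpli", "wPLI", method))))
}

method_undirected <- function(method) method %in% c("pcc", "wpli")

#' @export
print.conn_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<conn_matrix> %s (%s%s): %d x %d, %d nonzero edges\n",
              method_label(attr(x, "method")),
              if (attr(x, "directed")) "directed" else "undirected",
              if (is.null(b)) ", broadband"
              else sprintf(", %g-%g Hz", b[1], b[2]),
              nrow(x), ncol(x), sum(x != 0)))
  w <- matrix(unclass(x), nrow(x), ncol(x), dimnames = dimnames(x))
  print(round(w, 4), ...)
  invisible(x)
}

#' @describeIn conn_matrix Edge-list tibble
#'   (`sender`, `receiver`, `weight`, `method`, `band_lo`, `band_hi`);
#'   undirected matrices report each unordered pair once.
#' @param x A `conn_matrix`.
#' @param all_edges Keep zero-weight edges too?
#' @param ... Unused.
#' @export
tidy.conn_matrix <- function(x, all_edges = FALSE, ...) {
  labels <- attr(x, "labels")
  n <- nrow(x)
  idx <- which(if (attr(x, "directed")) row(x) != col(x) else row(x) > col(x))
  out <- tibble(
    receiver = labels[row(x)[idx]],
    sender = labels[col(x)[idx]],
    weight = unclass(x)[idx],
    method = method_label(attr(x, "method")),
    band_lo = (attr(x, "band") %||% c(NA_real_, NA_real_))[1],
    band_hi = (attr(x, "band") %||% c(NA_real_, NA_real_))[2]
  )
  if (!all_edges) out <- dplyr::filter(out, .data$weight != 0)
  dplyr::arrange(out, dplyr::desc(.data$weight))
}

#' Read and write connectivity matrices
#'
#' `write_conn_matrix()` stores the labeled weight matrix as CSV (method and
#' band in `#` comment lines); `write_edge_list()` stores the [tidy()] edge
#' list.  `read_conn_matrix()` restores the matrix form.
#'
#' @param x A [conn_matrix()].
#' @param path File path.
#' @export
write_conn_matrix <- function(x, path) {
  stopifnot(inherits(x, "conn_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  b <- attr(x, "band")
  writeLines(c(sprintf("# method: %s", attr(x, "method")),
               sprintf("# band: %s",
                       if (is.null(b)) "NA NA" else paste(b, collapse = " "))),
             con)
  write.csv(data.frame(label = attr(x, "labels"), unclass(x),
                       check.names = FALSE), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
read_conn_matrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  method <- sub("^#\\s*method:\\s*", "", hdr[1])
  band <- suppressWarnings(as.numeric(strsplit(
    sub("^#\\s*band:\\s*", "", hdr[2]), "\\s+")[[1]]))
  if (anyNA(band)) band <- NULL
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  conn_matrix(w, method = method, band = band, labels = as.character(df$label))
}

#' @rdname write_conn_matrix
#' @export
write_edge_list <- function(x, path) {
  write.csv(as.data.frame(tidy(x, all_edges = TRUE)), path, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation connectivity
#'
#' Absolute Pearson correlation between every channel pair of a segment
#' (magnitudes, so the undirected matrix is comparable with the nonnegative
#' directed estimators); diagonal zero.
#'
#' @param seg An [mc_recording()].
#' @return A [conn_matrix()] (`method = "pcc"`).
#' @export
pearson_matrix <- function(seg) {
  stopifnot(is_mc_recording(seg))
  v <- apply(unclass(seg), 2, stats::var)
  if (any(v <= 1e-14)) abort("degenerate input: zero-variance channel",
                             class = "epitarget_degenerate")
  conn_matrix(abs(cor(unclass(seg))), "pcc", band = NULL,
              labels = channel_labels(seg))
}

# Analytic signal via the FFT half-spectrum construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

bandpass_channels <- function(mat, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  apply(mat, 2, function(ch) signal::filtfilt(bf, ch))
}

#' Weighted phase lag index
#'
#' For each segment, channels are band-filtered (zero-phase Butterworth)
#' when a band is given, the analytic signal is formed, and
#' `wPLI = |mean(Im S12)| / mean(|Im S12|)` is computed from the
#' instantaneous cross term `S12(t) = A1 A2 exp(i (theta1 - theta2))`.
#' Segment values are averaged.  Identically zero imaginary cross terms
#' (e.g. zero-lag identical signals) give 0.
#'
#' @param segs A list of [mc_recording()] segments (or a single recording,
#'   which is used as one segment).
#' @param band Optional two-element Hz band.
#' @return A symmetric [conn_matrix()] with values in `[0, 1]`.
#' @export
wpli_matrix <- function(segs, band = NULL) {
  if (is_mc_recording(segs)) segs <- list(segs)
  stopifnot(length(segs) >= 1, all(vapply(segs, is_mc_recording, TRUE)))
  fs <- sampling_rate(segs[[1]])
  labels <- channel_labels(segs[[1]])
  N <- length(labels)
  acc <- matrix(0, N, N)
  for (seg in segs) {
    m <- unclass(seg)
    m <- sweep(m, 2, colMeans(m))
    if (!is.null(band)) {
      check_freqs(band, fs)
      m <- bandpass_channels(m, band, fs)
    }
    a <- apply(m, 2, analytic_signal)
    w <- matrix(0, N, N)
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        im <- Im(a[, i] * Conj(a[, j]))
        den <- mean(abs(im))
        w[i, j] <- w[j, i] <- if (den <= 1e-15) 0 else abs(mean(im)) / den
      }
    }
    acc <- acc + w
  }
  conn_matrix(acc / length(segs), "wpli", band = band, labels = labels)
}

# Normalized spectrogram: 1 s windows, 50% overlap, squared-modulus FFT
# cells over the positive-frequency half, normalized to sum to one.
normalized_spectrogram <- function(x, fs, win_s = 1.0, overlap_s = 0.5) {
  win <- round(win_s * fs)
  step <- round((win_s - overlap_s) * fs)
  starts <- seq.int(0L, length(x) - win, by = step)
  nf <- win %/% 2 + 1
  W <- vapply(starts, function(s0) {
    Mod(fft(x[(s0 + 1):(s0 + win)])[1:nf])^2
  }, numeric(nf))
  W / sum(W)
}

#' Kullback-Leibler spectrogram divergence
#'
#' Each channel's short-time Fourier spectrogram (1 s windows, 50% overlap)
#' is normalized into a time-frequency probability distribution `W`;
#' the asymmetric divergence `D(W_x || W_y) = sum W_x log(W_x / W_y)` is
#' reported for every ordered channel pair (row = `x`, column = `y`).
#' Reference cells are floored at `eps` to keep the sum finite.
#'
#' @param rec An [mc_recording()] of at least one window length.
#' @param win_s,overlap_s Spectrogram window and overlap in seconds.
#' @param eps Floor applied to reference distribution cells.
#' @return An asymmetric nonnegative [conn_matrix()] (`method = "kldiv"`).
#' @export
kldiv_matrix <- function(rec, win_s = 1.0, overlap_s = 0.5, eps = 1e-12) {
  stopifnot(is_mc_recording(rec))
  fs <- sampling_rate(rec)
  if (nrow(rec) < round(win_s * fs)) {
    abort("recording shorter than one spectrogram window",
          class = "epitarget_invalid")
  }
  W <- lapply(seq_len(ncol(rec)),
              function(i) normalized_spectrogram(unclass(rec)[, i], fs,
                                                 win_s, overlap_s))
  N <- ncol(rec)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      wx <- W[[i]]; wy <- pmax(W[[j]], eps)
      pos <- wx > 0
      D[i, j] <- sum(wx[pos] * log(wx[pos] / wy[pos]))
    }
  }
  conn_matrix(pmax(D, 0), "kldiv", band = NULL, labels = channel_labels(rec))
}
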