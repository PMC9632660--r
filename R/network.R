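# Shared machinery: compute band-collapsed, segment-averaged connectivity
# matrices for one or several methods from a single segmentation and (for
# the spectral estimators) a single set of per-segment MVAR fits.
raw_networks <- function(rec, methods, band = c(31, 80), win_s = 1.0,
                         overlap_s = 0.5, max_order = 20L) {
  stopifnot(is_mc_recording(rec))
  methods <- vapply(methods, canon_method, "")
  if (any(grepl("_sa$", methods))) {
    abort("raw_networks handles base methods only", class = "epitarget_internal")
  }
  fs <- sampling_rate(rec)
  labels <- channel_labels(rec)
  N <- n_channels(rec)
  segs <- segment_recording(rec, win_s, overlap_s)
  out <- list()

  spectral <- intersect(methods, c("dtf", "pdc", "icoh"))
  if (length(spectral) > 0) {
    freqs <- band_grid(band, fs)
    cube <- array(unlist(lapply(segs, unclass), use.names = FALSE),
                  dim = c(nrow(segs[[1]]), N, length(segs)))
    fits <- .mvar_fit_segments_cpp(cube, as.integer(
      min(max_order, (nrow(segs[[1]]) - 2L) %/% N)))
    acc <- setNames(rep(list(matrix(0, N, N)), length(spectral)), spectral)
    for (f in fits) {
      model <- new_mvar_model(f, fs = fs, labels = labels,
                              n_samples = nrow(segs[[1]]))
      for (m in spectral) {
        spec <- switch(m,
                       dtf = dtf_spectrum(model, freqs),
                       pdc = pdc_spectrum(model, freqs),
                       icoh = icoh_spectrum(model, freqs))
        acc[[m]] <- acc[[m]] + band_collapse(spec)
      }
    }
    for (m in spectral) {
      out[[m]] <- conn_matrix(acc[[m]] / length(fits), m, band = band,
                              labels = labels)
    }
  }
  if ("pcc" %in% methods) {
    mats <- lapply(segs, function(s) unclass(pearson_matrix(s)))
    out[["pcc"]] <- conn_matrix(Reduce(`+`, mats) / length(mats), "pcc",
                                band = NULL, labels = labels)
  }
  if ("wpli" %in% methods) out[["wpli"]] <- wpli_matrix(segs, band = band)
  if ("kldiv" %in% methods) {
    out[["kldiv"]] <- kldiv_matrix(rec, win_s = win_s, overlap_s = overlap_s)
  }
  out[methods]
}

raw_network <- function(rec, method, band = c(31, 80), win_s = 1.0,
                        overlap_s = 0.5, max_order = 20L) {
  raw_networks(rec, method, band, win_s, overlap_s, max_order)[[1]]
}

#' Build a connectivity network from a recording
#'
#' End-to-end estimator: segments the recording (1 s windows, 0.5 s
#' overlap by default), evaluates the requested estimator per segment,
#' averages spectral estimators over the band on an inclusive 1 Hz grid,
#' averages across segments, and -- for methods carrying the `-SA` suffix
#' -- applies the surrogate 95th-percentile test and the strongest-edge
#' budget via [sparsify_with_surrogates()].
#'
#' @param rec An [mc_recording()].
#' @param method One of `"pcc"`, `"dtf"`, `"dtf-sa"`, `"pdc"`, `"pdc-sa"`,
#'   `"icoh"`, `"icoh-sa"`, `"wpli"`, `"kldiv"` (case/hyphen insensitive).
#' @param band Analysis band in Hz (default gamma, 31--80); must lie inside
#'   `(0, fs/2)` for spectral methods.
#' @param win_s,overlap_s Segmentation parameters in seconds.
#' @param n_surr,keep_frac,seed Surrogate-analysis parameters (used by
#'   `-SA` methods only).
#' @param max_order MVAR order cap.
#' @return A [conn_matrix()].
#' @export
#'
#' @examples
#' rec <- simulate_mvar5(5000, seed = 1)
#' build_network(rec, "dtf")
build_network <- function(rec, method = "dtf-sa", band = c(31, 80),
                          win_s = 1.0, overlap_s = 0.5, n_surr = 200L,
                          keep_frac = 0.05, seed = NULL, max_order = 20L) {
  method <- canon_method(method)
  if (grepl("_sa$", method)) {
    sparsify_with_surrogates(rec, sub("_sa$", "", method), band = band,
                             n_surr = n_surr, keep_frac = keep_frac,
                             seed = seed, win_s = win_s,
                             overlap_s = overlap_s, max_order = max_order)
  } else {
    raw_network(rec, method, band, win_s, overlap_s, max_order)
  }
}

offdiag <- function(m) unclass(m)[row(m) != col(m)]

#' Benchmark the nine estimators against a known network
#'
#' Computes all nine connectivity estimators (PCC, DTF, DTF-SA, PDC,
#' PDC-SA, iCoh, iCoh-SA, wPLI, KLDIV) on `rec`, correlates each matrix's
#' off-diagonal entries with the ground-truth coupling magnitudes, and
#' normalizes the correlations by their maximum so the best method scores
#' exactly 1.  The three `-SA` variants share one surrogate set and one
#' collection of per-segment MVAR fits.  An estimate with zero variance
#' gets correlation 0.
#'
#' @param rec An [mc_recording()].
#' @param truth A [ground_truth_network()] with matching channel count.
#' @param band,win_s,overlap_s,n_surr,keep_frac,seed,max_order As in
#'   [build_network()].
#' @return A tibble with columns `method`, `correlation`, `score`
#'   (normalized correlation), ordered as the canonical method list.
#' @export
benchmark_methods <- function(rec, truth, band = c(31, 80), win_s = 1.0,
                              overlap_s = 0.5, n_surr = 200L,
                              keep_frac = 0.05, seed = NULL,
                              max_order = 20L) {
  stopifnot(inherits(truth, "ground_truth_network"),
            nrow(truth$adjacency) == n_channels(rec))
  base <- c("pcc", "dtf", "pdc", "icoh", "wpli", "kldiv")
  mats <- raw_networks(rec, base, band, win_s, overlap_s, max_order)
  sa_base <- c("dtf", "pdc", "icoh")
  nulls <- surrogate_null(rec, sa_base, band, n_surr, seed,
                          win_s, overlap_s, max_order)
  for (m in sa_base) {
    mats[[paste0(m, "_sa")]] <- withCallingHandlers(
      apply_sparsification(mats[[m]], nulls[[m]], keep_frac),
      epitarget_few_survivors = function(w) invokeRestart("muffleWarning"))
  }
  tv <- offdiag(truth$adjacency)
  cors <- vapply(METHODS, function(m) {
    ev <- offdiag(mats[[m]])
    if (sd(ev) <= 1e-15 || sd(tv) <= 1e-15) 0 else cor(ev, tv)
  }, numeric(1))
  tibble(method = method_label(METHODS),
         correlation = unname(cors),
         score = unname(cors / max(cors)))
}
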