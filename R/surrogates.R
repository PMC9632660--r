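# Phase-randomization surrogates: each channel keeps its amplitude spectrum
# exactly while its Fourier phases are redrawn uniformly (independently per
# channel), destroying all cross-channel and nonlinear temporal structure.

phase_randomize_once <- function(mat) {
  n <- nrow(mat)
  half <- if (n %% 2 == 0) (n / 2 - 1) else ((n - 1) / 2)
  apply(mat, 2, function(ch) {
    X <- fft(ch)
    if (half > 0) {
      phi <- runif(half, 0, 2 * pi)
      idx <- 2:(half + 1)
      X[idx] <- Mod(X[idx]) * exp(1i * phi)
      X[n + 2 - idx] <- Conj(X[idx])   # Hermitian mirror -> real output
    }
    Re(fft(X, inverse = TRUE) / n)
  })
}

#' Phase-randomization surrogate recordings
#'
#' Generates `n` surrogate recordings whose per-channel amplitude spectra
#' match the original exactly (DC and Nyquist bins untouched, Hermitian
#' phase symmetry enforced) while phases are randomized independently per
#' channel.  Used to build the null distribution for surrogate-thresholded
#' connectivity.
#'
#' @param rec An [mc_recording()].
#' @param n Number of surrogates (default 200).
#' @param seed Integer seed.
#' @return A list of `n` [mc_recording()] surrogates.
#' @export
#'
#' @examples
#' rec <- simulate_mvar5(1000, seed = 1)
#' s <- make_surrogates(rec, n = 2, seed = 1)
#' max(abs(Mod(fft(s[[1]][, 1])) - Mod(fft(rec[, 1]))))  # spectrum preserved
make_surrogates <- function(rec, n = 200L, seed = NULL) {
  stopifnot(is_mc_recording(rec), n >= 1L)
  with_seed(seed, {
    lapply(seq_len(n), function(s) {
      mc_recording(phase_randomize_once(unclass(rec)),
                   fs = sampling_rate(rec), labels = channel_labels(rec))
    })
  })
}

# Number of retained edges under the top-fraction budget.
edge_budget <- function(n_channels, keep_frac, directed) {
  total <- n_channels * (n_channels - 1)
  if (!directed) total <- total / 2
  ceiling(keep_frac * total)
}

# Apply the surrogate 95th-percentile test followed by the top-fraction
# budget to an observed matrix, given the per-edge null array (N x N x S).
apply_sparsification <- function(observed, null_array, keep_frac = 0.05,
                                 quantile_level = 0.95) {
  N <- nrow(observed)
  directed <- attr(observed, "directed")
  q95 <- apply(null_array, c(1, 2), quantile, probs = quantile_level,
               names = FALSE)
  surviving <- unclass(observed) > q95 & row(observed) != col(observed)
  if (!directed) surviving <- surviving & t(surviving)
  budget <- edge_budget(N, keep_frac, directed)
  idx <- which(if (directed) surviving else surviving & upper.tri(surviving))
  n_surv <- length(idx)
  keep <- matrix(FALSE, N, N)
  if (n_surv < budget) {
    warn(sprintf("only %d edge(s) exceed the surrogate threshold (budget %d); keeping all survivors",
                 n_surv, budget), class = "epitarget_few_survivors")
    keep[idx] <- TRUE
  } else {
    ord <- idx[order(unclass(observed)[idx], decreasing = TRUE)]
    keep[ord[seq_len(budget)]] <- TRUE
  }
  if (!directed) keep <- keep | t(keep)
  out <- unclass(observed)
  out[!keep] <- 0
  conn_matrix(out, paste0(attr(observed, "method"), "_sa"),
              band = attr(observed, "band"), labels = attr(observed, "labels"))
}

#' Surrogate-thresholded, sparsified connectivity
#'
#' Builds the connectivity matrix for `estimator`, then (1) zeroes every
#' edge that does not exceed the 95th percentile of its own null
#' distribution over `n_surr` phase-randomization surrogates (each
#' surrogate run through the identical segmentation / fitting / band
#' averaging pipeline), and (2) of the surviving edges keeps only the
#' strongest `ceil(keep_frac * N(N-1))` (halved for undirected methods).
#' When fewer edges survive than the budget allows, all survivors are kept
#' and a warning is logged.
#'
#' @param rec An [mc_recording()].
#' @param estimator Base method token (`"dtf"`, `"pdc"`, `"icoh"`, or an
#'   undirected method).
#' @param band Analysis band in Hz (default gamma, 31--80).
#' @param n_surr Number of surrogates (default 200).
#' @param keep_frac Fraction of all possible edges to retain (default 0.05).
#' @param seed Integer seed for the surrogate phases.
#' @param win_s,overlap_s Segmentation parameters.
#' @param max_order MVAR order cap for the spectral estimators.
#' @return A sparsified [conn_matrix()] with the `_sa` method suffix.
#' @export
sparsify_with_surrogates <- function(rec, estimator, band = c(31, 80),
                                     n_surr = 200L, keep_frac = 0.05,
                                     seed = NULL, win_s = 1.0,
                                     overlap_s = 0.5, max_order = 20L) {
  estimator <- canon_method(estimator)
  if (grepl("_sa$", estimator)) estimator <- sub("_sa$", "", estimator)
  observed <- raw_network(rec, estimator, band, win_s, overlap_s, max_order)
  nulls <- surrogate_null(rec, estimator, band, n_surr, seed,
                          win_s, overlap_s, max_order)
  apply_sparsification(observed, nulls[[estimator]], keep_frac)
}

# Null connectivity arrays (N x N x n_surr) for one or several methods from
# a single shared surrogate set; surrogates are generated and processed one
# at a time to bound memory, and spectral methods share the MVAR fits.
surrogate_null <- function(rec, methods, band, n_surr, seed,
                           win_s = 1.0, overlap_s = 0.5, max_order = 20L) {
  N <- n_channels(rec)
  out <- lapply(methods, function(m) array(0, dim = c(N, N, n_surr)))
  names(out) <- methods
  with_seed(seed, {
    for (s in seq_len(n_surr)) {
      surr <- mc_recording(phase_randomize_once(unclass(rec)),
                           fs = sampling_rate(rec),
                           labels = channel_labels(rec))
      mats <- raw_networks(surr, methods, band, win_s, overlap_s, max_order)
      for (m in methods) out[[m]][, , s] <- unclass(mats[[m]])
    }
  })
  out
}
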