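#' Connectivity spectrum container
#'
#' An N-by-N-by-F nonnegative array of directed coupling strengths
#' (receiver, sender, frequency) with its frequency grid and method tag.
#'
#' @param values N x N x F nonnegative array.
#' @param freqs Frequency grid in Hz.
#' @param method Method tag (e.g. `"dtf"`).
#' @param labels Channel labels.
#' @return An object of class `conn_spectrum`.
#' @export
conn_spectrum <- function(values, freqs, method, labels) {
  stopifnot(length(dim(values)) == 3L, dim(values)[1] == dim(values)[2],
            dim(values)[3] == length(freqs), all(is.finite(values)))
  dimnames(values) <- list(labels, labels, NULL)
  structure(list(values = values, freqs = as.numeric(freqs),
                 method = method, labels = labels),
            class = "conn_spectrum")
}

#' @export
print.conn_spectrum <- function(x, ...) {
  cat(sprintf("<conn_spectrum> %s: %d x %d channels, %d frequencies (%g-%g Hz)\n",
              method_label(x$method), dim(x$values)[1], dim(x$values)[2],
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

check_freqs <- function(freqs, fs) {
  if (length(freqs) == 0 || any(freqs <= 0) || any(freqs >= fs / 2)) {
    abort("frequencies must lie strictly inside (0, fs/2)",
          class = "epitarget_invalid")
  }
  as.numeric(freqs)
}

# Inclusive integer-Hz grid covering `band`.
band_grid <- function(band, fs) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  check_freqs(seq(ceiling(band[1]), floor(band[2]), by = 1), fs)
}

#' Directed transfer function spectrum
#'
#' From a fitted MVAR model, computes the transfer matrix
#' `H(f) = A(f)^{-1}` with `A(f) = I - sum_j A_j exp(-i 2 pi f j / fs)` and
#' the normalized directed transfer function
#' `r2[i,j](f) = |H[i,j](f)|^2 / sum_r |H[i,r](f)|^2`, the share of
#' receiver `i`'s spectral content arriving from sender `j`.  Rows sum to 1
#' at every frequency and all values lie in `[0, 1]`.
#'
#' @param model An [fit_mvar()] result.
#' @param freqs Frequency grid in Hz, strictly inside `(0, fs/2)`.
#' @return A [conn_spectrum()].
#' @export
#'
#' @examples
#' fit <- fit_mvar(simulate_mvar5(2000, seed = 1))
#' spec <- dtf_spectrum(fit, 31:80)
#' range(apply(spec$values, c(1, 3), sum))  # rows sum to 1
dtf_spectrum <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  freqs <- check_freqs(freqs, model$fs)
  sp <- .ar_spectra_cpp(model$coeffs, freqs, 1 / model$fs, TRUE)
  H2 <- Mod(sp$H)^2
  denom <- apply(H2, c(1, 3), sum)           # N x F row power
  N <- dim(H2)[1]
  r2 <- H2 / aperm(array(denom, dim = c(N, dim(H2)[3], N)), c(1, 3, 2))
  conn_spectrum(r2, freqs, "dtf", model$labels)
}

#' Partial directed coherence spectrum
#'
#' Column-normalized coefficient spectrum
#' `PDC[i,j](f) = |A[i,j](f)| / sqrt(sum_k |A[k,j](f)|^2)` with
#' `A(f) = I - sum_j A_j exp(-i 2 pi f j / fs)`: the share of sender `j`'s
#' outflow directed at receiver `i`.  Squared columns sum to 1.
#'
#' @inheritParams dtf_spectrum
#' @return A [conn_spectrum()].
#' @export
pdc_spectrum <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  freqs <- check_freqs(freqs, model$fs)
  sp <- .ar_spectra_cpp(model$coeffs, freqs, 1 / model$fs, FALSE)
  A2 <- Mod(sp$A)^2
  csum <- apply(A2, c(2, 3), sum)            # N x F column power
  if (any(csum <= 0)) abort("zero column norm in coefficient spectrum",
                            class = "epitarget_singular")
  N <- dim(A2)[1]
  pdc <- sqrt(A2 / aperm(array(csum, dim = c(N, dim(A2)[3], N)), c(3, 1, 2)))
  conn_spectrum(pdc, freqs, "pdc", model$labels)
}

#' Isolated effective coherence spectrum
#'
#' For each ordered pair (receiver `i`, sender `j`) the coefficient
#' matrices are reduced to the direct `j -> i` pathway plus the
#' autoregressive self terms (every other causal entry set to zero), and a
#' PDC-type ratio weighted by the inverse noise variances is evaluated:
#' `iCoh[i,j](f) = q_i |A[i,j](f)|^2 / (q_i |A[i,j](f)|^2 + q_j |A[j,j](f)|^2)`
#' with `q_k = 1 / noise_cov[k,k]`.  Because zeroing the irrelevant
#' pathways leaves the `(i,j)` and `(j,j)` entries of `A(f)` untouched,
#' only those entries enter the ratio; indirect chains contribute nothing.
#' The diagonal is set to zero (self-coherence is excluded downstream).
#'
#' @inheritParams dtf_spectrum
#' @return A [conn_spectrum()].
#' @export
icoh_spectrum <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  freqs <- check_freqs(freqs, model$fs)
  sp <- .ar_spectra_cpp(model$coeffs, freqs, 1 / model$fs, FALSE)
  A2 <- Mod(sp$A)^2
  N <- dim(A2)[1]; F <- dim(A2)[3]
  q <- 1 / diag(model$noise_cov)
  if (any(!is.finite(q))) abort("zero noise variance", class = "epitarget_singular")
  num <- A2 * array(q, dim = c(N, N, F))                 # q_i |A_ij|^2
  # q_j |A_jj(f)|^2, expanded to N x N x F over receivers
  diag_idx <- cbind(rep(1:N, times = F), rep(1:N, times = F),
                    rep(1:F, each = N))
  Ajj <- matrix(A2[diag_idx], N, F)                      # N x F
  den_j <- Ajj * q                                       # q_j |A_jj|^2
  den <- num + aperm(array(den_j, dim = c(N, F, N)), c(3, 1, 2))
  vals <- num / den
  for (f in seq_len(F)) diag(vals[, , f]) <- 0
  conn_spectrum(vals, freqs, "icoh", model$labels)
}

# Mean over the frequency dimension -> plain N x N matrix.
band_collapse <- function(spectrum) {
  apply(spectrum$values, c(1, 2), mean)
}
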