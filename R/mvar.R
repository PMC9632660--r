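#' Fit a multichannel autoregressive model
#'
#' Fits an MVAR model `x(t) = sum_j A_j x(t-j) + w(t)` to a (segment of a)
#' recording.  The model order is selected by Akaike's Final Prediction
#' Error over `1..max_order` (ties broken toward the smaller order) and the
#' coefficients solve the Yule-Walker normal equations, computed for all
#' orders in one pass of the multichannel Levinson recursion.  Channels are
#' demeaned before fitting.
#'
#' Coefficients are stored in regression form: the lag-`j` matrix entry
#' `(i, k)` is the influence of channel `k` at lag `j` on channel `i`.
#'
#' @param seg An [mc_recording()] (typically one 1 s segment).
#' @param max_order Largest candidate order (default 20); capped internally
#'   so that the normal equations stay overdetermined.
#'
#' @return An object of class `mvar_model` with elements `order`,
#'   `coeffs` (N x N x order array), `noise_cov`, `fpe`, `fs`, `labels`,
#'   `n_samples`.
#' @export
#'
#' @examples
#' rec <- simulate_mvar5(2000, seed = 1)
#' fit <- fit_mvar(rec)
#' fit$order
fit_mvar <- function(seg, max_order = 20L) {
  stopifnot(is_mc_recording(seg))
  if (max_order < 1L) abort("`max_order` must be >= 1",
                            class = "epitarget_invalid")
  if (nrow(seg) <= ncol(seg) * max_order) {
    max_order <- max(1L, (nrow(seg) - 2L) %/% ncol(seg))
  }
  fit <- tryCatch(.mvar_fit_cpp(unclass(seg), as.integer(max_order)),
                  error = function(e) {
                    abort(conditionMessage(e), class = "epitarget_degenerate")
                  })
  new_mvar_model(fit, fs = sampling_rate(seg), labels = channel_labels(seg),
                 n_samples = nrow(seg))
}

new_mvar_model <- function(fit, fs, labels, n_samples) {
  coeffs <- fit$coeffs
  dimnames(coeffs) <- list(labels, labels, NULL)
  dimnames(fit$noise_cov) <- list(labels, labels)
  structure(list(order = fit$order, coeffs = coeffs,
                 noise_cov = fit$noise_cov, fpe = drop(fit$fpe),
                 fs = fs, labels = labels, n_samples = n_samples),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> %d channels, order %d (FPE), fit on %d samples @ %g Hz\n",
              length(x$labels), x$order, x$n_samples, x$fs))
  invisible(x)
}

#' @describeIn fit_mvar Long-format coefficients: one row per
#'   (lag, receiver, sender) with the fitted coefficient.
#' @param x An `mvar_model`.
#' @param ... Unused.
#' @export
tidy.mvar_model <- function(x, ...) {
  p <- x$order
  N <- length(x$labels)
  tibble(
    lag = rep(seq_len(p), each = N * N),
    receiver = rep(rep(x$labels, times = N), times = p),
    sender = rep(rep(x$labels, each = N), times = p),
    coefficient = as.vector(x$coeffs)
  )
}

#' @describeIn fit_mvar One-row model summary (order, sample size,
#'   generalized noise variance, FPE at the selected order).
#' @export
glance.mvar_model <- function(x, ...) {
  tibble(order = x$order, n_samples = x$n_samples,
         n_channels = length(x$labels),
         noise_gen_var = det(x$noise_cov),
         fpe = x$fpe[x$order])
}
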