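#' Parameters of the bistable oscillator network
#'
#' Constants of the multi-unit stochastic model.  Each node is a complex
#' normal-form oscillator `dz/dt = (a|z|^4 + b|z|^2 + lambda - 1 + i*omega) z`
#' with `a = -1`, `b = 2`: for excitability `0 < lambda < 1` the origin
#' (quiescent state) coexists with a stable limit cycle of radius
#' `sqrt(1 + sqrt(lambda))`, separated by an unstable cycle of radius
#' `sqrt(1 - sqrt(lambda))`.  Nodes are diffusively coupled through
#' `beta * K * G` where `G` is the max-normalized connectivity matrix, and
#' driven by per-step complex noise increments
#' `alpha * (noise_mean + noise_sd * N(0,1))` on each part, applied at the
#' fixed Euler-Maruyama step `dt`.
#'
#' @param a,b Normal-form coefficients (defaults -1, 2).
#' @param omega Angular frequency of the limit cycle (model rad/time;
#'   default 1, so that `omega * dt` stays well below 1 for the explicit
#'   Euler scheme).
#' @param beta Coupling coefficient (default 0.02).
#' @param K Scale applied to the normalized connectivity (default 1000).
#' @param alpha Noise coefficient (default 1).
#' @param noise_mean,noise_sd Moments of the per-step noise increments
#'   (defaults 0.0003 and 0.05).
#' @param dt Integration step (default 0.05).
#' @param t_max Simulation horizon in model time units (default 500);
#'   escape times are censored here.
#' @param escape_radius Escape detector threshold on `|z|` (default 1,
#'   strictly between the unstable and stable cycle radii for every
#'   `lambda` in (0,1)).
#' @return A list of class `z6_params`.
#' @export
z6_params <- function(a = -1, b = 2, omega = 1, beta = 0.02, K = 1000,
                      alpha = 1, noise_mean = 3e-4, noise_sd = 0.05,
                      dt = 0.05, t_max = 500, escape_radius = 1) {
  stopifnot(dt > 0, t_max >= dt, escape_radius > 0, noise_sd >= 0,
            K >= 0, beta >= 0, alpha >= 0)
  structure(list(a = a, b = b, omega = omega, beta = beta, K = K,
                 alpha = alpha, noise_mean = noise_mean, noise_sd = noise_sd,
                 dt = dt, t_max = t_max, escape_radius = escape_radius),
            class = "z6_params")
}

#' @export
print.z6_params <- function(x, ...) {
  cat(sprintf(paste0("<z6_params> a=%g b=%g omega=%g beta=%g K=%g alpha=%g ",
                     "noise=(%g, %g)/step dt=%g t_max=%g escape_radius=%g\n"),
              x$a, x$b, x$omega, x$beta, x$K, x$alpha, x$noise_mean,
              x$noise_sd, x$dt, x$t_max, x$escape_radius))
  invisible(x)
}

#' Deterministic drift of a single oscillator
#'
#' `f(z) = (a|z|^4 + b|z|^2 + lambda - 1 + i*omega) z`.  The origin is a
#' fixed point; the radial equilibria solve `a r^4 + b r^2 + lambda - 1 = 0`,
#' i.e. `r^2 = 1 +/- sqrt(lambda)` at the defaults.
#'
#' @param z Complex state (vectorized).
#' @param lambda Excitability in (0, 1].
#' @param omega Angular frequency.
#' @param a,b Normal-form coefficients.
#' @return Complex derivative, same shape as `z`.
#' @export
#'
#' @examples
#' z6_drift(0, lambda = 0.25)                    # fixed point at the origin
#' Mod(z6_drift(sqrt(1.5) + 0i, lambda = 0.25))  # stable cycle radius
z6_drift <- function(z, lambda, omega = 1, a = -1, b = 2) {
  r2 <- Mod(z)^2
  (a * r2^2 + b * r2 + lambda - 1 + 1i * omega) * z
}

#' Normalize a connectivity matrix into the model coupling matrix
#'
#' Divides the (nonnegative) weight matrix by its maximum entry so the
#' strongest edge has weight 1 (a zero matrix passes through unchanged),
#' then scales by `K` to bring the coupling to the model's working
#' magnitude.
#'
#' @param W A [conn_matrix()] or plain nonnegative square matrix.
#' @param K Scale factor (default 1000).
#' @return A plain numeric matrix `K * W / max(W)` with the input labels.
#' @export
normalize_coupling <- function(W, K = 1000) {
  labels <- if (inherits(W, "conn_matrix")) attr(W, "labels") else
    colnames(W) %||% paste0("ch", seq_len(ncol(W)))
  W <- unclass(as.matrix(W))
  stopifnot(nrow(W) == ncol(W))
  if (any(W < 0)) abort("coupling weights must be nonnegative",
                        class = "epitarget_invalid")
  mx <- max(W)
  G <- if (mx > 0) W / mx else W
  out <- G * K
  dimnames(out) <- list(labels, labels)
  out
}

check_coupling <- function(G, lambdas) {
  G <- as.matrix(G)
  stopifnot(nrow(G) == ncol(G), all(is.finite(G)))
  if (length(lambdas) != nrow(G)) {
    abort("`lambdas` length must match the coupling matrix",
          class = "epitarget_invalid")
  }
  if (any(lambdas <= 0) || any(lambdas > 1)) {
    abort("excitability values must lie in (0, 1]", class = "epitarget_invalid")
  }
  G
}

#' Simulate the coupled stochastic network
#'
#' Euler-Maruyama integration of
#' `dz_i = [f(z_i) + beta * sum_j (K G)_ij (z_j - z_i)] dt + noise`
#' from `z_i(0) = 0`, with the per-step noise convention of [z6_params()].
#' Identical seeds give identical trajectories.  A realization whose state
#' exceeds `|z| > 10` is flagged as diverged and integration stops there.
#'
#' @param G Coupling matrix as returned by [normalize_coupling()]
#'   (i.e. already scaled by `K`).
#' @param lambdas Per-node excitability in (0, 1] (scalar recycled).
#' @param params A [z6_params()].
#' @param seed Integer seed.
#' @return An object of class `z6_trajectories`: list with `time` (vector),
#'   `z` (complex matrix, steps x nodes), `diverged`, `params`, `labels`.
#' @export
#'
#' @examples
#' tr <- simulate_network(matrix(0, 2, 2), lambdas = 0.9,
#'                        params = z6_params(t_max = 50), seed = 1)
#' escape_times(tr)
simulate_network <- function(G, lambdas, params = z6_params(), seed = NULL) {
  G <- check_coupling(G, lambdas <- rep_len(lambdas, nrow(as.matrix(G))))
  n_steps <- round(params$t_max / params$dt)
  res <- .z6_traj_cpp(params$beta * G, lambdas, params$omega, params$a,
                      params$b, params$dt, as.integer(n_steps), params$alpha,
                      params$noise_mean, params$noise_sd,
                      derive_stream(seed %||% 0, 1))
  z <- res$x + 1i * res$y
  colnames(z) <- rownames(G)
  structure(list(time = seq(0, by = params$dt, length.out = nrow(z)),
                 z = z, diverged = res$diverged, params = params,
                 lambdas = lambdas, labels = rownames(G), seed = seed),
            class = "z6_trajectories")
}

#' @export
print.z6_trajectories <- function(x, ...) {
  cat(sprintf("<z6_trajectories> %d nodes, %d steps (dt=%g, t_max=%g)%s\n",
              ncol(x$z), nrow(x$z) - 1L, x$params$dt, x$params$t_max,
              if (x$diverged) " [diverged]" else ""))
  invisible(x)
}

#' Escape times of simulated trajectories
#'
#' Per node, the first time `|z_i(t)|` reaches the escape radius (the
#' commitment to the oscillatory attractor); trajectories that never cross
#' are censored at `t_max`.  Two network-level summaries are reported: the
#' first-node crossing and the mean of per-node escape times with censored
#' nodes entering at `t_max` (the aggregate used by the perturbation map,
#' through which a node's downstream influence is visible).
#'
#' @param traj A [simulate_network()] result.
#' @param escape_radius Threshold on `|z|`; defaults to the value in the
#'   trajectory's parameters.
#' @return A list of class `escape_time_result`: `times` (per node, `NA`
#'   when censored), `censored`, `t_max`, `network_first`, `network_mean`.
#' @export
escape_times <- function(traj, escape_radius = NULL) {
  stopifnot(inherits(traj, "z6_trajectories"))
  radius <- escape_radius %||% traj$params$escape_radius
  mags <- Mod(traj$z)
  idx <- apply(mags >= radius, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  times <- traj$time[idx]
  t_max <- traj$params$t_max
  filled <- ifelse(is.na(times), t_max, times)
  structure(list(times = setNames(times, traj$labels),
                 censored = is.na(times), t_max = t_max,
                 network_first = min(filled), network_mean = mean(filled),
                 seed = traj$seed),
            class = "escape_time_result")
}

#' @export
print.escape_time_result <- function(x, ...) {
  cat(sprintf("<escape_time_result> first=%.3g mean=%.3g (%d/%d censored at t_max=%g)\n",
              x$network_first, x$network_mean, sum(x$censored),
              length(x$times), x$t_max))
  invisible(x)
}

# Fast path used by the perturbation map and the grid search: network-mean
# escape times (censored nodes at t_max) for a batch of realizations, with
# per-realization noise streams derived from (seed, realization index) only
# -- common random numbers across perturbation conditions.
network_escape_samples <- function(G, lambdas, params, n_realizations, seed) {
  G <- check_coupling(G, lambdas)
  n_steps <- round(params$t_max / params$dt)
  res <- .z6_escape_cpp(params$beta * G, lambdas, params$omega, params$a,
                        params$b, params$dt, as.integer(n_steps),
                        params$alpha, params$noise_mean, params$noise_sd,
                        params$escape_radius,
                        derive_stream(seed %||% 0, seq_len(n_realizations)),
                        TRUE)
  times <- res$times
  ok <- !res$diverged
  if (!any(ok)) {
    abort(paste0("every realization diverged (|z| > 10): the coupling ",
                 "matrix is too stiff for the fixed integration step; ",
                 "reduce K or the row sums of G"),
          class = "epitarget_diverged")
  }
  filled <- times
  filled[is.na(filled)] <- params$t_max
  list(mean_tes = rowMeans(filled)[ok],
       first_tes = apply(filled, 1, min)[ok],
       censor_frac = mean(is.na(times[ok, , drop = FALSE])),
       n_diverged = sum(!ok))
}
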