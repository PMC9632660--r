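#' Escape-time perturbation map
#'
#' Measures each node's leverage over network excitability.  With every
#' node at baseline excitability `lambda0` the network escape time is
#' recorded as `T0` (mean over realizations of the network-mean escape
#' time, censored values entering at `t_max`).  Then, one candidate node at
#' a time, its excitability is raised to `lambda1` and the escape time is
#' re-measured as `T1(k)`; the map reports `deltaT(k) = T0 - T1(k)`, the
#' escape-time reduction caused by exciting node `k`.  Noise streams are
#' shared across conditions at equal realization index (common random
#' numbers), so `deltaT` differences are low-variance.  Fully censored
#' conditions trigger a warning and are visible through `censor_frac`.
#'
#' @param G Coupling matrix from [normalize_coupling()].
#' @param lambda0 Baseline excitability in (0, 1).
#' @param lambda1 Perturbed excitability in `[lambda0, 1]`.
#' @param n_realizations Noise realizations per condition (default 100).
#' @param seed Integer seed.
#' @param params A [z6_params()].
#' @return An object of class `delta_t_map`: named `delta_t` vector plus
#'   `t0`, `t1`, `lambda0`, `lambda1`, `n_realizations`, `censor_frac`,
#'   `labels`.  [tidy()] gives one row per node; [glance()] one summary row.
#' @export
#'
#' @examples
#' G <- normalize_coupling(mvar5_ground_truth()$adjacency)
#' dt_map <- delta_t_map(G, 0.5, 0.85, n_realizations = 10, seed = 1)
#' tidy(dt_map)
delta_t_map <- function(G, lambda0, lambda1, n_realizations = 100L,
                        seed = NULL, params = z6_params()) {
  G <- as.matrix(G)
  N <- nrow(G)
  if (!(lambda0 > 0 && lambda0 <= lambda1 && lambda1 <= 1)) {
    abort("need 0 < lambda0 <= lambda1 <= 1", class = "epitarget_invalid")
  }
  labels <- colnames(G) %||% paste0("ch", seq_len(N))
  base <- network_escape_samples(G, rep(lambda0, N), params,
                                 n_realizations, seed)
  warn_censored(base, "baseline")
  t1 <- numeric(N)
  cf <- numeric(N)
  for (k in seq_len(N)) {
    lam <- rep(lambda0, N)
    lam[k] <- lambda1
    res <- network_escape_samples(G, lam, params, n_realizations, seed)
    warn_censored(res, labels[k])
    t1[k] <- mean(res$mean_tes)
    cf[k] <- res$censor_frac
  }
  t0 <- mean(base$mean_tes)
  structure(list(delta_t = setNames(t0 - t1, labels), t0 = t0,
                 t1 = setNames(t1, labels), lambda0 = lambda0,
                 lambda1 = lambda1, n_realizations = n_realizations,
                 censor_frac = setNames(cf, labels),
                 censor_frac_baseline = base$censor_frac,
                 labels = labels, seed = seed, params = params),
            class = "delta_t_map")
}

warn_censored <- function(res, what) {
  if (res$censor_frac >= 1) {
    warn(sprintf("all node escapes censored at t_max in condition '%s' (censoring fraction %.2f)",
                 what, res$censor_frac), class = "epitarget_censored")
  }
  if (res$n_diverged > 0) {
    warn(sprintf("%d diverged realization(s) dropped in condition '%s'",
                 res$n_diverged, what), class = "epitarget_diverged")
  }
}

#' @export
print.delta_t_map <- function(x, ...) {
  cat(sprintf("<delta_t_map> %d nodes, lambda0=%.2f lambda1=%.2f, %d realizations, T0=%.3g\n",
              length(x$delta_t), x$lambda0, x$lambda1, x$n_realizations, x$t0))
  best <- which.max(x$delta_t)
  cat(sprintf("largest deltaT: %s = %.4g\n", x$labels[best], x$delta_t[best]))
  invisible(x)
}

#' @describeIn delta_t_map One row per node with `delta_t`, `t1` and the
#'   censoring fraction of that node's perturbed condition.
#' @param x A `delta_t_map`.
#' @param ... Unused.
#' @export
tidy.delta_t_map <- function(x, ...) {
  tibble(node = x$labels, delta_t = unname(x$delta_t), t1 = unname(x$t1),
         censor_frac = unname(x$censor_frac))
}

#' @describeIn delta_t_map One-row summary: the excitability pair, `t0`,
#'   realization count and the argmax node.
#' @export
glance.delta_t_map <- function(x, ...) {
  tibble(lambda0 = x$lambda0, lambda1 = x$lambda1, t0 = x$t0,
         n_realizations = x$n_realizations,
         target = x$labels[which.max(x$delta_t)],
         censor_frac_baseline = x$censor_frac_baseline)
}

#' Excitability grid search
#'
#' Scans the `(lambda0, lambda1)` grid (baseline 0--0.5, perturbed
#' 0.5--1.0, both in steps of 0.05; a baseline of 0 is clamped to 0.05
#' since the model requires positive excitability) and computes the
#' across-node standard deviation of `deltaT` at every pair.  The pair
#' that maximizes this spread -- the most discriminative operating point
#' for ranking nodes -- is selected; ties break toward smaller `lambda0`,
#' then larger `lambda1`.  Baseline escape samples are computed once per
#' `lambda0` and shared across the row.
#'
#' @param G Coupling matrix from [normalize_coupling()].
#' @param grid0,grid1 Baseline / perturbed excitability grids.
#' @param n_realizations Realizations per condition (default 50).
#' @param seed Integer seed.
#' @param params A [z6_params()].
#' @return An object of class `lambda_grid`: `surface` tibble
#'   (`lambda0`, `lambda1`, `sd_delta_t`), `lambda0`, `lambda1` (the
#'   selected pair) and the search settings.
#' @export
grid_search_lambda <- function(G, grid0 = seq(0, 0.5, by = 0.05),
                               grid1 = seq(0.5, 1, by = 0.05),
                               n_realizations = 50L, seed = NULL,
                               params = z6_params()) {
  G <- as.matrix(G)
  N <- nrow(G)
  if (any(grid0 > 1) || any(grid1 > 1) || any(grid1 <= 0)) {
    abort("grids must lie within (0, 1]", class = "epitarget_invalid")
  }
  grid0 <- pmax(grid0, 0.05)
  surface <- tidyr::expand_grid(lambda0 = grid0, lambda1 = grid1)
  surface <- dplyr::filter(surface, .data$lambda0 <= .data$lambda1)
  t0_cache <- lapply(setNames(nm = as.character(grid0)), function(l0) {
    mean(network_escape_samples(G, rep(as.numeric(l0), N), params,
                                n_realizations, seed)$mean_tes)
  })
  sd_dt <- purrr::pmap_dbl(surface, function(lambda0, lambda1) {
    t0 <- t0_cache[[as.character(lambda0)]]
    dts <- vapply(seq_len(N), function(k) {
      lam <- rep(lambda0, N)
      lam[k] <- lambda1
      t0 - mean(network_escape_samples(G, lam, params, n_realizations,
                                       seed)$mean_tes)
    }, numeric(1))
    sd(dts)
  })
  surface$sd_delta_t <- sd_dt
  ranked <- dplyr::arrange(surface, dplyr::desc(.data$sd_delta_t),
                           .data$lambda0, dplyr::desc(.data$lambda1))
  structure(list(surface = surface, lambda0 = ranked$lambda0[1],
                 lambda1 = ranked$lambda1[1],
                 n_realizations = n_realizations, seed = seed,
                 params = params),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("<lambda_grid> %d pairs at %d realizations; selected lambda0=%.2f lambda1=%.2f\n",
              nrow(x$surface), x$n_realizations, x$lambda0, x$lambda1))
  invisible(x)
}

#' @describeIn grid_search_lambda The `(lambda0, lambda1, sd_delta_t)`
#'   surface as a tibble.
#' @param x A `lambda_grid`.
#' @param ... Unused.
#' @export
tidy.lambda_grid <- function(x, ...) x$surface

#' @describeIn grid_search_lambda One-row summary with the selected pair.
#' @export
glance.lambda_grid <- function(x, ...) {
  tibble(lambda0 = x$lambda0, lambda1 = x$lambda1,
         sd_delta_t = max(x$surface$sd_delta_t),
         n_realizations = x$n_realizations)
}
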