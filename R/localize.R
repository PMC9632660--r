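#' Localize the optimal neuromodulation target
#'
#' End-to-end localization: the recording is turned into a directed
#' network ([build_network()], DTF with surrogate analysis by default),
#' the network parameterizes the bistable model ([normalize_coupling()]),
#' the excitability pair is either fixed or chosen by
#' [grid_search_lambda()], and the channel with the largest escape-time
#' reduction [delta_t_map()] is selected as the target.  Exact
#' `deltaT` ties are broken toward the lexicographically smallest channel
#' label with a warning.
#'
#' @param rec An [mc_recording()] with at least 2 channels.
#' @param method Connectivity method token (default `"dtf-sa"`).
#' @param band Analysis band in Hz (default gamma, 31--80).
#' @param lambda0,lambda1 Excitability pair; when either is `NULL` the
#'   pair is selected by [grid_search_lambda()].
#' @param n_realizations Realizations for the perturbation map.
#' @param grid_realizations Realizations per grid-search condition.
#' @param seed Integer seed covering network surrogates, grid search and
#'   perturbation map.
#' @param params A [z6_params()].
#' @param electrodes Optional `electrode_set` for distance reporting.
#' @param n_surr,keep_frac,win_s,overlap_s,max_order Passed to
#'   [build_network()].
#' @return An object of class `target_report`; see [tidy.target_report()].
#' @export
#'
#' @examples
#' \donttest{
#' rec <- simulate_mvar5(5000, seed = 7)
#' rep <- localize_target(rec, lambda0 = 0.5, lambda1 = 0.85,
#'                        n_realizations = 20, seed = 7)
#' rep$target
#' }
localize_target <- function(rec, method = "dtf-sa", band = c(31, 80),
                            lambda0 = NULL, lambda1 = NULL,
                            n_realizations = 100L, grid_realizations = 50L,
                            seed = NULL, params = z6_params(),
                            electrodes = NULL, n_surr = 200L,
                            keep_frac = 0.05, win_s = 1.0, overlap_s = 0.5,
                            max_order = 20L) {
  if (!is_mc_recording(rec) || n_channels(rec) < 2L) {
    abort("need a recording with at least 2 channels",
          class = "epitarget_invalid")
  }
  network <- build_network(rec, method, band = band, win_s = win_s,
                           overlap_s = overlap_s, n_surr = n_surr,
                           keep_frac = keep_frac, seed = seed,
                           max_order = max_order)
  G <- normalize_coupling(network, K = params$K)
  grid <- NULL
  if (is.null(lambda0) || is.null(lambda1)) {
    grid <- grid_search_lambda(G, n_realizations = grid_realizations,
                               seed = seed, params = params)
    lambda0 <- grid$lambda0
    lambda1 <- grid$lambda1
  }
  dtm <- delta_t_map(G, lambda0, lambda1, n_realizations = n_realizations,
                     seed = seed, params = params)
  if (all(dtm$censor_frac >= 1) && dtm$censor_frac_baseline >= 1) {
    abort("all simulations censored: no escape observed in any condition",
          class = "epitarget_censored")
  }
  new_target_report(dtm, network = network, grid = grid, method = method,
                    band = band, seed = seed, electrodes = electrodes)
}

new_target_report <- function(dtm, network, grid, method, band, seed,
                              electrodes = NULL) {
  dvec <- dtm$delta_t
  top <- which(dvec >= max(dvec) - 1e-12)
  if (length(top) > 1L) {
    warn(sprintf("deltaT tie among %s; choosing the lexicographically smallest label",
                 paste(names(dvec)[top], collapse = ", ")),
         class = "epitarget_tie")
  }
  target <- sort(names(dvec)[top])[1]
  distance_mm <- if (!is.null(electrodes)) {
    tryCatch(distance_to_resection(target, electrodes),
             epitarget_no_resection = function(c) NA_real_)
  } else NA_real_
  structure(list(target = target, delta_t = dvec, t0 = dtm$t0,
                 lambda0 = dtm$lambda0, lambda1 = dtm$lambda1,
                 n_realizations = dtm$n_realizations,
                 censor_frac = dtm$censor_frac,
                 censor_frac_baseline = dtm$censor_frac_baseline,
                 method = canon_method(method), band = band, seed = seed,
                 distance_mm = distance_mm, network = network, grid = grid,
                 labels = dtm$labels),
            class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("<target_report> target = %s (deltaT = %.4g), method = %s, lambda = (%.2f, %.2f)\n",
              x$target, max(x$delta_t), method_label(x$method),
              x$lambda0, x$lambda1))
  if (!is.na(x$distance_mm)) {
    cat(sprintf("distance to nearest resected contact: %.1f mm\n",
                x$distance_mm))
  }
  invisible(x)
}

#' @describeIn localize_target One row per channel: `delta_t`,
#'   whether it is the selected target, and the censoring fraction.
#' @param x A `target_report`.
#' @param ... Unused.
#' @export
tidy.target_report <- function(x, ...) {
  tibble(channel = x$labels, delta_t = unname(x$delta_t),
         is_target = x$labels == x$target,
         censor_frac = unname(x$censor_frac))
}

#' @describeIn localize_target One-row run summary (target, excitability
#'   pair, method, band, seed, distance to resection when available).
#' @export
glance.target_report <- function(x, ...) {
  tibble(target = x$target, lambda0 = x$lambda0, lambda1 = x$lambda1,
         method = method_label(x$method), band_lo = x$band[1],
         band_hi = x$band[2], n_realizations = x$n_realizations,
         seed = x$seed %||% NA_integer_, distance_mm = x$distance_mm)
}

#' Virtual resection
#'
#' Removes the channels flagged as resected in `electrodes` *before*
#' network construction (the connectivity matrix is recomputed on the
#' surviving channels, giving a smaller network), then re-runs the
#' localization with a fixed excitability pair (defaults
#' `lambda0 = 0.22`, `lambda1 = 1`).
#'
#' @inheritParams localize_target
#' @param electrodes An `electrode_set` whose `resected` flags name the
#'   channels to drop; labels must cover the recording's channels.
#' @return A `target_report` on the resected network; resected labels do
#'   not appear in it.
#' @export
virtual_resection <- function(rec, electrodes, lambda0 = 0.22,
                              lambda1 = 1.0, method = "dtf-sa",
                              band = c(31, 80), n_realizations = 100L,
                              seed = NULL, params = z6_params(),
                              n_surr = 200L, keep_frac = 0.05,
                              win_s = 1.0, overlap_s = 0.5,
                              max_order = 20L) {
  stopifnot(inherits(electrodes, "electrode_set"))
  resected <- electrodes$label[electrodes$resected]
  keep <- !(channel_labels(rec) %in% resected)
  if (sum(keep) < 2L) {
    abort("fewer than 2 channels survive the resection",
          class = "epitarget_invalid")
  }
  sub <- if (all(keep)) rec else subset_channels(rec, keep)
  localize_target(sub, method = method, band = band, lambda0 = lambda0,
                  lambda1 = lambda1, n_realizations = n_realizations,
                  seed = seed, params = params, electrodes = electrodes,
                  n_surr = n_surr, keep_frac = keep_frac, win_s = win_s,
                  overlap_s = overlap_s, max_order = max_order)
}

#' Validate the localized target by inhibitory modulation
#'
#' Simulates inhibitory neuromodulation: one node at a time has its
#' excitability clamped to `lambda_inhib` (near-maximal stability,
#' default 0.01) while all others sit at `lambda0`, and the network escape
#' time is sampled over noise realizations.  An effective target should
#' delay network escape more than any other node.  Escape-time samples are
#' min-max normalized per network and the target-stimulation samples are
#' compared with the pooled non-target samples by a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param G Coupling matrix from [normalize_coupling()].
#' @param target Target channel label or index.
#' @param lambda0 Baseline excitability of the non-stimulated nodes.
#' @param lambda_inhib Inhibited excitability of the stimulated node.
#' @param n_realizations Realizations per stimulated node (default 100).
#' @param seed Integer seed.
#' @param params A [z6_params()].
#' @return A list of class `modulation_validation`: `samples` tibble
#'   (`stimulated`, `is_target`, `tes`, `tes_norm`), `p_value`,
#'   `median_target`, `median_nontarget` (of the normalized samples).
#' @export
validate_modulation <- function(G, target, lambda0 = 0.5,
                                lambda_inhib = 0.01,
                                n_realizations = 100L, seed = NULL,
                                params = z6_params()) {
  G <- as.matrix(G)
  N <- nrow(G)
  labels <- colnames(G) %||% paste0("ch", seq_len(N))
  if (is.character(target)) {
    target_idx <- match(target, labels)
    if (is.na(target_idx)) abort("unknown target label",
                                 class = "epitarget_invalid")
  } else {
    target_idx <- as.integer(target)
    stopifnot(target_idx >= 1L, target_idx <= N)
  }
  samples <- purrr::map_dfr(seq_len(N), function(s) {
    lam <- rep(lambda0, N)
    lam[s] <- lambda_inhib
    res <- network_escape_samples(G, lam, params, n_realizations, seed)
    tibble(stimulated = labels[s], is_target = s == target_idx,
           tes = res$mean_tes)
  })
  rng <- range(samples$tes)
  if (diff(rng) <= 0) {
    abort("degenerate escape samples (no variation; likely all censored)",
          class = "epitarget_censored")
  }
  samples$tes_norm <- (samples$tes - rng[1]) / diff(rng)
  pv <- wilcox.test(samples$tes_norm[samples$is_target],
                    samples$tes_norm[!samples$is_target],
                    alternative = "two.sided", exact = FALSE)$p.value
  structure(list(samples = samples, p_value = pv,
                 median_target = median(samples$tes_norm[samples$is_target]),
                 median_nontarget = median(samples$tes_norm[!samples$is_target]),
                 target = labels[target_idx], lambda0 = lambda0,
                 lambda_inhib = lambda_inhib,
                 n_realizations = n_realizations, seed = seed),
            class = "modulation_validation")
}

#' @export
print.modulation_validation <- function(x, ...) {
  cat(sprintf("<modulation_validation> target %s: median normalized Tes %.3g vs %.3g (non-target), rank-sum p = %.3g\n",
              x$target, x$median_target, x$median_nontarget, x$p_value))
  invisible(x)
}

#' Distance from a contact to the nearest resected contact
#'
#' Minimum Euclidean distance (mm) from the named contact to any contact
#' flagged as resected; zero when the contact is itself resected.  When no
#' contact is flagged, the distance is undefined and reported as missing
#' (with a condition of class `epitarget_no_resection`).
#'
#' @param target_label Contact label.
#' @param electrodes An `electrode_set`.
#' @return Distance in mm (scalar), or `NA` when no contact is resected.
#' @export
distance_to_resection <- function(target_label, electrodes) {
  stopifnot(inherits(electrodes, "electrode_set"))
  i <- match(target_label, electrodes$label)
  if (is.na(i)) abort("unknown contact label", class = "epitarget_invalid")
  res <- electrodes[electrodes$resected, , drop = FALSE]
  if (nrow(res) == 0) {
    cnd <- structure(class = c("epitarget_no_resection", "condition"),
                     list(message = "no resected contacts", call = NULL))
    withRestarts(signalCondition(cnd), muffle = function() NULL)
    return(NA_real_)
  }
  p <- c(electrodes$x_mm[i], electrodes$y_mm[i], electrodes$z_mm[i])
  min(sqrt((res$x_mm - p[1])^2 + (res$y_mm - p[2])^2 + (res$z_mm - p[3])^2))
}
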