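# ggplot2 methods for the package's result types.

#' @describeIn conn_matrix Heatmap of the weight matrix
#'   (receiver rows, sender columns).
#' @param object The object to plot.
#' @export
autoplot.conn_matrix <- function(object, ...) {
  df <- tidy(object, all_edges = TRUE)
  labs <- attr(object, "labels")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$sender, levels = labs),
    y = factor(.data$receiver, levels = rev(labs)),
    fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sender", y = "receiver",
                  fill = "weight",
                  title = method_label(attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' @describeIn delta_t_map Per-node bar chart of the escape-time change;
#'   the selected target is the largest bar.
#' @param object The object to plot.
#' @export
autoplot.delta_t_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$node, levels = object$labels),
    y = .data$delta_t)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = expression(Delta * T),
                  title = sprintf("Escape-time change (lambda0=%.2f, lambda1=%.2f)",
                                  object$lambda0, object$lambda1)) +
    ggplot2::theme_minimal()
}

#' @describeIn grid_search_lambda Tile plot of the deltaT spread over the
#'   excitability grid with the selected pair marked.
#' @param object The object to plot.
#' @export
autoplot.lambda_grid <- function(object, ...) {
  ggplot2::ggplot(object$surface, ggplot2::aes(
    x = .data$lambda0, y = .data$lambda1, fill = .data$sd_delta_t)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$lambda0, y = object$lambda1,
                      shape = 4, size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(lambda[0]), y = expression(lambda[1]),
                  fill = "sd(deltaT)") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_network Node magnitudes `|z_i(t)|` over time with
#'   the escape radius marked.
#' @param object The object to plot.
#' @param ... Unused.
#' @export
autoplot.z6_trajectories <- function(object, ...) {
  df <- tibble(
    time = rep(object$time, times = ncol(object$z)),
    node = rep(object$labels %||% paste0("ch", seq_len(ncol(object$z))),
               each = length(object$time)),
    magnitude = as.vector(Mod(object$z))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$magnitude,
                                   colour = .data$node)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$params$escape_radius,
                        linetype = "dashed") +
    ggplot2::labs(x = "time (model units)", y = "|z|") +
    ggplot2::theme_minimal()
}

#' @describeIn validate_modulation Box plot of normalized escape times for
#'   target vs non-target stimulation.
#' @param object The object to plot.
#' @param ... Unused.
#' @export
autoplot.modulation_validation <- function(object, ...) {
  df <- object$samples
  df$group <- ifelse(df$is_target, "target", "non-target")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$tes_norm)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::labs(x = NULL, y = "normalized escape time",
                  subtitle = sprintf("rank-sum p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}
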