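#' @export
print.mstdp_net <- function(x, ...) {
  cat(sprintf("<mstdp_net> %d visible x %d hidden (%s), %d presentations\n",
              nrow(x$weights$W), ncol(x$weights$W), x$config$mode,
              x$presentation))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  last eval: reconstruction loss %.3f, sparsity loss %.1f, symmetry %.3f\n",
                last$reconstruction_loss, last$sparsity_loss,
                last$symmetry_correlation))
  }
  invisible(x)
}

#' Tidy a trained network into a long weight table
#'
#' @param x An `mstdp_net`.
#' @param ... Unused.
#' @return Tibble with one row per connection: `visible`, `hidden`,
#'   `feedforward` (W), `feedback` (corresponding Q entry).
#' @export
tidy.mstdp_net <- function(x, ...) {
  W <- x$weights$W
  tibble(visible = rep(seq_len(nrow(W)), ncol(W)),
         hidden = rep(seq_len(ncol(W)), each = nrow(W)),
         feedforward = as.vector(W),
         feedback = as.vector(t(x$weights$Q)))
}

#' One-row summary of a trained network
#'
#' @param x An `mstdp_net`.
#' @param ... Unused.
#' @return One-row tibble: sizes, mode, presentations, final metrics from
#'   the last evaluation (NA if none), and the current symmetry correlation.
#' @export
glance.mstdp_net <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else NULL
  tibble(n_vis = nrow(x$weights$W), n_hid = ncol(x$weights$W),
         mode = x$config$mode, presentations = x$presentation,
         reconstruction_loss = last$reconstruction_loss %||% NA_real_,
         sparsity_loss = last$sparsity_loss %||% NA_real_,
         symmetry_correlation = symmetry_correlation(x$weights),
         mean_activation = last$mean_activation %||% NA_real_)
}

#' Plot the evaluation history of a trained network
#'
#' @param object An `mstdp_net`.
#' @param ... Unused.
#' @return A ggplot: reconstruction loss, sparsity loss (log scale via
#'   facet-free colour) and symmetry correlation over presentations.
#' @export
autoplot.mstdp_net <- function(object, ...) {
  if (!nrow(object$history)) abort("no evaluation history to plot")
  long <- tidyr::pivot_longer(
    object$history,
    c("reconstruction_loss", "sparsity_loss", "symmetry_correlation"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$presentation, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "presentation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a grid of receptive fields
#'
#' @param object An `mstdp_rf` tibble from [receptive_fields()].
#' @param ncol Number of grid columns (default: square-ish).
#' @param ... Unused.
#' @return A ggplot raster grid, one panel per hidden unit, diverging scale
#'   centred at zero (ON-dominant pixels light, OFF-dominant dark).
#' @export
autoplot.mstdp_rf <- function(object, ncol = NULL, ...) {
  ncol <- ncol %||% ceiling(sqrt(max(object$unit)))
  ggplot2::ggplot(object, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~unit, ncol = ncol) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Spike raster plot for one trial
#'
#' @param spikes Spike tibble from [simulate_trial()].
#' @param stimulus_end Optional end of the external input window (ms), drawn
#'   as a shaded band from 0.
#' @return A ggplot raster (time vs neuron, one panel per population).
#' @export
plot_spike_raster <- function(spikes, stimulus_end = attr(spikes, "stimulus_end")) {
  p <- ggplot2::ggplot(spikes, ggplot2::aes(.data$time_ms, .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
  if (!is.null(stimulus_end)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = stimulus_end,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}
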