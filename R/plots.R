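clarke_grid_segments <- function(lim = 400) {
  data.frame(
    x = c(58.33, 70, 0, 70, 0, 70, 130, 180, 240, 240, 70),
    y = c(70, 56, 70, 84, 180, 180, 0, 70, 70, 180, 0),
    xend = c(lim / 1.2, lim, 58.33, 70, 70, min(lim - 110, 290), 180, lim,
             240, lim, 70),
    yend = c(lim, 0.8 * lim, 70, lim, 180, min(lim, 400), 70, 70, 180, 180,
             56))
}

zone_label_positions <- function() {
  data.frame(zone = c("A", "B", "B", "C", "C", "D", "D", "E", "E"),
             x = c(220, 280, 140, 160, 160, 30, 320, 30, 330),
             y = c(220, 340, 50, 370, 15, 130, 130, 330, 30))
}

#' Clarke error grid plot
#'
#' Scatter of estimated versus reference glucose with the canonical Clarke
#' zone boundaries drawn and points colored by zone.
#'
#' @inheritParams mard
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_cega <- function(estimates, references, title = "Clarke error grid") {
  check_pairs(estimates, references)
  lim <- max(400, references, estimates)
  pts <- data.frame(reference = references, estimate = estimates,
                    zone = clarke_zone(references, estimates))
  segs <- clarke_grid_segments(lim)
  labs <- zone_label_positions()
  ggplot2::ggplot(pts, ggplot2::aes(x = reference, y = estimate)) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
                          inherit.aes = FALSE, linewidth = 0.3,
                          color = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_text(data = labs, ggplot2::aes(x = x, y = y, label = zone),
                       inherit.aes = FALSE, color = "grey30", size = 5) +
    ggplot2::geom_point(ggplot2::aes(color = zone), size = 1.6,
                        alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(A = "#1b9e77", B = "#7570b3",
                                           C = "#e6ab02", D = "#d95f02",
                                           E = "#e7298a"), drop = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, lim), ylim = c(0, lim), expand = FALSE) +
    ggplot2::labs(title = title, x = "Reference glucose (mg/dL)",
                  y = "Estimated glucose (mg/dL)", color = "Zone") +
    ggplot2::theme_minimal()
}

#' Training loss curves plot
#'
#' Per-cluster sum-of-squared-error training curves of the selected MLP
#' models, used to check convergence (no under-/over-fitting plateau
#' anomalies) after hyperparameter selection.
#'
#' @param curves data.frame with columns `cluster`, `iteration`, `sse`
#'   (as written by [run_calibrate()]).
#' @return A ggplot object.
#' @export
plot_loss_curves <- function(curves) {
  stopifnot(all(c("cluster", "iteration", "sse") %in% names(curves)))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = iteration, y = sse,
                               group = factor(cluster))) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~cluster, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Training iteration", y = "Sum of squared errors") +
    ggplot2::theme_minimal()
}
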