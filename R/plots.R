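# ggplot2 figures for each result type. Analysis never depends on these;
# they render the tibbles the pipeline already produced.

#' Plot a band line-scan profile
#'
#' Normalized intensity of each channel against the signed distance from
#' the center-line (dotted line at x = 0).
#'
#' @param profile A `linescan_profile` (or a pooled tibble with the same
#'   columns plus an optional `roi_id`).
#' @param peaks Optional peak tibble from [call_peaks()] to overlay.
#' @return A ggplot object.
#' @export
plot_linescan <- function(profile, peaks = NULL) {
  roles <- attr(profile, "channel_roles")
  if (is.null(roles)) roles <- c("Bassoon", "PSD95", "Dyn1xA")
  long <- tidyr::pivot_longer(tibble::as_tibble(profile),
                              cols = dplyr::ends_with("_norm"),
                              names_to = "channel", values_to = "intensity")
  long$channel <- roles[as.integer(sub("^CH(\\d+)_norm$", "\\1",
                                       long$channel))]
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x_nm,
                                          y = .data$intensity,
                                          colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "distance from center-line (nm)",
                  y = "normalized intensity", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    g <- g + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$x_nm, y = .data$amplitude),
      inherit.aes = FALSE, shape = 4, size = 2)
  }
  g
}

#' Plot a punctum-to-boundary distance summary
#'
#' Histogram of signed distances with the periactive-zone band shaded and
#' the cumulative distribution overlaid.
#'
#' @param summary Result of [distance_summary()].
#' @param band Band to shade (default -50 to 50 nm).
#' @return A ggplot object.
#' @export
plot_distance_summary <- function(summary, band = c(-50, 50)) {
  h <- summary$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid_nm, y = .data$count)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_col(width = diff(h$bin_mid_nm[1:2]) * 0.9) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "signed distance to active-zone boundary (nm)",
                  y = "puncta") +
    ggplot2::theme_minimal()
}

#' Plot per-profile structure counts
#'
#' @param counts Tibble from [count_profile()].
#' @return A ggplot object.
#' @export
plot_profile_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts, cols = dplyr::starts_with("n_"),
                              names_to = "structure", values_to = "count")
  long$structure <- sub("^n_", "", long$structure)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$structure, y = .data$count)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0.05, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "count per synaptic profile") +
    ggplot2::theme_minimal()
}

#' Plot a calcium trace with its fit
#'
#' @param norm_trace A `normalized_trace` (baseline 1, minimum 0).
#' @param fit Optional `ca_expfit` to overlay.
#' @return A ggplot object.
#' @export
plot_calcium_trace <- function(norm_trace, fit = NULL) {
  g <- ggplot2::ggplot(norm_trace, ggplot2::aes(x = .data$t_ms,
                                                y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "time (ms)", y = "normalized fluorescence") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && is.finite(fit$tau_ms)) {
    t <- norm_trace$t_ms[norm_trace$t_ms >= fit$t0_ms]
    pred <- tibble::tibble(
      t_ms = t,
      value = 1 + (fit$A * exp(-(t - fit$t0_ms) / fit$tau_ms) + fit$C) /
        abs(fit$minimum))
    g <- g + ggplot2::geom_line(data = pred, colour = "red",
                                linetype = "dashed")
  }
  g
}
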