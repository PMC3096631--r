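#' Plot a mismatch-by-position profile
#'
#' Mismatch ratio against read position (sequencing cycle); a rising curve is
#' the signature of 3'-end signal decay in GA-style data.
#'
#' @param object a `mismatch_profile` from [mismatch_by_position()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mismatch_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       y = .data$mismatch_ratio)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Base position in read (cycle)",
                  y = "Mismatch ratio",
                  title = "Mismatch ratio by read position") +
    ggplot2::theme_minimal()
}

#' Plot a saturation fit
#'
#' Observed (coverage, TP) points with the fitted curve
#' `TP(n) = T (1 - A n^-B)` and its asymptote.
#'
#' @param object a `saturation_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(n = exp(seq(log(min(d$n)), log(max(d$n)), length.out = 200)))
  grid$TP <- predict(object, grid$n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$TP)) +
    ggplot2::geom_hline(yintercept = object$T_total, linetype = "dotted") +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean coverage (fold)", y = "True positives",
                  title = "Detection saturation: TP(n) = T (1 - A n^-B)") +
    ggplot2::theme_minimal()
}

#' Plot coverage depth along the reference
#'
#' @param depth a `depth_track` from [depth_and_uncovered()].
#' @param window smoothing window in bases (mean depth per window).
#' @return A ggplot.
#' @export
plot_depth <- function(depth, window = 100L) {
  stopifnot(inherits(depth, "depth_track"))
  d <- depth$depth
  G <- length(d)
  bins <- ceiling(seq_along(d) / window)
  smoothed <- tibble(
    position = tapply(seq_len(G) - 1L, bins, mean),
    depth = tapply(d, bins, mean)
  )
  ggplot2::ggplot(smoothed, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = depth$mean_coverage, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(x = "Genome position (bp)", y = sprintf("Depth (%d bp mean)", window)) +
    ggplot2::theme_minimal()
}
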