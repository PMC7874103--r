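#' Plot a delta-index window profile
#'
#' Delta index per window along each chromosome, one panel per variant
#' class, with the threshold line and called regions shaded.
#'
#' @param object A `bsa_scan` from [run_association()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_scan <- function(object, ...) {
  w <- object$windows
  w <- w[!is.na(w$delta), , drop = FALSE]
  mid <- (w$start + w$end) / 2
  p <- ggplot2::ggplot(w, ggplot2::aes(x = mid / 1e6, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), colour = "blue",
                       linetype = "dashed") +
    ggplot2::facet_grid(.data$variant_class ~ .data$chrom) +
    ggplot2::labs(x = "position (Mbp)", y = expression(Delta ~ "index"),
                  title = "Delta index profile (dashed: 95% null threshold)") +
    ggplot2::theme_minimal()
  reg <- object$regions[object$regions$source == "overlap", , drop = FALSE]
  if (nrow(reg) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = reg$start / 1e6,
                               xmax = reg$end / 1e6, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "red")
  }
  p
}

#' @rdname autoplot.bsa_scan
#' @param scan A `bsa_scan`.
#' @export
plot_delta_profile <- function(scan) autoplot.bsa_scan(scan)
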