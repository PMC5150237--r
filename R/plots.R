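#' Plot a randomization-test result
#'
#' Histogram of the simulated index means with the observed mean marked by a
#' dashed vertical line.
#'
#' @param x A `randomization_test`.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments to [graphics::hist()].
#' @export
plot.randomization_test <- function(x, breaks = 40, ...) {
  graphics::hist(x$simulated_means, breaks = breaks, col = "steelblue",
                 border = "white",
                 main = sprintf("%s (p = %.4g)", x$index, x$p_two_tailed),
                 xlab = sprintf("Randomized mean %s", x$index), ...)
  graphics::abline(v = x$observed_mean, lty = 2, lwd = 2)
  invisible(x)
}

#' Plot a predicted choice curve with its confidence band
#'
#' @param x A `choice_curve` from [predicted_choice_curve()].
#' @param add Add to an existing plot.
#' @param col Curve colour.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.choice_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    graphics::plot(x$MHC_INDEX, x$fit, type = "n", ylim = c(0, max(x$upr)),
                   xlab = "MHC index", ylab = "P(chosen)", ...)
  }
  shade <- grDevices::adjustcolor(col, alpha.f = 0.3)
  graphics::polygon(c(x$MHC_INDEX, rev(x$MHC_INDEX)), c(x$lwr, rev(x$upr)),
                    col = shade, border = NA)
  graphics::lines(x$MHC_INDEX, x$fit, col = col, lwd = 2)
  invisible(x)
}
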