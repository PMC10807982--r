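#' Plot a trajectory
#'
#' Line plot of the naive (dotted), inefficient (dashed) and efficient
#' (solid) fractions against time.
#'
#' @param x A `culture_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.culture_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states[, c("e", "i", "n")], type = "l",
                    lty = c(1, 2, 3), col = "black", xlab = "time",
                    ylab = "fraction of population", ylim = c(0, 1), ...)
  graphics::legend("right", legend = c("efficient e(t)", "inefficient i(t)",
                                       "naive n(t)"),
                   lty = c(1, 2, 3), bty = "n")
  invisible(x)
}

#' Plot a sweep grid as a heatmap
#'
#' Image of the swept quantity over the two axes; unreachable cells are
#' left blank.
#'
#' @param x A `sweep_grid`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sweep_grid <- function(x, ...) {
  graphics::image(x$axis1$values, x$axis2$values, x$values,
                  xlab = x$axis1$name, ylab = x$axis2$name,
                  main = x$quantity, ...)
  invisible(x)
}
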