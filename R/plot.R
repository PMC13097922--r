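#' Plot an SIR curve with its fitted model
#'
#' Data points, the fitted composite curve, and — for the bi-component
#' model — each component drawn separately (Gaussian bulk-flow and
#' gamma-variate perfusion-like terms).
#'
#' @param x An `sir_fit` object.
#' @param curve The `sir_curve` that was fitted (for the data points).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.sir_fit <- function(x, curve = NULL, ...) {
  supp <- model_support(x$model, x$params)
  lo <- if (!is.null(curve)) min(supp[1], min(curve$ti)) else supp[1]
  hi <- if (!is.null(curve)) max(supp[2], max(curve$ti)) else supp[2]
  tt <- seq(lo, hi, length.out = 400)
  y <- eval_model(x$model, x$params, tt)
  ylim <- range(0, y, if (!is.null(curve)) curve$sir)
  graphics::plot(tt, y, type = "l", lwd = 2, col = "red3",
                 xlab = "TI [ms]", ylab = "SIR", ylim = ylim, ...)
  if (x$model == "bicomponent") {
    graphics::lines(tt, eval_gamma_variate(x$params$gamma, tt),
                    col = "steelblue", lwd = 1.5, lty = 2)
    graphics::lines(tt, eval_gaussian(x$params$gaussian, tt),
                    col = "forestgreen", lwd = 1.5, lty = 2)
    graphics::legend("topright", bty = "n", lwd = c(2, 1.5, 1.5),
                     lty = c(1, 2, 2),
                     col = c("red3", "steelblue", "forestgreen"),
                     legend = c("bi-component", "gamma-variate", "Gaussian"))
  }
  if (!is.null(curve))
    graphics::points(curve$ti, curve$sir, pch = 16)
  graphics::title(sub = sprintf("R2 = %.3f, RMSE = %.3g",
                                x$gof$r2, x$gof$rmse))
  invisible(x)
}
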