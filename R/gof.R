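#' Goodness-of-fit metrics for a fitted SIR curve
#'
#' @param observed An `sir_curve` object (or numeric vector of observed
#'   SIR values).
#' @param predicted Numeric vector of model predictions at the observed
#'   TIs, same length.
#' @return A list of class `gof` with `sse` (sum of squared errors),
#'   `r2` (coefficient of determination, `NA` with `r2_undefined = TRUE`
#'   for a constant observed curve) and `rmse` (`sqrt(SSE/n)`, n = number
#'   of samples).
#' @export
#' @examples
#' goodness_of_fit(c(0, 0.2, 0.4), c(0.1, 0.2, 0.3))  # SSE 0.02
goodness_of_fit <- function(observed, predicted) {
  obs <- if (inherits(observed, "sir_curve")) observed$sir else observed
  stopifnot(is.numeric(obs), is.numeric(predicted))
  n <- length(obs)
  if (n < 2 || length(predicted) != n)
    stop("observed and predicted must have equal length >= 2")
  sse <- sum((obs - predicted)^2)
  sst <- sum((obs - mean(obs))^2)
  r2_undefined <- sst == 0
  r2 <- if (r2_undefined) NA_real_ else 1 - sse / sst
  structure(list(sse = sse, r2 = r2, rmse = sqrt(sse / n),
                 r2_undefined = r2_undefined, n = n),
            class = "gof")
}

#' @export
print.gof <- function(x, ...) {
  cat(sprintf("R2 = %s | SSE = %.4g | RMSE = %.4g (n = %d)\n",
              if (x$r2_undefined) "undefined" else sprintf("%.4f", x$r2),
              x$sse, x$rmse, x$n))
  invisible(x)
}

# Small-sample-corrected AIC from SSE under i.i.d. Gaussian errors.
# k counts the free model parameters. Returns +Inf when the correction
# denominator n - k - 1 is not positive (model too rich for the data).
aicc_from_sse <- function(sse, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  n * log(max(sse, .Machine$double.xmin) / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}
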