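#' Gamma-variate model parameters
#'
#' Parameter set for the perfusion-like (slow) component of the Time-SLIP
#' signal increase ratio: `SIR(TI) = f * (TI - delta_t) * exp(-(TI - delta_t) / t1_app)`
#' for `TI >= delta_t`, and 0 before bolus arrival.
#'
#' @param f Perfusion-like scale factor, in 1/ms. Must be >= 0.
#' @param delta_t Bolus arrival time in ms. Must be >= 0.
#' @param t1_app Apparent longitudinal relaxation time in ms governing the
#'   decay of the tagged component. Must be > 0.
#' @return An object of class `gamma_variate_params`.
#' @export
#' @examples
#' p <- gamma_variate_params(f = 1e-3, delta_t = 200, t1_app = 1000)
#' eval_gamma_variate(p, 1200)  # peak value f * t1_app / e
gamma_variate_params <- function(f, delta_t, t1_app) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f), f >= 0,
            is.numeric(delta_t), length(delta_t) == 1L, is.finite(delta_t), delta_t >= 0,
            is.numeric(t1_app), length(t1_app) == 1L, is.finite(t1_app), t1_app > 0)
  structure(list(f = unname(f), delta_t = unname(delta_t),
                 t1_app = unname(t1_app)),
            class = "gamma_variate_params")
}

#' Windowed Gaussian (bulk flow) model parameters
#'
#' Parameter set for the fast bulk-flow component: an offset Gaussian
#' restricted to the bolus passage window `[delta_t, delta_t + 4 * tau]`,
#' `SIR(TI) = A * (exp(-((TI - delta_t) - 2*tau)^2 / (2*tau^2)) - exp(-2))`
#' inside the window and exactly 0 outside. The `exp(-2)` offset makes the
#' curve continuous (zero) at both window edges; the peak
#' `A * (1 - exp(-2))` occurs at `TI = delta_t + 2*tau`.
#'
#' @param amplitude Dimensionless Gaussian amplitude A. Must be >= 0.
#' @param delta_t Bolus arrival time in ms. Must be >= 0.
#' @param tau Temporal spread in ms. Must be >= 0; `tau = 0` gives a
#'   degenerate (everywhere zero) component.
#' @return An object of class `gaussian_params`.
#' @export
#' @examples
#' p <- gaussian_params(amplitude = 1, delta_t = 0, tau = 500)
#' eval_gaussian(p, 1000)  # peak value 1 - exp(-2)
gaussian_params <- function(amplitude, delta_t, tau) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude), amplitude >= 0,
            is.numeric(delta_t), length(delta_t) == 1L, is.finite(delta_t), delta_t >= 0,
            is.numeric(tau), length(tau) == 1L, is.finite(tau), tau >= 0)
  structure(list(amplitude = unname(amplitude), delta_t = unname(delta_t),
                 tau = unname(tau)),
            class = "gaussian_params")
}

#' Bi-component model parameters
#'
#' Combines a windowed Gaussian bulk-flow component with a gamma-variate
#' perfusion-like component. The physical ordering of bolus propagation
#' requires the Gaussian arrival to precede the gamma-variate arrival
#' (`gaussian$delta_t < gamma$delta_t`) unless the gamma-variate term has
#' been suppressed, in which case its scale `f` must be 0.
#'
#' @param gamma A [gamma_variate_params()] object.
#' @param gaussian A [gaussian_params()] object.
#' @param gamma_suppressed Logical; `TRUE` when the model-selection rule
#'   removed the perfusion-like term (then `gamma$f` must be 0).
#' @return An object of class `bicomponent_params`.
#' @export
bicomponent_params <- function(gamma, gaussian, gamma_suppressed = FALSE) {
  stopifnot(inherits(gamma, "gamma_variate_params"),
            inherits(gaussian, "gaussian_params"),
            is.logical(gamma_suppressed), length(gamma_suppressed) == 1L)
  if (gamma_suppressed) {
    if (gamma$f != 0)
      stop("gamma_suppressed = TRUE requires gamma$f == 0")
  } else if (gamma$f > 0 && gaussian$amplitude > 0 &&
             !(gaussian$delta_t < gamma$delta_t)) {
    stop("ordering constraint violated: gaussian delta_t must be < gamma delta_t")
  }
  structure(list(gamma = gamma, gaussian = gaussian,
                 gamma_suppressed = gamma_suppressed),
            class = "bicomponent_params")
}

#' Evaluate the gamma-variate component
#'
#' @param p A [gamma_variate_params()] object.
#' @param ti Numeric vector of inversion times in ms.
#' @return Numeric vector of dimensionless SIR values; 0 for `ti < delta_t`
#'   (the tagged bolus has not arrived), continuous at `ti = delta_t`.
#' @export
eval_gamma_variate <- function(p, ti) {
  stopifnot(inherits(p, "gamma_variate_params"))
  if (!is.numeric(ti) || any(!is.finite(ti)))
    stop("ti must be finite numeric")
  u <- ti - p$delta_t
  out <- ifelse(u > 0, p$f * u * exp(-u / p$t1_app), 0)
  as.numeric(out)
}

#' Evaluate the windowed Gaussian component
#'
#' @param p A [gaussian_params()] object.
#' @param ti Numeric vector of inversion times in ms.
#' @return Numeric vector of dimensionless SIR values; exactly 0 outside
#'   the window `[delta_t, delta_t + 4*tau]` and at both window edges.
#' @export
eval_gaussian <- function(p, ti) {
  stopifnot(inherits(p, "gaussian_params"))
  if (!is.numeric(ti) || any(!is.finite(ti)))
    stop("ti must be finite numeric")
  if (p$tau == 0) return(numeric(length(ti)))  # degenerate window
  u <- ti - p$delta_t
  inside <- u >= 0 & u <= 4 * p$tau
  out <- numeric(length(ti))
  out[inside] <- p$amplitude *
    (exp(-(u[inside] - 2 * p$tau)^2 / (2 * p$tau^2)) - exp(-2))
  out
}

#' Evaluate the bi-component model
#'
#' Sum of the gamma-variate and windowed Gaussian components.
#'
#' @param p A [bicomponent_params()] object.
#' @param ti Numeric vector of inversion times in ms.
#' @return Numeric vector of dimensionless SIR values.
#' @export
eval_bicomponent <- function(p, ti) {
  stopifnot(inherits(p, "bicomponent_params"))
  eval_gamma_variate(p$gamma, ti) + eval_gaussian(p$gaussian, ti)
}

# Dispatch a model id + params to its evaluation function.
eval_model <- function(model, params, ti) {
  switch(model,
         gamma = eval_gamma_variate(params, ti),
         gaussian = eval_gaussian(params, ti),
         bicomponent = eval_bicomponent(params, ti),
         stop("unknown model id: ", model))
}

# Support interval [lo, hi] over which a model can be non-zero, used to
# build descriptor grids. The gamma-variate has infinite support; its tail
# is truncated where it falls below `tail_frac` of the peak.
model_support <- function(model, params, tail_frac = 1e-4) {
  if (model == "gaussian") {
    c(params$delta_t, params$delta_t + 4 * params$tau)
  } else if (model == "gamma") {
    if (params$f == 0) return(c(0, 0))
    # solve u * exp(-u/T) = tail_frac * T/e on the decaying flank
    t1 <- params$t1_app
    upper <- params$delta_t + t1 * (1 + 25)  # u e^-u < 1e-9 at u = 26
    g <- function(ti) eval_gamma_variate(params, ti) -
      tail_frac * params$f * t1 * exp(-1)
    hi <- stats::uniroot(g, lower = params$delta_t + t1, upper = upper)$root
    c(params$delta_t, hi)
  } else if (model == "bicomponent") {
    sg <- model_support("gaussian", params$gaussian)
    sgam <- if (params$gamma$f > 0) model_support("gamma", params$gamma) else sg
    range(sg, sgam)
  } else stop("unknown model id: ", model)
}
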