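#' Model-selection configuration for the bi-component fit
#'
#' The composite model retains its gamma-variate (perfusion-like) term
#' only when that term substantially improves the fit over a Gaussian-only
#' model fitted in parallel. The default rule requires both (i) a lower
#' small-sample-corrected AIC (AICc, with k = number of free parameters)
#' and (ii) a relative SSE reduction of at least `rel_sse_min`. Otherwise
#' the gamma-variate term is suppressed (`f = 0`) and the Gaussian-only
#' result is returned.
#'
#' @param use_aicc Require AICc(composite) < AICc(Gaussian-only).
#' @param rel_sse_min Minimum relative SSE reduction
#'   `(SSE_gauss - SSE_comp) / SSE_gauss` needed to keep the term
#'   (default 0.10).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(use_aicc = TRUE, rel_sse_min = 0.10) {
  stopifnot(is.logical(use_aicc), is.numeric(rel_sse_min),
            rel_sse_min >= 0, rel_sse_min < 1)
  structure(list(use_aicc = use_aicc, rel_sse_min = rel_sse_min),
            class = "selection_config")
}

# Deterministic multi-start grids. Arrival-time starts sit at the
# quartiles of the observed TI range; spread/relaxation starts are 3
# log-spaced values inside their bounds; amplitudes are initialized from
# the observed peak.
logspace3 <- function(lo, hi) exp(seq(log(lo), log(hi), length.out = 3))

# crude observed-peak geometry used to seed the optimizer: peak location,
# half-maximum width (linear interpolation) and first-rise time
observed_peak <- function(curve) {
  y <- curve$sir; ti <- curve$ti
  imax <- which.max(y)
  smax <- max(y)
  half <- smax / 2
  t_left <- ti[1]
  if (imax > 1) {
    below <- which(y[seq_len(imax - 1)] < half)
    if (length(below)) {
      i <- max(below)
      t_left <- ti[i] + (half - y[i]) * (ti[i + 1] - ti[i]) / (y[i + 1] - y[i])
    }
  }
  t_right <- ti[length(ti)]
  if (imax < length(y)) {
    below <- which(y[(imax + 1):length(y)] < half)
    if (length(below)) {
      i <- imax + min(below)
      t_right <- ti[i - 1] + (y[i - 1] - half) * (ti[i] - ti[i - 1]) /
        (y[i - 1] - y[i])
    }
  }
  rise <- which(y >= 0.1 * smax)
  list(ttp = ti[imax], smax = smax,
       hw = max(t_right - t_left, diff(range(ti)) / 20),
       onset = if (length(rise)) ti[max(min(rise) - 1, 1)] else ti[1])
}

start_grid_single <- function(curve, model, bounds) {
  span <- diff(range(curve$ti))
  smax <- max(max(curve$sir), .Machine$double.eps)
  pk <- observed_peak(curve)
  clip <- function(x, b) pmin(pmax(x, b[1]), b[2])
  if (model == "gamma") {
    dt0 <- clip(min(curve$ti) + c(0, 0.25, 0.5, 0.75) * span, bounds$delta_t)
    t1s <- logspace3(max(bounds$t1_app[1], 50), bounds$t1_app[2])
    g <- expand.grid(delta_t = unique(dt0), t1_app = t1s)
    # data-driven: peak sits at delta_t + t1_app
    t1_pk <- clip(pmax(pk$ttp - pk$onset, 50), bounds$t1_app)
    g <- rbind(g, data.frame(delta_t = clip(pk$onset, bounds$delta_t),
                             t1_app = t1_pk))
    g$f <- pmin(smax * exp(1) / g$t1_app, bounds$f[2])
    lapply(seq_len(nrow(g)), function(i)
      c(f = g$f[i], delta_t = g$delta_t[i], t1_app = g$t1_app[i]))
  } else {
    # FWHM of the windowed Gaussian is ~2.13 tau; peak sits at delta_t + 2 tau
    tau_pk <- pk$hw / (2 * sqrt(2 * log(2 / (1 + exp(-2)))))
    taus <- unique(clip(c(tau_pk * c(0.5, 1, 2),
                          logspace3(max(span / 40, 10),
                                    min(bounds$tau[2], span))),
                        c(max(bounds$tau[1], 10), bounds$tau[2])))
    g <- data.frame(delta_t = clip(pk$ttp - 2 * taus, bounds$delta_t),
                    tau = taus)
    dt0 <- clip(min(curve$ti) + c(0, 0.25, 0.5, 0.75) * span, bounds$delta_t)
    g <- rbind(g, expand.grid(delta_t = unique(dt0),
                              tau = clip(tau_pk, c(10, bounds$tau[2]))))
    amp <- min(smax / (1 - exp(-2)), bounds$amplitude[2])
    lapply(seq_len(nrow(g)), function(i)
      c(amplitude = amp, delta_t = g$delta_t[i], tau = g$tau[i]))
  }
}

run_multistart <- function(starts, lower, upper, resid_fn) {
  best <- NULL
  used <- 0L
  for (p0 in starts) {
    used <- used + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper),
                         lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-15)
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) return(NULL)
  best$n_starts_used <- used
  best
}

# Exact solution of min ||y - c1*x1 - c2*x2||^2 subject to
# 0 <= c1 <= u1, 0 <= c2 <= u2 (2-variable box-constrained least squares).
# Tries the interior stationary point, then every edge with the other
# coefficient re-optimized in 1-D and clipped, and keeps the best.
ls_box2 <- function(y, x1, x2, u1, u2) {
  ls1 <- function(x, r, u) {
    s2 <- sum(x^2)
    if (s2 == 0) return(0)
    min(max(sum(x * r) / s2, 0), u)
  }
  cand <- list()
  a11 <- sum(x1^2); a22 <- sum(x2^2); a12 <- sum(x1 * x2)
  det <- a11 * a22 - a12^2
  if (det > 1e-12 * max(a11 * a22, 1e-300)) {
    b1 <- sum(x1 * y); b2 <- sum(x2 * y)
    c1 <- (a22 * b1 - a12 * b2) / det
    c2 <- (a11 * b2 - a12 * b1) / det
    if (c1 >= 0 && c1 <= u1 && c2 >= 0 && c2 <= u2)
      cand[[length(cand) + 1L]] <- c(c1, c2)
  }
  for (c1 in c(0, u1))
    cand[[length(cand) + 1L]] <- c(c1, ls1(x2, y - c1 * x1, u2))
  for (c2 in c(0, u2))
    cand[[length(cand) + 1L]] <- c(ls1(x1, y - c2 * x2, u1), c2)
  sse <- vapply(cand, function(cc) sum((y - cc[1] * x1 - cc[2] * x2)^2),
                numeric(1))
  cand[[which.min(sse)]]
}

make_fit_result <- function(model, params, curve, n_starts,
                            selection = NULL, degenerate = FALSE) {
  pred <- eval_model(model, params, curve$ti)
  gof <- goodness_of_fit(curve, pred)
  desc <- curve_descriptors(model, params)
  structure(list(model = model, params = params, gof = gof,
                 descriptors = desc, selection = selection,
                 n_starts_used = n_starts, degenerate = degenerate,
                 curve_label = curve$label),
            class = "sir_fit")
}

#' Fit a single-component model to an SIR curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints) from a deterministic grid of starting points; the best
#' converged start is returned. The procedure is fully deterministic for
#' a given curve and configuration.
#'
#' @param curve An `sir_curve` object with at least 4 samples.
#' @param model `"gamma"` or `"gaussian"`.
#' @param bounds Optional [default_bounds()] result; built from the curve
#'   when NULL.
#' @param starts Optional list of named numeric start vectors; default is
#'   the deterministic grid described above.
#' @return An object of class `sir_fit`: fitted parameter object, `gof`
#'   ([goodness_of_fit()] at the observed TIs), `descriptors`
#'   ([curve_descriptors()]), and `n_starts_used`.
#' @export
#' @examples
#' truth <- gaussian_params(0.6, 400, 300)
#' crv <- sir_curve(ti_grid("invivo"), eval_gaussian(truth, ti_grid("invivo")))
#' fit_single(crv, "gaussian")
fit_single <- function(curve, model = c("gamma", "gaussian"),
                       bounds = NULL, starts = NULL) {
  stopifnot(inherits(curve, "sir_curve"))
  model <- match.arg(model)
  if (length(curve$ti) < 4)
    stop("at least 4 samples are required for a fit")
  if (is.null(bounds)) bounds <- default_bounds(curve, model)
  if (is.null(starts)) starts <- start_grid_single(curve, model, bounds)

  if (model == "gamma") {
    lower <- c(bounds$f[1], bounds$delta_t[1], bounds$t1_app[1])
    upper <- c(bounds$f[2], bounds$delta_t[2], bounds$t1_app[2])
    resid <- function(p) curve$sir -
      eval_gamma_variate(gamma_variate_params(p[1], p[2], p[3]), curve$ti)
  } else {
    lower <- c(bounds$amplitude[1], bounds$delta_t[1], bounds$tau[1])
    upper <- c(bounds$amplitude[2], bounds$delta_t[2], bounds$tau[2])
    resid <- function(p) curve$sir -
      eval_gaussian(gaussian_params(p[1], p[2], p[3]), curve$ti)
  }
  best <- run_multistart(starts, lower, upper, resid)
  if (is.null(best))
    stop(sprintf("no start converged for model '%s' on curve '%s'",
                 model, curve$label %||% "<unnamed>"))
  params <- if (model == "gamma")
    gamma_variate_params(best$par[1], best$par[2], best$par[3])
  else
    gaussian_params(best$par[1], best$par[2], best$par[3])
  make_fit_result(model, params, curve, best$n_starts_used,
                  degenerate = isTRUE(bounds$degenerate))
}

#' Fit the bi-component model with automatic gamma-variate suppression
#'
#' Fits the 5-free-parameter composite (gamma-variate scale `f` and
#' arrival `delta_t_gamma`; Gaussian `amplitude`, `delta_t_g`, `tau`; the
#' apparent T1 of the slow term fixed at 2000 ms), with the bolus-ordering
#' constraint `delta_t_g < delta_t_gamma` enforced by the
#' reparameterization `delta_t_gamma = delta_t_g + delta`, `delta >= 1` ms
#' (capped at the 2000 ms arrival bound). A Gaussian-only model is fitted
#' in parallel; the gamma-variate term is retained only when the
#' [selection_config()] rule judges its contribution substantial,
#' otherwise the Gaussian-only result is returned with
#' `gamma_suppressed = TRUE` and `f = 0`.
#'
#' @param curve An `sir_curve` object.
#' @param bounds Optional [default_bounds()] for `"bicomponent"`.
#' @param selection A [selection_config()].
#' @param starts Optional list of start vectors
#'   `(f, delta, amplitude, delta_t_g, tau)`.
#' @return An `sir_fit` whose `selection` field records both candidate
#'   SSEs, the AICc values, the relative SSE reduction, and the decision.
#' @export
fit_bicomponent <- function(curve, bounds = NULL,
                            selection = selection_config(),
                            starts = NULL) {
  stopifnot(inherits(curve, "sir_curve"), inherits(selection, "selection_config"))
  if (length(curve$ti) < 4)
    stop("at least 4 samples are required for a fit")
  if (is.null(bounds)) bounds <- default_bounds(curve, "bicomponent")
  t1_fix <- bounds$t1_app_fixed
  delta_min <- 1  # ms; keeps delta_t_g strictly below delta_t_gamma

  gauss_fit <- fit_single(curve, "gaussian",
                          bounds = default_bounds(curve, "gaussian"))

  comp_eval <- function(p, ti) {
    # p = (f, delta, amplitude, delta_t_g, tau)
    dtg <- p[4]
    dtgam <- min(dtg + p[2], bounds$delta_t_gamma[2])
    eval_gamma_variate(gamma_variate_params(p[1], dtgam, t1_fix), ti) +
      eval_gaussian(gaussian_params(p[3], dtg, p[5]), ti)
  }
  resid <- function(p) curve$sir - comp_eval(p, curve$ti)

  # Variable projection: f and A enter linearly, so for any candidate
  # (delta, delta_t_g, tau) the optimal box-constrained (f, A) pair has an
  # exact solution. The outer optimizer then only has to search the three
  # nonlinear time parameters, which conditions the kinked problem far
  # better than the joint 5-parameter search.
  inner_coef <- function(q) {
    # q = (delta, delta_t_g, tau)
    dtgam <- min(q[2] + q[1], bounds$delta_t_gamma[2])
    x1 <- eval_gamma_variate(gamma_variate_params(1, dtgam, t1_fix), curve$ti)
    x2 <- eval_gaussian(gaussian_params(1, q[2], q[3]), curve$ti)
    ls_box2(curve$sir, x1, x2, bounds$f[2], bounds$amplitude[2])
  }
  resid3 <- function(q) {
    cc <- inner_coef(q)
    resid(c(cc[1], q[1], cc[2], q[2], q[3]))
  }

  if (is.null(starts)) {
    span <- diff(range(curve$ti))
    smax <- bounds$sir_max
    dt0 <- unique(pmin(pmax(min(curve$ti) + c(0, 0.25, 0.5) * span, 0),
                       bounds$delta_t_g[2]))
    taus <- logspace3(max(span / 40, 10), min(bounds$tau[2], span))
    deltas <- c(200, 800)
    f0 <- min(0.4 * smax * exp(1) / t1_fix, bounds$f[2])
    a0 <- min(smax / (1 - exp(-2)), bounds$amplitude[2])
    g <- expand.grid(dtg = dt0, tau = taus, delta = deltas)
    # data-driven start from the observed peak geometry
    pk <- observed_peak(curve)
    tau_pk <- max(pk$hw / (2 * sqrt(2 * log(2 / (1 + exp(-2))))), 10)
    tau_pk <- min(tau_pk, bounds$tau[2])
    g <- rbind(g, data.frame(
      dtg = min(max(pk$ttp - 2 * tau_pk, 0), bounds$delta_t_g[2]),
      tau = tau_pk, delta = deltas))
    starts <- lapply(seq_len(nrow(g)), function(i)
      c(f = f0, delta = g$delta[i], amplitude = a0,
        dtg = g$dtg[i], tau = g$tau[i]))
    # warm start at the Gaussian-only solution (f = 0) so the composite
    # can never end up worse than the nested model
    gp <- gauss_fit$params
    starts <- c(starts, list(c(f = 0, delta = 500, amplitude = gp$amplitude,
                               dtg = gp$delta_t, tau = gp$tau)))
  }

  lower <- c(bounds$f[1], delta_min, bounds$amplitude[1],
             bounds$delta_t_g[1], bounds$tau[1])
  upper <- c(bounds$f[2], bounds$delta_t_gamma[2], bounds$amplitude[2],
             bounds$delta_t_g[2], bounds$tau[2])

  # outer search over (delta, delta_t_g, tau); inner exact (f, A)
  starts3 <- lapply(starts, function(p) p[c(2, 4, 5)])
  best3 <- run_multistart(starts3, lower[c(2, 4, 5)], upper[c(2, 4, 5)],
                          resid3)
  if (is.null(best3))
    stop(sprintf("no start converged for model 'bicomponent' on curve '%s'",
                 curve$label %||% "<unnamed>"))
  cc <- inner_coef(best3$par)
  p5 <- c(cc[1], best3$par[1], cc[2], best3$par[2], best3$par[3])
  best <- list(par = p5, sse = sum(resid(p5)^2),
               n_starts_used = best3$n_starts_used)

  # final joint refinement of all five parameters; keep only if it improves
  joint <- tryCatch(minpack.lm::nls.lm(
    par = best$par, lower = lower, upper = upper, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(joint) && sum(joint$fvec^2) < best$sse) {
    best$par <- joint$par
    best$sse <- sum(joint$fvec^2)
  }

  n <- length(curve$ti)
  sse_c <- best$sse
  sse_g <- gauss_fit$gof$sse
  aicc_c <- aicc_from_sse(sse_c, n, 5L)
  aicc_g <- aicc_from_sse(sse_g, n, 3L)
  rel_red <- if (sse_g > 0) (sse_g - sse_c) / sse_g else 0
  retain <- rel_red >= selection$rel_sse_min &&
    (!selection$use_aicc || aicc_c < aicc_g)

  sel <- list(gamma_suppressed = !retain,
              sse_composite = sse_c, sse_gaussian_only = sse_g,
              aicc_composite = aicc_c, aicc_gaussian_only = aicc_g,
              rel_sse_reduction = rel_red,
              rel_sse_min = selection$rel_sse_min,
              use_aicc = selection$use_aicc)

  if (retain) {
    p <- best$par
    dtg <- p[4]
    dtgam <- min(dtg + p[2], bounds$delta_t_gamma[2])
    params <- bicomponent_params(
      gamma = gamma_variate_params(p[1], dtgam, t1_fix),
      gaussian = gaussian_params(p[3], dtg, p[5]),
      gamma_suppressed = FALSE)
    n_starts <- best$n_starts_used + gauss_fit$n_starts_used
  } else {
    gp <- gauss_fit$params
    params <- bicomponent_params(
      gamma = gamma_variate_params(0, gp$delta_t + delta_min, t1_fix),
      gaussian = gp, gamma_suppressed = TRUE)
    n_starts <- best$n_starts_used + gauss_fit$n_starts_used
  }
  make_fit_result("bicomponent", params, curve, n_starts, selection = sel,
                  degenerate = isTRUE(bounds$degenerate))
}

#' Fit all three models to an SIR curve
#'
#' Convenience wrapper returning the gamma-variate-only, Gaussian-only,
#' and bi-component fits of the same curve.
#'
#' @param curve An `sir_curve` object.
#' @param selection A [selection_config()] for the bi-component fit.
#' @return A named list of `sir_fit` objects
#'   (`gamma`, `gaussian`, `bicomponent`) of class `sir_fit_set`.
#' @export
fit_all <- function(curve, selection = selection_config()) {
  out <- list(gamma = fit_single(curve, "gamma"),
              gaussian = fit_single(curve, "gaussian"),
              bicomponent = fit_bicomponent(curve, selection = selection))
  class(out) <- "sir_fit_set"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sir_fit <- function(x, ...) {
  cat(sprintf("%s fit%s\n", x$model,
              if (!is.null(x$curve_label)) paste0(" of '", x$curve_label, "'") else ""))
  p <- unlist(flatten_params(x))
  cat("  params:", paste(sprintf("%s=%.4g", names(p), p), collapse = ", "), "\n")
  if (x$model == "bicomponent")
    cat("  gamma term:", if (x$params$gamma_suppressed) "suppressed" else "retained", "\n")
  cat("  "); print(x$gof)
  cat("  "); print(x$descriptors)
  invisible(x)
}

flatten_params <- function(fit) {
  p <- fit$params
  switch(fit$model,
         gamma = list(f = p$f, delta_t_gamma = p$delta_t, t1_app = p$t1_app),
         gaussian = list(amplitude = p$amplitude, delta_t_g = p$delta_t,
                         tau = p$tau),
         bicomponent = list(f = p$gamma$f, delta_t_gamma = p$gamma$delta_t,
                            t1_app = p$gamma$t1_app,
                            amplitude = p$gaussian$amplitude,
                            delta_t_g = p$gaussian$delta_t,
                            tau = p$gaussian$tau,
                            gamma_suppressed = p$gamma_suppressed))
}

#' Flatten fit results to a table
#'
#' One row per fit with the descriptor and goodness-of-fit columns (TTP,
#' FWHM, PH, AUC, R2, SSE, RMSE; PH in %, AUC in %.s) plus the fitted
#' parameters.
#'
#' @param fits An `sir_fit`, an `sir_fit_set`, or a list of either.
#' @return A data.frame, one row per curve/model pair.
#' @export
fit_results_table <- function(fits) {
  if (inherits(fits, "sir_fit")) fits <- list(fits)
  if (inherits(fits, "sir_fit_set")) fits <- unclass(fits)
  fits <- unlist(lapply(fits, function(f)
    if (inherits(f, "sir_fit_set")) unclass(f) else list(f)), recursive = FALSE)
  rows <- lapply(fits, function(f) {
    d <- curve_descriptors(f$model, f$params, as_percent = TRUE)
    p <- flatten_params(f)
    base <- data.frame(
      curve = f$curve_label %||% NA_character_, model = f$model,
      TTP = d$ttp, FWHM = d$fwhm, PH = d$peak_height, AUC = d$auc,
      R2 = f$gof$r2, SSE = f$gof$sse, RMSE = f$gof$rmse,
      n_starts = f$n_starts_used, stringsAsFactors = FALSE)
    for (nm in names(p)) base[[nm]] <- p[[nm]]
    base
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}
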