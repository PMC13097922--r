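test_that("noise-free single-component curves are recovered to high precision", {
  # Gaussian truth at the 9 sparse in-vivo TIs. The recovery oracle needs
  # bounds that contain the truth: the default amplitude box caps A at the
  # observed max SIR, which for a pure Gaussian is (1 - e^-2) * A < A.
  tr <- gaussian_params(0.6, 400, 300)
  ti <- ti_grid("invivo")
  crv <- sir_curve(ti, eval_gaussian(tr, ti))
  b <- default_bounds(crv, "gaussian")
  b$amplitude <- c(0, 1)
  f <- fit_single(crv, "gaussian", bounds = b)
  expect_equal(f$params$amplitude, 0.6, tolerance = 1e-3)
  expect_equal(f$params$delta_t, 400, tolerance = 1e-3)
  expect_equal(f$params$tau, 300, tolerance = 1e-3)
  expect_lt(f$gof$sse, 1e-12)

  # gamma truth on a 100 ms grid, default bounds contain it
  tg <- gamma_variate_params(5e-4, 300, 900)
  grid <- seq(0, 4000, by = 100)
  fg <- fit_single(sir_curve(grid, eval_gamma_variate(tg, grid)), "gamma")
  expect_equal(fg$params$f, 5e-4, tolerance = 1e-3)
  expect_equal(fg$params$delta_t, 300, tolerance = 1e-3)
  expect_equal(fg$params$t1_app, 900, tolerance = 1e-3)
})

test_that("noise-free bi-component curves are recovered to high precision", {
  tr <- truth_defaults("invivo")
  ti <- ti_grid("invivo")
  crv <- sir_curve(ti, eval_bicomponent(tr, ti))
  fb <- fit_bicomponent(crv)
  expect_false(fb$params$gamma_suppressed)
  expect_equal(fb$params$gaussian$amplitude, tr$gaussian$amplitude,
               tolerance = 1e-3)
  expect_equal(fb$params$gaussian$delta_t, tr$gaussian$delta_t,
               tolerance = 1e-3)
  expect_equal(fb$params$gaussian$tau, tr$gaussian$tau, tolerance = 1e-3)
  expect_equal(fb$params$gamma$f, tr$gamma$f, tolerance = 1e-3)
  expect_equal(fb$params$gamma$delta_t, tr$gamma$delta_t, tolerance = 1e-3)
  expect_equal(fb$params$gamma$t1_app, 2000)  # fixed, not fitted
})

test_that("fitted parameters respect their bounds and the arrival ordering", {
  for (s in 1:10) {
    sim <- make_invivo_sim(seed = s, sigma = 0.05)
    b <- default_bounds(sim$curve, "bicomponent")
    fb <- fit_bicomponent(sim$curve)
    p <- fb$params
    expect_gte(p$gaussian$amplitude, b$amplitude[1])
    expect_lte(p$gaussian$amplitude, b$amplitude[2])
    expect_gte(p$gaussian$delta_t, b$delta_t_g[1])
    expect_lte(p$gaussian$delta_t, b$delta_t_g[2])
    expect_gte(p$gaussian$tau, b$tau[1])
    expect_lte(p$gaussian$tau, b$tau[2])
    expect_gte(p$gamma$f, b$f[1])
    expect_lte(p$gamma$f, b$f[2])
    expect_gte(p$gamma$delta_t, b$delta_t_gamma[1])
    expect_lte(p$gamma$delta_t, b$delta_t_gamma[2])
    if (!p$gamma_suppressed)
      expect_lt(p$gaussian$delta_t, p$gamma$delta_t)  # strict ordering
  }
})

test_that("bi-component SSE never exceeds the Gaussian-only SSE (nesting)", {
  # structured curves
  for (s in 1:5) {
    sim <- make_invivo_sim(seed = s, sigma = 0.05)
    fb <- fit_bicomponent(sim$curve)
    fg <- fit_single(sim$curve, "gaussian")
    expect_lte(fb$gof$sse, fg$gof$sse + 1e-12)
  }
  # adversarial random curves
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:14, 1)
    crv <- sir_curve(sort(sample(100:3800, n)), runif(n, -0.1, 0.8))
    fb <- fit_bicomponent(crv)
    fg <- fit_single(crv, "gaussian")
    expect_lte(fb$gof$sse, fg$gof$sse + 1e-12)
  }
})

test_that("fits are deterministic: same curve and config give identical results", {
  sim <- make_invivo_sim(seed = 7, sigma = 0.03)
  f1 <- fit_bicomponent(sim$curve)
  f2 <- fit_bicomponent(sim$curve)
  expect_identical(f1, f2)
  g1 <- fit_single(sim$curve, "gamma")
  g2 <- fit_single(sim$curve, "gamma")
  expect_identical(g1, g2)
})

test_that("degenerate all-zero curves fit to zero amplitude with the flag set", {
  crv <- sir_curve(ti_grid("invivo"), rep(0, 9))
  f <- fit_single(crv, "gaussian")
  expect_true(f$degenerate)
  expect_lt(f$params$amplitude, 1e-10)
  expect_true(f$gof$r2_undefined)
  fb <- fit_bicomponent(crv)
  expect_true(fb$params$gamma_suppressed)
  expect_lt(fb$params$gaussian$amplitude, 1e-10)
})

test_that("curves with fewer than 4 samples are rejected", {
  crv <- sir_curve(c(500, 1000, 1500), c(0.1, 0.3, 0.2))
  expect_error(fit_single(crv, "gaussian"), "4 samples")
  expect_error(fit_bicomponent(crv), "4 samples")
})

test_that("symmetric bolus curves push the unconstrained gamma-variate T1app far below the fluid T1", {
  # the phantom-shape property: Gaussian attains the better fit while the
  # gamma-variate can only mimic the compact symmetric peak by shrinking
  # its apparent relaxation time an order of magnitude below the true
  # fluid T1 (3000 ms here)
  t1_apps <- numeric(5); r2_gauss <- numeric(5); r2_gamma <- numeric(5)
  for (s in 1:5) {
    sim <- make_phantom_sim(seed = s)
    fgam <- fit_single(sim$curve, "gamma")
    fgau <- fit_single(sim$curve, "gaussian")
    t1_apps[s] <- fgam$params$t1_app
    r2_gauss[s] <- fgau$gof$r2
    r2_gamma[s] <- fgam$gof$r2
  }
  expect_lt(median(t1_apps), 3000 / 3)
  expect_true(all(r2_gauss > r2_gamma))
})

test_that("fit_all returns the three models with consistent bookkeeping", {
  sim <- make_invivo_sim(seed = 3)
  fs <- fit_all(sim$curve)
  expect_named(fs, c("gamma", "gaussian", "bicomponent"))
  expect_lte(fs$bicomponent$gof$sse, fs$gaussian$gof$sse + 1e-12)
  tab <- fit_results_table(fs)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("TTP", "FWHM", "PH", "AUC", "R2", "SSE", "RMSE") %in%
                    names(tab)))
  # PH column is in percent: within [0, 100] for these data
  expect_true(all(tab$PH > 0 & tab$PH < 100))
})

test_that("selection record explains the suppression decision", {
  sim <- make_phantom_sim(seed = 2)
  fb <- fit_bicomponent(sim$curve)
  sel <- fb$selection
  expect_true(sel$gamma_suppressed)
  expect_true(is.finite(sel$sse_composite))
  expect_true(is.finite(sel$sse_gaussian_only))
  expect_equal(sel$rel_sse_min, 0.10)
  # a stricter rule can only suppress more
  fb2 <- fit_bicomponent(sim$curve,
                         selection = selection_config(rel_sse_min = 0.9))
  expect_true(fb2$params$gamma_suppressed)
})
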