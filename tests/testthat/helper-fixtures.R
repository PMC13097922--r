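# Independent closed-form evaluators used as oracles. Written from the
# formulas directly, NOT via the package's eval_* functions, so tests
# compare two separate routes.
oracle_gamma <- function(ti, f, dt, t1) {
  ifelse(ti > dt, f * (ti - dt) * exp(-(ti - dt) / t1), 0)
}
oracle_gauss <- function(ti, A, dt, tau) {
  u <- ti - dt
  ifelse(u >= 0 & u <= 4 * tau,
         A * (exp(-(u - 2 * tau)^2 / (2 * tau^2)) - exp(-2)), 0)
}

# default ground truths used across fitting tests
invivo_truth <- function() truth_defaults("invivo")
phantom_truth <- function() truth_defaults("phantom")

make_invivo_sim <- function(seed, sigma = 0.02) {
  simulate_curve("bicomponent", invivo_truth(), ti_grid("invivo"),
                 noise_sigma = sigma, seed = seed)
}
make_phantom_sim <- function(seed, sigma = 0.02) {
  simulate_curve("gaussian", phantom_truth(), ti_grid("phantom"),
                 noise_sigma = sigma, seed = seed)
}

# tiny synthetic tag/control series: 8x8 grid, uniform background per TI,
# with a bright square in the tag images
tiny_series <- function(ti = c(500, 1500, 3000), bright = 2) {
  mk <- function(v) matrix(v, 8, 8)
  control <- lapply(seq_along(ti), function(k) mk(100 + 10 * k))
  tag <- lapply(seq_along(ti), function(k) {
    m <- mk(100 + 10 * k); m[3:5, 3:5] <- m[3:5, 3:5] * bright; m
  })
  image_series(ti, tag, control, m0 = "derived")
}
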