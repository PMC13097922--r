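#' Preset inversion-time grids
#'
#' Two acquisition layouts: the in-vivo protocol samples 9 inversion
#' times between 500 and 3000 ms, densest around the expected bolus peak;
#' the phantom protocol samples 31 TIs from 1119 to 4119 ms in 100 ms
#' steps.
#'
#' @param preset `"invivo"` or `"phantom"`.
#' @return Numeric vector of inversion times in ms.
#' @export
#' @examples
#' ti_grid("invivo")
ti_grid <- function(preset = c("invivo", "phantom")) {
  preset <- match.arg(preset)
  switch(preset,
         invivo = c(500, 750, 1000, 1150, 1250, 1350, 1500, 2000, 3000),
         phantom = seq(1119, 4119, by = 100))
}

#' Default ground-truth parameters for the presets
#'
#' The in-vivo preset is a bi-component truth producing a composite curve
#' with time-to-peak near 1250 ms and peak height near 0.65 (the scale of
#' curves measured over the superior sagittal sinus region): a Gaussian
#' bulk bolus arriving at 500 ms with 300 ms spread, plus a slow
#' gamma-variate tail with apparent T1 2000 ms. The phantom preset is a
#' pure bulk bolus (no perfusion-like term) centered mid-acquisition, as
#' produced by an oscillating pump pushing a tagged slab through the ROI.
#'
#' @param preset `"invivo"` or `"phantom"`.
#' @return A parameter object: [bicomponent_params()] for `"invivo"`,
#'   [gaussian_params()] for `"phantom"`.
#' @export
truth_defaults <- function(preset = c("invivo", "phantom")) {
  preset <- match.arg(preset)
  if (preset == "invivo") {
    bicomponent_params(
      gamma = gamma_variate_params(f = 3.4e-4, delta_t = 700, t1_app = 2000),
      gaussian = gaussian_params(amplitude = 0.60, delta_t = 500, tau = 300))
  } else {
    gaussian_params(amplitude = 0.50, delta_t = 1400, tau = 300)
  }
}

#' Longitudinal recovery fraction after saturation or inversion
#'
#' Fraction of equilibrium longitudinal magnetization recovered a time
#' `ti` after the preparation pulse: `1 - exp(-ti/t1)` for saturation,
#' `1 - 2*exp(-ti/t1)` for inversion. For CSF-like T1 of 3000 ms at 3T,
#' waiting 5-7 s after inversion-like preparation recovers roughly
#' 80-90% of the signal, which justifies approximating M0 by the control
#' image at the longest acquired TI.
#'
#' @param t1 Longitudinal relaxation time, ms.
#' @param ti Recovery delay, ms (>= 0).
#' @param mode `"saturation"` or `"inversion"`.
#' @return Recovery fraction in `[-1, 1]`.
#' @export
#' @examples
#' recovery_fraction(3000, 5000)  # 0.811
recovery_fraction <- function(t1, ti, mode = c("saturation", "inversion")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t1), t1 > 0, is.numeric(ti), ti >= 0)
  e <- exp(-ti / t1)
  if (mode == "saturation") 1 - e else 1 - 2 * e
}

#' Ideal T2-preparation signal retention
#'
#' An ideal T2-preparation module stores magnetization after a transverse
#' evolution time `te`, attenuating species by `exp(-te/t2)`. Long-T2
#' fluids (CSF-like water, T2 >= 1.5 s) retain > 90% at TE = 70 ms,
#' whereas short-T2 venous-like species (T2 of a few tens of ms) lose
#' ~75-80%, which is the basis for separating CSF from venous blood
#' signal.
#'
#' @param te Preparation echo time, ms (> 0).
#' @param t2 Transverse relaxation time, ms (> 0).
#' @return List with `retention = exp(-te/t2)` and
#'   `attenuation = 1 - retention`.
#' @export
#' @examples
#' t2prep_retention(te = 70, t2 = 1500)$retention  # 0.954
t2prep_retention <- function(te, t2) {
  stopifnot(is.numeric(te), te > 0, is.numeric(t2), t2 > 0)
  r <- exp(-te / t2)
  list(retention = r, attenuation = 1 - r)
}

#' Simulate a noisy SIR curve with known ground truth
#'
#' Evaluates a model on a TI grid and adds zero-mean Gaussian noise.
#' Negative noisy samples are kept: subtraction data scatter around the
#' noise-free curve, and only the models are non-negative by
#' construction. Deterministic for a given seed.
#'
#' @param model Model id (`"gamma"`, `"gaussian"`, `"bicomponent"`).
#' @param params The matching parameter object (the ground truth).
#' @param ti TI grid in ms (e.g. [ti_grid()]).
#' @param noise_sigma Standard deviation of the additive Gaussian noise
#'   on SIR (dimensionless, >= 0).
#' @param seed Integer RNG seed.
#' @param label Optional curve label.
#' @return A list of class `synthetic_curve` with fields `curve`
#'   (an [sir_curve()]) and `truth` (model id, params, grid,
#'   `noise_sigma`, `seed`).
#' @export
#' @examples
#' s <- simulate_curve("bicomponent", truth_defaults("invivo"),
#'                     ti_grid("invivo"), noise_sigma = 0.02, seed = 1)
#' s$curve
simulate_curve <- function(model, params, ti, noise_sigma = 0, seed = 1,
                           label = NULL) {
  stopifnot(is.numeric(noise_sigma), noise_sigma >= 0)
  y <- eval_model(model, params, ti)
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(ti), 0, noise_sigma)
  }
  structure(list(
    curve = sir_curve(ti, y, label = label),
    truth = list(model = model, params = params, ti = ti,
                 noise_sigma = noise_sigma, seed = as.integer(seed))),
    class = "synthetic_curve")
}

#' Simulate a phantom Time-SLIP image series
#'
#' Renders a miniature version of the flow-phantom experiment: a tagged
#' slab of fluid (default 20 mm) translating along a straight channel at
#' constant velocity, imaged at each TI as paired Tag and Control
#' images. The background follows inversion-recovery toward equilibrium
#' (see [recovery_fraction()]); the tagged band appears bright in the Tag
#' image only. The control image at the longest TI serves as the M0
#' reference. Gaussian edge blur can soften the slab profile; optional
#' Rician magnitude noise is available.
#'
#' @param ti TI grid in ms (default the phantom preset).
#' @param fov_mm Field of view along the channel, mm (default 120).
#' @param res_mm Pixel size, mm (default 1): the image is
#'   `n_rows x (fov_mm/res_mm)`.
#' @param n_rows Image rows; the channel occupies the middle
#'   `channel_rows` rows (defaults 40 and 20).
#' @param channel_rows Rows spanned by the fluid channel.
#' @param slab_mm Tag slab thickness along the channel, mm (default 20).
#' @param slab_start_mm Position of the leading edge of the slab at
#'   TI = 0, mm from the left edge (default 10).
#' @param velocity_mm_s Bulk flow velocity, mm/s (default 20).
#' @param roi_center_mm ROI center along the channel, mm (default 60).
#' @param roi_width_mm,roi_height_mm ROI extent, mm (defaults 15 x 10).
#' @param t1_fluid Fluid longitudinal relaxation time, ms (default 3000,
#'   distilled-water-like at 3T).
#' @param edge_blur_mm Gaussian blur of the slab edges, mm (default 2).
#' @param noise_sigma Noise sd relative to M0 (default 0); applied as
#'   Rician magnitude noise when `rician = TRUE`, otherwise additive
#'   Gaussian.
#' @param rician Use magnitude-domain Rician noise (default FALSE).
#' @param seed Integer RNG seed.
#' @return A list of class `phantom_series` with `series` (an
#'   `image_series` usable by [compute_sir_series()]), `roi_mask`, and
#'   `truth` (geometry, velocity and the ground-truth transit time of the
#'   slab center through the ROI center).
#' @export
simulate_phantom_series <- function(ti = ti_grid("phantom"),
                                    fov_mm = 120, res_mm = 1,
                                    n_rows = 40, channel_rows = 20,
                                    slab_mm = 20, slab_start_mm = 10,
                                    velocity_mm_s = 20,
                                    roi_center_mm = 60,
                                    roi_width_mm = 15, roi_height_mm = 10,
                                    t1_fluid = 3000, edge_blur_mm = 2,
                                    noise_sigma = 0, rician = FALSE,
                                    seed = 1) {
  ncol <- round(fov_mm / res_mm)
  x_mm <- (seq_len(ncol) - 0.5) * res_mm
  ch_rows <- seq(floor((n_rows - channel_rows) / 2) + 1L,
                 length.out = channel_rows)
  roi_cols <- which(abs(x_mm - roi_center_mm) <= roi_width_mm / 2)
  roi_rows_n <- round(roi_height_mm / res_mm)
  roi_rows <- seq(floor((n_rows - roi_rows_n) / 2) + 1L, length.out = roi_rows_n)
  if (length(roi_cols) == 0 || !all(roi_rows %in% ch_rows))
    stop("ROI must lie inside the channel")

  m0_val <- 1000  # arbitrary equilibrium intensity
  # soft slab indicator along the channel at a given TI
  slab_profile <- function(t_ms) {
    lead <- slab_start_mm + velocity_mm_s * t_ms / 1000
    trail <- lead - slab_mm
    if (edge_blur_mm > 0) {
      stats::pnorm(x_mm, trail, edge_blur_mm) *
        (1 - stats::pnorm(x_mm, lead, edge_blur_mm))
    } else {
      as.numeric(x_mm > trail & x_mm <= lead)
    }
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  add_noise <- function(img) {
    if (noise_sigma <= 0) return(img)
    s <- noise_sigma * m0_val
    if (rician) {
      sqrt((img + stats::rnorm(length(img), 0, s))^2 +
             stats::rnorm(length(img), 0, s)^2)
    } else {
      img + stats::rnorm(length(img), 0, s)
    }
  }

  tags <- controls <- vector("list", length(ti))
  for (k in seq_along(ti)) {
    # control: everything recovers from inversion (-Mz); tag: fluid inside
    # the (advected) tagged slab was re-inverted back to +Mz and sits at
    # equilibrium. Images are magnitudes of the signed Mz.
    bg_signed <- recovery_fraction(t1_fluid, ti[k], "inversion") * m0_val
    control <- matrix(abs(bg_signed), n_rows, ncol)
    tag_signed <- matrix(bg_signed, n_rows, ncol)
    prof <- slab_profile(ti[k])  # partial-volume blend at slab edges
    tag_signed[ch_rows, ] <-
      matrix(prof * m0_val + (1 - prof) * bg_signed,
             length(ch_rows), ncol, byrow = TRUE)
    tags[[k]] <- add_noise(abs(tag_signed))
    controls[[k]] <- add_noise(control)
  }

  series <- image_series(ti, tags, controls, m0 = "derived")
  mask <- matrix(FALSE, n_rows, ncol)
  mask[roi_rows, roi_cols] <- TRUE

  # ground truth: TI at which the slab center crosses the ROI center
  transit_ms <- (roi_center_mm - (slab_start_mm - slab_mm / 2)) /
    velocity_mm_s * 1000
  structure(list(series = series, roi_mask = roi_mask(mask, label = "channel"),
                 truth = list(transit_ms = transit_ms,
                              velocity_mm_s = velocity_mm_s,
                              slab_mm = slab_mm, t1_fluid = t1_fluid,
                              noise_sigma = noise_sigma, seed = as.integer(seed))),
            class = "phantom_series")
}
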