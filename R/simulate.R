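#' Equilibrium resonance shift of one sensor element for one sample
#'
#' The shift decomposes into a bulk refractive-index term common to all
#' elements and a chemistry-specific adsorption term with Langmuir
#' saturation per analyte feature:
#' \deqn{\Delta\lambda_{eq} = S_{bulk}\,(n_{sample} - n_{water}) +
#'   \sum_j A_j \frac{c_j}{K_j + c_j}}
#'
#' @param chemistry one row of a [default_chemistries()] table.
#' @param sample a [liquid_sample()].
#' @param model a [response_model()].
#' @return Equilibrium shift in nm (finite scalar).
#' @export
equilibrium_shift <- function(chemistry, sample, model = response_model()) {
  feats <- analyte_features()
  conc <- unclass(sample$composition)[feats]
  aff <- as.numeric(chemistry[paste0("aff_", feats)])
  ks <- as.numeric(chemistry[paste0("k_", feats)])
  bulk <- model$bulk_sensitivity * (sample$refractive_index - RI_WATER_25C)
  occ <- ifelse(conc > 0, conc / (ks + conc), 0)
  shift <- bulk + sum(aff * occ)
  stopifnot(is.finite(shift))
  shift
}

#' Saturating kinetic development of a resonance shift
#'
#' Single-exponential approach to equilibrium (the adsorption
#' "on-curve"): \eqn{\Delta\lambda(t) = \Delta\lambda_{eq}(1 - e^{-kt})}.
#'
#' @param delta_eq equilibrium shift (nm).
#' @param rate rate constant k (s^-1, > 0).
#' @param t time since sample introduction (s, >= 0); vectorised.
#' @return Shift at time `t` (nm).
#' @export
kinetic_shift <- function(delta_eq, rate, t) {
  stopifnot(rate > 0)
  if (any(t < 0)) stop("t must be nonnegative")
  delta_eq * (1 - exp(-rate * t))
}

# Effective on-rate for a (chemistry, sample) pair. Small molecules
# equilibrate at the chemistry's base rate; the macromolecule-bound part
# of the response develops at slow_rate (default 1/180 s^-1, so a
# macromolecule-dominated response stabilises after ~8 min). The two are
# blended harmonically by the macromolecule fraction of the adsorption
# signal, giving a single effective exponential per element.
effective_rate <- function(chemistry, sample, slow_rate = 1 / 180) {
  feats <- analyte_features()
  conc <- unclass(sample$composition)[feats]
  aff <- as.numeric(chemistry[paste0("aff_", feats)])
  ks <- as.numeric(chemistry[paste0("k_", feats)])
  occ <- ifelse(conc > 0, conc / (ks + conc), 0)
  contrib <- aff * occ
  total <- sum(contrib)
  w <- if (total > 0) contrib[feats == "macromolecules"] / total else 0
  1 / ((1 - w) / chemistry$kinetic_rate + w / slow_rate)
}

#' Time-resolved resonance shift of one sensor element
#'
#' Composes the physically distinct parts of the response: the bulk
#' refractive-index term appears as soon as the liquid has exchanged
#' (instantaneous on the 30 s reading grid), while each adsorption
#' contribution develops as its own on-curve — at the chemistry's base
#' rate for small molecules and at `slow_rate` for macromolecules,
#' which diffuse to and rearrange on the surface slowly (a
#' macromolecule-dominated response stabilises after about 8 min).
#'
#' @param chemistry one row of a [default_chemistries()] table.
#' @param sample a [liquid_sample()].
#' @param t time since sample introduction (s).
#' @param model a [response_model()].
#' @param slow_rate macromolecule on-rate (s^-1).
#' @return Shift at time `t` (nm); approaches
#'   [equilibrium_shift()] as `t` grows.
#' @export
shift_at_time <- function(chemistry, sample, t, model = response_model(),
                          slow_rate = 1 / 180) {
  feats <- analyte_features()
  conc <- unclass(sample$composition)[feats]
  aff <- as.numeric(chemistry[paste0("aff_", feats)])
  ks <- as.numeric(chemistry[paste0("k_", feats)])
  occ <- ifelse(conc > 0, conc / (ks + conc), 0)
  rates <- ifelse(feats == "macromolecules", slow_rate,
                  chemistry$kinetic_rate)
  bulk <- model$bulk_sensitivity * (sample$refractive_index - RI_WATER_25C)
  bulk + sum(aff * occ * (1 - exp(-rates * t)))
}

#' Smooth lamp emission profile of the illumination source
#'
#' Broad Gaussian in wavelength emulating a tungsten-halogen white-light
#' source over the instrument's 550-900 nm range.
#'
#' @param wavelengths wavelengths (nm).
#' @param center,width Gaussian centre and sd (nm).
#' @param peak peak intensity (arbitrary counts).
#' @return Intensity at each wavelength.
#' @export
lamp_profile <- function(wavelengths, center = 725, width = 150,
                         peak = 5e4) {
  peak * exp(-0.5 * ((wavelengths - center) / width)^2)
}

#' Lorentzian transmission dip
#'
#' \deqn{T(\lambda) = T_0\left[1 - \frac{d}{1 +
#'   ((\lambda-\lambda_0)/(\Gamma/2))^2}\right]}
#'
#' @param wavelengths wavelengths (nm).
#' @param lambda0 resonance (dip centre) wavelength (nm).
#' @param depth fractional loss d at resonance.
#' @param fwhm full width at half maximum Gamma (nm).
#' @param t0 off-resonance transmission level.
#' @return Transmission at each wavelength.
#' @export
lorentzian_dip <- function(wavelengths, lambda0, depth = 0.5, fwhm = 80,
                           t0 = 1) {
  t0 * (1 - depth / (1 + ((wavelengths - lambda0) / (fwhm / 2))^2))
}

#' Default wavelength calibration of the simulated spectrograph
#'
#' Affine map from detector row to wavelength covering 550-900 nm.
#'
#' @param lambda_min,lambda_max range covered (nm).
#' @param step nm per detector row.
#' @return List with `intercept`, `slope` (nm, nm/row) and `n_rows`.
#' @export
default_calibration <- function(lambda_min = 550, lambda_max = 900,
                                step = 0.1) {
  n_rows <- as.integer(round((lambda_max - lambda_min) / step)) + 1L
  list(intercept = lambda_min, slope = step, n_rows = n_rows)
}

calibration_wavelengths <- function(cal) {
  cal$intercept + cal$slope * (seq_len(cal$n_rows) - 1)
}

#' Render one hyperspectral frame of the chip
#'
#' Each aperture produces a spatially separated column of transmitted
#' light; the vertical (row) axis is wavelength. Sensor columns carry a
#' Lorentzian dip at their per-sensor centre on the lamp profile;
#' reference and edge-blank columns carry the undipped lamp profile.
#' Multiplicative Gaussian intensity noise of the stated relative sd is
#' applied pixelwise; the same seed yields a bit-identical frame.
#'
#' @param layout a [default_layout()].
#' @param dip_centers numeric vector of 24 dip-centre wavelengths (nm),
#'   indexed by sensor id.
#' @param model a [response_model()] (dip shape and noise).
#' @param calibration a [default_calibration()].
#' @param seed integer seed for the pixel noise.
#' @return Object of class `hyperspectral_frame`: list with `intensity`
#'   (rows x columns matrix), `calibration` and `layout`.
#' @export
render_frame <- function(layout, dip_centers, model = response_model(),
                         calibration = default_calibration(), seed = 1L) {
  validate_layout(layout)
  stopifnot(length(dip_centers) == 24L)
  wl <- calibration_wavelengths(calibration)
  if (any(dip_centers < min(wl)) || any(dip_centers > max(wl)))
    stop("dip center outside calibrated wavelength range")
  lamp <- lamp_profile(wl)
  n_cols <- max(layout$column_pixel_map[, 2])
  img <- matrix(0, nrow = length(wl), ncol = n_cols)
  for (a in seq_len(layout$n_apertures)) {
    cols <- layout$column_pixel_map[a, 1]:layout$column_pixel_map[a, 2]
    prof <- if (layout$aperture_roles[a] == "sensor") {
      lamp * lorentzian_dip(wl, dip_centers[layout$sensor_ids[a]],
                            depth = model$dip_depth, fwhm = model$dip_fwhm)
    } else {
      lamp
    }
    img[, cols] <- prof
  }
  if (model$intensity_noise_sd > 0) {
    img <- withr::with_seed(as.integer(seed), {
      img * matrix(stats::rnorm(length(img), 1, model$intensity_noise_sd),
                   nrow = nrow(img))
    })
    img[img < 0] <- 0
  }
  structure(list(intensity = img, calibration = calibration,
                 layout = layout),
            class = "hyperspectral_frame")
}

#' @export
print.hyperspectral_frame <- function(x, ...) {
  cat(sprintf("<hyperspectral_frame> %d rows x %d cols, %.1f-%.1f nm (%.3g nm/row)\n",
              nrow(x$intensity), ncol(x$intensity), x$calibration$intercept,
              x$calibration$intercept +
                x$calibration$slope * (nrow(x$intensity) - 1),
              x$calibration$slope))
  invisible(x)
}

#' Simulate a single noisy transmission spectrum
#'
#' Shortcut past frame rendering: the analytic Lorentzian transmission
#' with multiplicative intensity noise, on the instrument's uniform
#' 0.1 nm grid. Equivalent to rendering a one-sensor frame and
#' normalising against a noisy reference (both sensor and reference
#' noise realisations are applied to the ratio).
#'
#' @param lambda0 dip centre (nm).
#' @param model a [response_model()].
#' @param calibration a [default_calibration()].
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A `transmission_spectrum` (see [to_transmission()]).
#' @export
simulate_spectrum <- function(lambda0, model = response_model(),
                              calibration = default_calibration(),
                              seed = NULL) {
  wl <- calibration_wavelengths(calibration)
  tr <- lorentzian_dip(wl, lambda0, depth = model$dip_depth,
                       fwhm = model$dip_fwhm)
  draw <- function() {
    if (model$intensity_noise_sd > 0) {
      # sensor and reference columns are both noisy; the ratio carries
      # the quotient of two independent multiplicative factors
      num <- stats::rnorm(length(wl), 1, model$intensity_noise_sd)
      den <- stats::rnorm(length(wl), 1, model$intensity_noise_sd)
      den[abs(den) < 0.5] <- 0.5   # guard against pathological draws
      tr * num / den
    } else tr
  }
  tr <- if (is.null(seed)) draw() else
    withr::with_seed(as.integer(seed), draw())
  new_transmission_spectrum(wl, pmax(tr, .Machine$double.eps),
                            sensor_id = 1L, time_s = 0)
}
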