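#' Construct a transmission spectrum
#'
#' @param wavelengths strictly ascending uniform grid (nm).
#' @param transmission positive finite transmission ratio per wavelength.
#' @param sensor_id sensor element index, 1-24.
#' @param time_s seconds since sample introduction.
#' @return Object of class `transmission_spectrum`.
#' @export
new_transmission_spectrum <- function(wavelengths, transmission,
                                      sensor_id = 1L, time_s = 0) {
  stopifnot(length(wavelengths) == length(transmission),
            all(diff(wavelengths) > 0))
  dw <- diff(wavelengths)
  if (diff(range(dw)) > 1e-9)
    stop("wavelength grid must be uniform to within 1e-9 nm")
  if (!all(is.finite(transmission)) || any(transmission <= 0))
    stop("transmission must be finite and > 0")
  structure(list(wavelengths = wavelengths, transmission = transmission,
                 sensor_id = as.integer(sensor_id), time_s = time_s),
            class = "transmission_spectrum")
}

#' @export
print.transmission_spectrum <- function(x, ...) {
  cat(sprintf("<transmission_spectrum> sensor %d, t = %g s, %d points (%.1f-%.1f nm)\n",
              x$sensor_id, x$time_s, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Pixelwise mean of repeated hyperspectral frames
#'
#' Successive exposures of the same liquid are combined by averaging
#' before sectioning, improving shot-noise statistics.
#'
#' @param frames list of `hyperspectral_frame` objects with identical
#'   shapes and calibrations.
#' @return A single averaged `hyperspectral_frame`.
#' @export
combine_frames <- function(frames) {
  if (length(frames) < 1) stop("need at least one frame")
  ref <- frames[[1]]
  for (f in frames[-1]) {
    if (!identical(dim(f$intensity), dim(ref$intensity)))
      stop("frames have mismatched shapes")
    if (!isTRUE(all.equal(f$calibration, ref$calibration)))
      stop("frames have mismatched calibrations")
  }
  acc <- Reduce(`+`, lapply(frames, `[[`, "intensity"))
  out <- ref
  out$intensity <- acc / length(frames)
  out
}

#' Section a frame into per-aperture intensity profiles
#'
#' Averages the pixel columns belonging to each aperture, yielding one
#' intensity-versus-row profile per aperture in layout order.
#'
#' @param frame a `hyperspectral_frame`.
#' @param layout a `chip_layout`; defaults to the frame's own.
#' @return Matrix (rows x 55): one column profile per aperture.
#' @export
section_frame <- function(frame, layout = frame$layout) {
  validate_layout(layout)
  img <- frame$intensity
  if (max(layout$column_pixel_map) > ncol(img))
    stop("layout column range out of frame bounds")
  profiles <- vapply(seq_len(layout$n_apertures), function(a) {
    cols <- layout$column_pixel_map[a, 1]:layout$column_pixel_map[a, 2]
    rowMeans(img[, cols, drop = FALSE])
  }, numeric(nrow(img)))
  colnames(profiles) <- paste0("aperture_", seq_len(layout$n_apertures))
  profiles
}

#' Normalise a sensor profile against its light reference
#'
#' Transmission is the row-wise ratio of sensor to reference intensity,
#' mapped through the affine wavelength calibration and resampled by
#' cubic interpolation onto a uniform 0.1 nm grid spanning the
#' calibrated range.
#'
#' @param sensor_profile,reference_profile equal-length intensity
#'   profiles (one value per detector row).
#' @param calibration affine row -> nm map (see [default_calibration()]).
#' @param sensor_id,time_s metadata attached to the result.
#' @param floor_fraction reference-validity floor: every reference value
#'   must exceed this fraction of the reference maximum, else the
#'   reference is considered blocked or failed and an error is raised.
#' @param grid_step output grid spacing (nm).
#' @return A `transmission_spectrum` on the uniform grid.
#' @export
to_transmission <- function(sensor_profile, reference_profile, calibration,
                            sensor_id = 1L, time_s = 0,
                            floor_fraction = 0.01, grid_step = 0.1) {
  if (length(sensor_profile) != length(reference_profile))
    stop("profile length mismatch")
  floor <- floor_fraction * max(reference_profile)
  if (any(reference_profile <= floor) || any(!is.finite(reference_profile)))
    stop("reference profile below validity floor (blocked or failed reference)")
  wl_native <- calibration$intercept +
    calibration$slope * (seq_along(sensor_profile) - 1)
  tr_native <- sensor_profile / reference_profile
  grid <- seq(ceiling(min(wl_native) / grid_step) * grid_step,
              floor(max(wl_native) / grid_step) * grid_step,
              by = grid_step)
  tr <- stats::spline(wl_native, tr_native, xout = grid,
                      method = "natural")$y
  new_transmission_spectrum(grid, pmax(tr, .Machine$double.eps),
                            sensor_id = sensor_id, time_s = time_s)
}

#' Extract all 24 sensor transmission spectra from a frame
#'
#' Sections the frame, pairs every sensor with its adjacent light
#' reference (see [pair_references()]) and normalises each pair.
#'
#' @param frame a `hyperspectral_frame`.
#' @param time_s acquisition time attached to each spectrum.
#' @param ... passed to [to_transmission()].
#' @return List of 24 `transmission_spectrum` objects, by sensor id.
#' @export
frame_to_spectra <- function(frame, time_s = 0, ...) {
  layout <- frame$layout
  profiles <- section_frame(frame, layout)
  refs <- pair_references(layout)
  sensors <- order(layout$sensor_ids[layout$aperture_roles == "sensor"])
  sensor_apertures <- which(layout$aperture_roles == "sensor")
  sensor_apertures <- sensor_apertures[sensors]
  lapply(1:24, function(i) {
    to_transmission(profiles[, sensor_apertures[i]], profiles[, refs[i]],
                    frame$calibration, sensor_id = i, time_s = time_s, ...)
  })
}

#' Export spectra to a long-format CSV
#'
#' @param spectra list of `transmission_spectrum` objects.
#' @param file optional output path.
#' @return data.frame with columns sensor_id, time_s, wavelength_nm,
#'   transmission.
#' @export
spectra_table <- function(spectra, file = NULL) {
  out <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(sensor_id = s$sensor_id, time_s = s$time_s,
               wavelength_nm = s$wavelengths, transmission = s$transmission)
  }))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Write a hyperspectral frame as a 16-bit grayscale image + sidecar
#'
#' The frame is stored as an ASCII PGM (P2, maxval 65535) image; the
#' wavelength calibration, intensity scale and per-aperture column
#' ranges go into a sidecar text file `<path>.cal.txt` so that real or
#' simulated frames round-trip losslessly at 16-bit depth.
#'
#' @param frame a `hyperspectral_frame`.
#' @param path output image path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  img <- frame$intensity
  scale <- max(img)
  if (scale <= 0) scale <- 1
  q <- round(img / scale * 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "65535"), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  cal <- frame$calibration
  cm <- frame$layout$column_pixel_map
  side <- c(
    sprintf("intensity_scale %.10g", scale),
    sprintf("wavelength_intercept_nm %.10g", cal$intercept),
    sprintf("wavelength_slope_nm_per_row %.10g", cal$slope),
    sprintf("aperture_columns %s",
            paste(sprintf("%d:%d", cm[, 1], cm[, 2]), collapse = " "))
  )
  writeLines(side, paste0(path, ".cal.txt"))
  invisible(path)
}

#' Read a frame written by [write_frame()]
#'
#' @param path path to the PGM image (the sidecar `<path>.cal.txt` must
#'   sit next to it).
#' @param layout chip layout to attach; defaults to [default_layout()]
#'   with the sidecar's column map substituted in.
#' @return A `hyperspectral_frame`.
#' @export
read_frame <- function(path, layout = default_layout()) {
  lines <- readLines(path)
  if (lines[1] != "P2") stop("not an ASCII PGM (P2) file")
  dims <- scan(text = lines[2], quiet = TRUE)
  maxval <- scan(text = lines[3], quiet = TRUE)
  vals <- scan(text = paste(lines[-(1:3)], collapse = " "), quiet = TRUE)
  img <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  side <- readLines(paste0(path, ".cal.txt"))
  getval <- function(key) {
    ln <- side[startsWith(side, key)]
    sub(paste0(key, " "), "", ln)
  }
  scale <- as.numeric(getval("intensity_scale"))
  cal <- list(intercept = as.numeric(getval("wavelength_intercept_nm")),
              slope = as.numeric(getval("wavelength_slope_nm_per_row")),
              n_rows = dims[2])
  cols <- strsplit(getval("aperture_columns"), " ")[[1]]
  cm <- do.call(rbind, lapply(strsplit(cols, ":"), as.integer))
  colnames(cm) <- c("first", "last")
  layout$column_pixel_map <- cm
  validate_layout(layout)
  structure(list(intensity = img / maxval * scale, calibration = cal,
                 layout = layout),
            class = "hyperspectral_frame")
}
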