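#' Chip layout: aperture geometry and role map
#'
#' The sensor chip carries a single row of 55 slit-shaped apertures
#' (25 x 500 um, 750 um pitch) milled through an opaque metal film.
#' The outer 4 apertures on each side are edge blanks; the inner 47
#' strictly alternate between plasmonic sensor elements (24) and empty
#' light-reference apertures (23), beginning and ending with a sensor.
#'
#' @param slit_width_um,slit_height_um slit dimensions in micrometres.
#' @param pitch_um centre-to-centre aperture spacing in micrometres.
#' @param px_per_aperture width in detector pixels of each aperture's
#'   column footprint.
#' @param px_gap dark pixels between adjacent aperture footprints.
#' @return An object of class `chip_layout`: a list with `n_apertures`,
#'   `aperture_roles` (character vector, `"edge_blank"`, `"sensor"` or
#'   `"reference"`), `sensor_ids` (named integer map aperture -> 1..24),
#'   `pitch_um`, `slit_width_um`, `slit_height_um` and
#'   `column_pixel_map` (two-column matrix of first/last detector column
#'   per aperture).
#' @examples
#' lay <- default_layout()
#' table(lay$aperture_roles)
#' @export
default_layout <- function(slit_width_um = 25, slit_height_um = 500,
                           pitch_um = 750, px_per_aperture = 6L,
                           px_gap = 4L) {
  n <- 55L
  roles <- rep("edge_blank", n)
  inner <- 5:51
  # alternation starts and ends with a sensor
  roles[inner] <- ifelse(seq_along(inner) %% 2L == 1L, "sensor", "reference")
  sensor_apertures <- which(roles == "sensor")
  sensor_ids <- integer(n)
  sensor_ids[sensor_apertures] <- seq_along(sensor_apertures)

  step <- px_per_aperture + px_gap
  first <- (seq_len(n) - 1L) * step + 1L
  col_map <- cbind(first = first, last = first + px_per_aperture - 1L)

  layout <- structure(
    list(
      n_apertures     = n,
      aperture_roles  = roles,
      sensor_ids      = sensor_ids,
      pitch_um        = pitch_um,
      slit_width_um   = slit_width_um,
      slit_height_um  = slit_height_um,
      column_pixel_map = col_map
    ),
    class = "chip_layout"
  )
  validate_layout(layout)
  layout
}

#' Validate a chip layout against its structural invariants
#'
#' @param layout a `chip_layout` object.
#' @return `layout`, invisibly; errors if any invariant fails.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  roles <- layout$aperture_roles
  if (layout$n_apertures != 55L || length(roles) != 55L)
    stop("layout must have exactly 55 apertures")
  if (!all(roles[c(1:4, 52:55)] == "edge_blank"))
    stop("first and last 4 apertures must be edge blanks")
  inner <- roles[5:51]
  if (any(inner == "edge_blank"))
    stop("inner apertures may not be edge blanks")
  expected <- ifelse(seq_along(inner) %% 2L == 1L, "sensor", "reference")
  if (!identical(inner, expected))
    stop("inner 47 apertures must alternate sensor/reference, ",
         "starting and ending with a sensor")
  if (sum(roles == "sensor") != 24L || sum(roles == "reference") != 23L)
    stop("layout must contain 24 sensors and 23 references")
  ids <- layout$sensor_ids[roles == "sensor"]
  if (!setequal(ids, 1:24) || anyDuplicated(ids))
    stop("sensor_ids must be a bijection onto 1..24")
  cm <- layout$column_pixel_map
  if (nrow(cm) != 55L || any(cm[, 2] < cm[, 1]))
    stop("column_pixel_map must give a nonempty column range per aperture")
  invisible(layout)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat("<chip_layout> 55 apertures:",
      sum(x$aperture_roles == "sensor"), "sensors,",
      sum(x$aperture_roles == "reference"), "references,",
      sum(x$aperture_roles == "edge_blank"), "edge blanks\n")
  cat("  pitch", x$pitch_um, "um; slit", x$slit_width_um, "x",
      x$slit_height_um, "um\n")
  invisible(x)
}

#' Pair each sensor aperture with its light-reference aperture
#'
#' Each sensor is normalised against an adjacent empty aperture. The
#' rule used is: the reference immediately following the sensor in
#' aperture order; the last sensor (which has no following reference)
#' uses the reference immediately preceding it. The pairing is total
#' over the 24 sensors and deterministic.
#'
#' @param layout a `chip_layout`.
#' @return Integer vector of length 24: for sensor id `i`,
#'   `pair_references(layout)[i]` is the aperture index of its reference.
#' @export
pair_references <- function(layout) {
  validate_layout(layout)
  roles <- layout$aperture_roles
  sensors <- which(roles == "sensor")
  ref <- integer(length(sensors))
  for (k in seq_along(sensors)) {
    a <- sensors[k]
    if (a + 1L <= layout$n_apertures && roles[a + 1L] == "reference") {
      ref[k] <- a + 1L
    } else if (roles[a - 1L] == "reference") {
      ref[k] <- a - 1L
    } else {
      stop("sensor aperture ", a, " has no adjacent reference")
    }
  }
  ref[order(layout$sensor_ids[sensors])]
}
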