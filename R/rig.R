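#' Define a camera rig
#'
#' A camera rig is the frame of reference for all positioning: a fixed camera
#' overlooking a harbour channel, with the waterline of the opposite wharf
#' serving as an artificial horizon. Bearings are obtained by interpolating
#' between surveyed landmarks visible in the image; the vertical pixel scale
#' comes either from stored lens metadata (still camera) or from the known
#' heights of lights on the opposite wharf (video camera).
#'
#' @param camera_id Identifier for the camera.
#' @param lat,lon Geographic position of the camera (decimal degrees).
#' @param height_above_datum Lens height above the tidal datum (m, > 0). The
#'   tide series supplied to positioning functions must use the same datum.
#' @param image_width,image_height Image dimensions in pixels.
#' @param horizon_row Pixel row at which a horizontal ray from the lens would
#'   appear (the zero-depression reference row). May lie outside the image.
#' @param landmarks data.frame with columns \code{name}, \code{bearing_true}
#'   (degrees, in [0, 360)), \code{pixel_col}; optionally
#'   \code{pixel_row_top}, \code{pixel_row_base}, \code{physical_height} (m)
#'   for height-calibrated landmarks such as wharf flood lights. At least two
#'   landmarks with distinct pixel columns are required and bearings must be
#'   strictly monotone in pixel column.
#' @param wharf_profile data.frame with columns \code{bearing_deg},
#'   \code{distance_m}: horizontal distance from the camera to the opposite
#'   wharf waterline, linearly interpolated in bearing. All distances > 0.
#' @param focal_length Lens focal length in mm (still camera), or \code{NULL}.
#' @param pixel_pitch Sensor pixel pitch in mm/pixel, paired with
#'   \code{focal_length}, or \code{NULL}.
#' @param heading_reference Nominal true bearing of the optical axis
#'   (informational).
#'
#' @return An object of class \code{camera_rig}.
#' @examples
#' rig <- camera_rig(
#'   camera_id = "video", lat = -32.04, lon = 115.75,
#'   height_above_datum = 5, image_width = 1440, image_height = 1020,
#'   horizon_row = 300,
#'   landmarks = data.frame(
#'     name = c("lightA", "crane", "lightB"),
#'     bearing_true = c(250, 280, 310),
#'     pixel_col = c(100, 720, 1340),
#'     pixel_row_top = c(250, NA, 250),
#'     pixel_row_base = c(380, NA, 390),
#'     physical_height = c(18, NA, 18)),
#'   wharf_profile = data.frame(bearing_deg = c(245, 315),
#'                              distance_m = c(150, 420)))
#' rig
#' @export
camera_rig <- function(camera_id, lat, lon, height_above_datum,
                       image_width, image_height, horizon_row,
                       landmarks, wharf_profile,
                       focal_length = NULL, pixel_pitch = NULL,
                       heading_reference = NULL) {
  if (!is.numeric(height_above_datum) || height_above_datum <= 0)
    stop_config("height_above_datum must be > 0")
  if (image_width <= 0 || image_height <= 0)
    stop_config("pixel dimensions must be positive")
  need <- c("name", "bearing_true", "pixel_col")
  if (!is.data.frame(landmarks) || !all(need %in% names(landmarks)))
    stop_config("landmarks must be a data.frame with columns ",
                paste(need, collapse = ", "))
  if (nrow(landmarks) < 2)
    stop_config("at least 2 landmarks are required for bearing interpolation")
  if (anyDuplicated(landmarks$pixel_col))
    stop_config("landmark pixel columns must be distinct")
  if (any(landmarks$bearing_true < 0 | landmarks$bearing_true >= 360))
    stop_config("landmark bearings must lie in [0, 360)")
  if (any(landmarks$pixel_col < 0 | landmarks$pixel_col > image_width))
    stop_config("landmark pixel columns must lie within the image width")
  ord <- order(landmarks$pixel_col)
  lmk <- landmarks[ord, , drop = FALSE]
  db <- diff(lmk$bearing_true)
  if (!(all(db > 0) || all(db < 0)))
    stop_config("landmark bearings must be strictly monotone in pixel column")
  for (col in c("pixel_row_top", "pixel_row_base", "physical_height"))
    if (is.null(lmk[[col]])) lmk[[col]] <- NA_real_
  hcal <- !is.na(lmk$physical_height)
  if (any(hcal & (is.na(lmk$pixel_row_top) | is.na(lmk$pixel_row_base))))
    stop_config("height-calibrated landmarks need pixel_row_top and pixel_row_base")
  if (any(hcal & lmk$pixel_row_top >= lmk$pixel_row_base, na.rm = TRUE))
    stop_config("pixel_row_top must be above (smaller than) pixel_row_base")
  if (!is.data.frame(wharf_profile) ||
      !all(c("bearing_deg", "distance_m") %in% names(wharf_profile)) ||
      nrow(wharf_profile) < 2)
    stop_config("wharf_profile needs >= 2 rows of (bearing_deg, distance_m)")
  if (any(wharf_profile$distance_m <= 0))
    stop_config("all wharf_profile distances must be > 0")
  if (xor(is.null(focal_length), is.null(pixel_pitch)))
    stop_config("focal_length and pixel_pitch must be supplied together")

  structure(list(
    camera_id = camera_id, lat = lat, lon = lon,
    height_above_datum = height_above_datum,
    image_width = image_width, image_height = image_height,
    horizon_row = horizon_row,
    landmarks = lmk,
    wharf_profile = wharf_profile[order(wharf_profile$bearing_deg), ,
                                  drop = FALSE],
    focal_length = focal_length, pixel_pitch = pixel_pitch,
    heading_reference = heading_reference
  ), class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  type <- if (is.null(x$focal_length)) "video-style (landmark-height pixel scale)"
          else "still-style (focal-length pixel scale)"
  cat("Camera rig '", x$camera_id, "' (", type, ")\n", sep = "")
  cat(sprintf("  position: %.5f, %.5f; lens %.2f m above tidal datum\n",
              x$lat, x$lon, x$height_above_datum))
  cat(sprintf("  image: %d x %d px; horizon row %.1f\n",
              as.integer(x$image_width), as.integer(x$image_height),
              x$horizon_row))
  cat(sprintf("  %d landmarks spanning bearings %.1f-%.1f deg; wharf %0.f-%0.f m\n",
              nrow(x$landmarks), min(x$landmarks$bearing_true),
              max(x$landmarks$bearing_true),
              min(x$wharf_profile$distance_m), max(x$wharf_profile$distance_m)))
  invisible(x)
}

#' Distance from camera to the opposite wharf waterline at a bearing
#'
#' Linear interpolation of the rig's wharf profile in bearing; clamped at the
#' profile's end bearings.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param bearing_deg True bearing(s), degrees.
#' @return Distance(s) in metres.
#' @export
wharf_distance <- function(rig, bearing_deg) {
  stats::approx(rig$wharf_profile$bearing_deg, rig$wharf_profile$distance_m,
                xout = bearing_deg, rule = 2, ties = "ordered")$y
}

#' Tide-corrected effective camera height
#'
#' The lens height above the instantaneous water surface: lens height above
#' datum minus the gauge water level at the observation time, with the water
#' level linearly interpolated between bracketing gauge readings.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param tide data.frame with columns \code{timestamp} (POSIXct, strictly
#'   increasing) and \code{level_m} (water level above the same tidal datum
#'   as the rig height).
#' @param t POSIXct time(s) of observation.
#' @param extrapolation_tol Maximum time (seconds) by which \code{t} may fall
#'   outside the gauge series; the end reading is used within this tolerance.
#' @return Effective height(s) in metres (> 0).
#' @export
effective_height <- function(rig, tide, t, extrapolation_tol = 1800) {
  if (!all(c("timestamp", "level_m") %in% names(tide)))
    stop_config("tide series needs columns timestamp, level_m")
  tt <- as.numeric(tide$timestamp)
  if (is.unsorted(tt, strictly = TRUE))
    stop_config("tide series must be strictly time-ordered")
  if (any(!is.finite(tide$level_m)))
    stop_config("tide levels must be finite")
  tq <- as.numeric(t)
  if (any(tq < tt[1] - extrapolation_tol | tq > tt[length(tt)] + extrapolation_tol))
    stop_data("observation time outside the tide series span (tolerance ",
              extrapolation_tol, " s)")
  level <- stats::approx(tt, tide$level_m, xout = tq, rule = 2,
                         ties = "ordered")$y
  h <- rig$height_above_datum - level
  if (any(h <= 0))
    stop_data("effective camera height <= 0: water level above the lens")
  h
}
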