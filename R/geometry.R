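#' Interpolate a true bearing from a pixel column
#'
#' Bearings are piecewise-linearly interpolated between the rig's surveyed
#' landmarks (flood lights, buildings) as a function of pixel column, and
#' linearly extrapolated beyond the outermost landmarks. Extrapolated values
#' carry a logical \code{extrapolated} attribute.
#'
#' @param rig A \code{\link{camera_rig}} (>= 2 landmarks).
#' @param pixel_col Pixel column(s), within the image width.
#' @return Bearing(s) in degrees true, normalised to [0, 360), with an
#'   \code{extrapolated} attribute.
#' @export
pixel_to_bearing <- function(rig, pixel_col) {
  if (any(pixel_col < 0 | pixel_col > rig$image_width))
    stop_data("pixel_col outside the image width")
  b <- lin_interp_extrap(rig$landmarks$pixel_col, rig$landmarks$bearing_true,
                         pixel_col)
  ex <- attr(b, "extrapolated")
  out <- norm_bearing(as.numeric(b))
  attr(out, "extrapolated") <- ex
  out
}

#' @rdname pixel_to_bearing
#' @param bearing_deg True bearing(s) in degrees.
#' @export
bearing_to_pixel <- function(rig, bearing_deg) {
  # unwrap bearings relative to the landmark span so that a target just
  # across the 0/360 seam (e.g. 359.9999 for a rig spanning [0, 120]) is
  # treated as a small negative offset, not a 360-degree extrapolation
  mid <- mean(range(rig$landmarks$bearing_true))
  bearing_deg <- bearing_deg - 360 * round((bearing_deg - mid) / 360)
  p <- lin_interp_extrap(rig$landmarks$bearing_true, rig$landmarks$pixel_col,
                         bearing_deg)
  ex <- attr(p, "extrapolated")
  out <- as.numeric(p)
  attr(out, "extrapolated") <- ex
  out
}

#' Convert a pixel offset to an angle using lens metadata (still camera)
#'
#' Pinhole model: angle = atan(offset * pixel_pitch / focal_length). Used for
#' still images, whose files store the focal length.
#'
#' @param rig A \code{\link{camera_rig}} with \code{focal_length} and
#'   \code{pixel_pitch}.
#' @param pixel_offset Signed pixel offset(s) from the reference row/column.
#' @return Signed angle(s) in degrees.
#' @export
pixel_to_degrees_still <- function(rig, pixel_offset) {
  if (is.null(rig$focal_length) || is.null(rig$pixel_pitch))
    stop_config("rig has no focal-length metadata; use the video-style ",
                "landmark-height calibration (pixel_to_degrees_video)")
  rad2deg(atan(pixel_offset * rig$pixel_pitch / rig$focal_length))
}

#' Vertical pixel scale from landmark heights (video camera)
#'
#' Video frames store no focal length, so the degrees-per-pixel scale is
#' calibrated from landmarks of known physical height (the lights on the
#' opposite wharf): the angular span of each landmark as seen from the lens,
#' atan(h/D) + atan((H - h)/D) with lens height h, landmark height H and
#' wharf distance D at the landmark's bearing, divided by its pixel span.
#' With several height-calibrated landmarks the per-landmark scales are
#' averaged. The scale is computed once per rig at the reference (datum)
#' water level.
#'
#' @param rig A \code{\link{camera_rig}} with >= 1 height-calibrated landmark.
#' @return Scale in degrees per pixel.
#' @export
video_pixel_scale <- function(rig) {
  lmk <- rig$landmarks
  hc <- which(!is.na(lmk$physical_height))
  if (length(hc) == 0)
    stop_config("no height-calibrated landmark: cannot derive a video pixel scale")
  h <- rig$height_above_datum
  scales <- vapply(hc, function(i) {
    D <- wharf_distance(rig, lmk$bearing_true[i])
    span <- rad2deg(atan(h / D) + atan((lmk$physical_height[i] - h) / D))
    span / (lmk$pixel_row_base[i] - lmk$pixel_row_top[i])
  }, numeric(1))
  mean(scales)
}

#' @rdname pixel_to_degrees_still
#' @details \code{pixel_to_degrees_video} applies the landmark-height scale
#'   linearly: angle = pixel_offset * scale.
#' @export
pixel_to_degrees_video <- function(rig, pixel_offset) {
  pixel_offset * video_pixel_scale(rig)
}

# camera-appropriate conversions, angle <-> vertical pixel offset
pixels_to_angle <- function(rig, pixel_offset) {
  if (is.null(rig$focal_length)) pixel_to_degrees_video(rig, pixel_offset)
  else pixel_to_degrees_still(rig, pixel_offset)
}

angle_to_pixels <- function(rig, angle_deg) {
  if (is.null(rig$focal_length)) angle_deg / video_pixel_scale(rig)
  else tan(deg2rad(angle_deg)) * rig$focal_length / rig$pixel_pitch
}

#' Depression of the wharf waterline (the artificial horizon)
#'
#' Angle below the horizontal from the lens to the point where the opposite
#' wharf meets the water at a given bearing: atan(h_eff / D).
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param bearing_deg True bearing(s).
#' @param h_eff Effective (tide-corrected) camera height, metres.
#' @return Depression in degrees (> 0).
#' @export
wharf_depression <- function(rig, bearing_deg, h_eff) {
  rad2deg(atan(h_eff / wharf_distance(rig, bearing_deg)))
}

#' Pixel row of the wharf waterline at a column
#'
#' @inheritParams wharf_depression
#' @param pixel_col Pixel column(s).
#' @return Pixel row(s) of the waterline for that column at the given tide.
#' @export
waterline_row <- function(rig, pixel_col, h_eff) {
  b <- pixel_to_bearing(rig, pixel_col)
  rig$horizon_row + angle_to_pixels(rig, wharf_depression(rig, b, h_eff))
}

#' Range from depression angle below the horizontal
#'
#' The artificial-horizon range equation: range = h_eff / tan(depression),
#' where the total depression is the waterline depression at the dolphin's
#' bearing plus the angle measured down from the waterline to the dolphin
#' pixel.
#'
#' @param effective_height Tide-corrected camera height (m).
#' @param depression_deg Total depression below the horizontal (degrees, > 0).
#' @return Range(s) in metres.
#' @export
depression_to_range <- function(effective_height, depression_deg) {
  if (any(depression_deg <= 0))
    stop_data("depression angle <= 0: target at or above the artificial horizon")
  effective_height / tan(deg2rad(depression_deg))
}

# total depression of a pixel: waterline depression + angle below waterline
pixel_depression <- function(rig, pixel_col, pixel_row, h_eff) {
  b <- pixel_to_bearing(rig, pixel_col)
  wd <- wharf_depression(rig, b, h_eff)
  wl <- rig$horizon_row + angle_to_pixels(rig, wd)
  wd + pixels_to_angle(rig, pixel_row - wl)
}

#' Estimate dolphin positions from pixel observations
#'
#' Composes bearing interpolation, tide correction, the camera-appropriate
#' pixel-to-degrees conversion, and the artificial-horizon range equation,
#' then places each surfacing on a local planar east-north frame centred at
#' the camera and converts back to latitude/longitude. Observations that
#' cannot be resolved (at or above the artificial horizon, outside the image,
#' outside the tide series) are returned as flagged skip records, never
#' dropped.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param observations data.frame with columns \code{obs_id},
#'   \code{timestamp} (POSIXct), \code{pixel_col}, \code{pixel_row};
#'   optional \code{transit_event_id}, \code{camera_id}.
#' @param tide Tide series as in \code{\link{effective_height}}.
#' @param extrapolation_tol Passed to \code{\link{effective_height}}.
#' @return data.frame with one row per input observation: \code{obs_id},
#'   \code{timestamp}, \code{transit_event_id}, \code{range_m},
#'   \code{bearing_true}, \code{lat}, \code{lon},
#'   \code{effective_camera_height}, \code{depression_deg},
#'   \code{bearing_extrapolated}, \code{status} ("ok" or a skip reason).
#'   Skipped rows have NA estimates.
#' @export
estimate_position <- function(rig, observations, tide,
                              extrapolation_tol = 1800) {
  obs <- observations
  n <- nrow(obs)
  out <- data.frame(
    obs_id = obs$obs_id,
    timestamp = obs$timestamp,
    transit_event_id = obs$transit_event_id %||% rep(NA, n),
    range_m = NA_real_, bearing_true = NA_real_,
    lat = NA_real_, lon = NA_real_,
    effective_camera_height = NA_real_, depression_deg = NA_real_,
    bearing_extrapolated = NA, status = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (obs$pixel_col[i] < 0 || obs$pixel_col[i] > rig$image_width ||
          obs$pixel_row[i] < 0 || obs$pixel_row[i] > rig$image_height)
        stop_data("pixel coordinates outside image bounds")
      h <- effective_height(rig, tide, obs$timestamp[i], extrapolation_tol)
      b <- pixel_to_bearing(rig, obs$pixel_col[i])
      dep <- pixel_depression(rig, obs$pixel_col[i], obs$pixel_row[i], h)
      r <- depression_to_range(h, dep)
      en <- polar_to_enu(r, as.numeric(b))
      ll <- enu_to_latlon(rig$lat, rig$lon, en$x_east, en$y_north)
      list(range_m = r, bearing_true = as.numeric(b), lat = ll$lat,
           lon = ll$lon, h = h, dep = dep,
           ex = attr(b, "extrapolated")[1], status = "ok")
    }, error = function(e) list(status = paste0("skipped: ", conditionMessage(e))))
    out$status[i] <- res$status
    if (identical(res$status, "ok")) {
      out$range_m[i] <- res$range_m
      out$bearing_true[i] <- res$bearing_true
      out$lat[i] <- res$lat; out$lon[i] <- res$lon
      out$effective_camera_height[i] <- res$h
      out$depression_deg[i] <- res$dep
      out$bearing_extrapolated[i] <- res$ex
    }
  }
  out
}

#' Project a geographic position into pixel coordinates
#'
#' The exact forward model inverted by \code{\link{estimate_position}}; used
#' by the harbour simulator. Positions outside the field of view, beyond the
#' wharf waterline, or projecting outside the image are flagged out-of-view.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param lat,lon Geographic position(s) of the target at the water surface.
#' @param tide Tide series as in \code{\link{effective_height}}.
#' @param t POSIXct time(s).
#' @return data.frame with \code{pixel_col}, \code{pixel_row},
#'   \code{range_m}, \code{bearing_true}, \code{in_view}, \code{reason}.
#' @export
project_forward <- function(rig, lat, lon, tide, t) {
  h <- effective_height(rig, tide, t)
  en <- latlon_to_enu(rig$lat, rig$lon, lat, lon)
  pol <- enu_to_polar(en$x_east, en$y_north)
  r <- pol$range_m; b <- pol$bearing_deg
  n <- length(r)
  h <- rep_len(h, n)
  col <- as.numeric(bearing_to_pixel(rig, b))
  D <- wharf_distance(rig, b)
  dep <- rad2deg(atan(h / r))
  wd <- rad2deg(atan(h / D))
  wlr <- rig$horizon_row + angle_to_pixels(rig, wd)
  row <- wlr + angle_to_pixels(rig, dep - wd)
  reason <- rep(NA_character_, n)
  reason[r >= D] <- "beyond wharf waterline (above artificial horizon)"
  bad_col <- is.na(reason) & (col < 0 | col > rig$image_width)
  reason[bad_col] <- "bearing outside image"
  bad_row <- is.na(reason) & (row < 0 | row > rig$image_height)
  reason[bad_row] <- "row outside image"
  data.frame(pixel_col = col, pixel_row = row, range_m = r, bearing_true = b,
             in_view = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}
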