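# internal helpers: angle units, local planar frame, interpolation

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi
EARTH_RADIUS_M <- 6378137

deg2rad <- function(x) x * DEG2RAD
rad2deg <- function(x) x * RAD2DEG

norm_bearing <- function(b) b %% 360

#' @noRd
#' Local east-north offsets (m) -> geographic coordinates, spherical earth.
#' Valid for sub-kilometre offsets; curvature error is negligible against
#' pixel-level positioning error at these ranges.
enu_to_latlon <- function(lat0, lon0, x_east, y_north) {
  lat <- lat0 + rad2deg(y_north / EARTH_RADIUS_M)
  lon <- lon0 + rad2deg(x_east / (EARTH_RADIUS_M * cos(deg2rad(lat0))))
  list(lat = lat, lon = lon)
}

#' @noRd
latlon_to_enu <- function(lat0, lon0, lat, lon) {
  y <- deg2rad(lat - lat0) * EARTH_RADIUS_M
  x <- deg2rad(lon - lon0) * EARTH_RADIUS_M * cos(deg2rad(lat0))
  list(x_east = x, y_north = y)
}

# range/bearing (true, clockwise from north) -> east-north offsets
polar_to_enu <- function(range_m, bearing_deg) {
  th <- deg2rad(bearing_deg)
  list(x_east = range_m * sin(th), y_north = range_m * cos(th))
}

enu_to_polar <- function(x_east, y_north) {
  list(range_m = sqrt(x_east^2 + y_north^2),
       bearing_deg = norm_bearing(rad2deg(atan2(x_east, y_north))))
}

# linear interpolation with linear extrapolation beyond the end nodes;
# returns values plus a logical 'extrapolated' attribute
lin_interp_extrap <- function(x, y, xout) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) out[lo] <- y[1] + (xout[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  if (any(hi)) out[hi] <- y[n] + (xout[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  attr(out, "extrapolated") <- lo | hi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(errorCondition(paste0(...),
  class = c("harbourcam_config_error", "error")))
stop_data <- function(...) stop(errorCondition(paste0(...),
  class = c("harbourcam_data_error", "error")))
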