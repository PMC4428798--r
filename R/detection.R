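#' Build the field-of-view polygon of a rig
#'
#' The water-surface footprint visible to the camera: a fan bounded by the
#' camera apex, the bearing rays at the left and right image edges, and the
#' opposite wharf waterline. The far boundary follows the wharf profile
#' (distance linear in bearing), densely sampled; area is the planar shoelace
#' area on the local east-north frame.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param step_deg Bearing sampling step along the wharf boundary (degrees).
#' @return Object of class \code{field_of_view}: list with \code{camera_id},
#'   \code{polygon} (data.frame \code{x_east}, \code{y_north}, \code{lat},
#'   \code{lon}; first vertex is the camera), \code{area_m2},
#'   \code{bearing_min}, \code{bearing_max}.
#' @export
build_fov <- function(rig, step_deg = 0.25) {
  b0 <- as.numeric(pixel_to_bearing(rig, 0))
  b1 <- as.numeric(pixel_to_bearing(rig, rig$image_width))
  bmin <- min(b0, b1); bmax <- max(b0, b1)
  if (bmax - bmin < 1e-9)
    stop_config("degenerate field of view: zero bearing width")
  bs <- unique(c(seq(bmin, bmax, by = step_deg), bmax,
                 rig$wharf_profile$bearing_deg[
                   rig$wharf_profile$bearing_deg > bmin &
                   rig$wharf_profile$bearing_deg < bmax]))
  bs <- sort(bs)
  D <- wharf_distance(rig, bs)
  en <- polar_to_enu(D, bs)
  x <- c(0, en$x_east); y <- c(0, en$y_north)
  ll <- enu_to_latlon(rig$lat, rig$lon, x, y)
  n <- length(x)
  area <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  structure(list(camera_id = rig$camera_id,
                 polygon = data.frame(x_east = x, y_north = y,
                                      lat = ll$lat, lon = ll$lon),
                 area_m2 = area, bearing_min = bmin, bearing_max = bmax),
            class = "field_of_view")
}

#' @export
print.field_of_view <- function(x, ...) {
  cat(sprintf("Field of view of camera '%s': %.0f m2, bearings %.1f-%.1f deg (%d vertices)\n",
              x$camera_id, x$area_m2, x$bearing_min, x$bearing_max,
              nrow(x$polygon)))
  invisible(x)
}

#' Water-surface area of the field of view falling in each range bin
#'
#' For detection-count expectations under uniform spatial density: the area
#' of the intersection of the FOV fan with each range annulus, by numerical
#' integration over bearing of (min(D, r2)^2 - min(D, r1)^2) / 2.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param breaks Increasing range-bin edges (m), half-open bins [lo, hi).
#' @param n_grid Bearing grid size for the integration.
#' @return data.frame with \code{bin_lo}, \code{bin_hi}, \code{area_m2}.
#' @export
fov_range_bin_areas <- function(rig, breaks, n_grid = 2000) {
  fov <- build_fov(rig)
  bs <- seq(fov$bearing_min, fov$bearing_max, length.out = n_grid)
  D <- wharf_distance(rig, bs)
  dth <- deg2rad(diff(bs))
  k <- length(breaks) - 1
  areas <- numeric(k)
  for (j in seq_len(k)) {
    f <- (pmin(D, breaks[j + 1])^2 - pmin(D, breaks[j])^2) / 2
    f <- pmax(f, 0)
    areas[j] <- sum((f[-1] + f[-length(f)]) / 2 * dth)
  }
  data.frame(bin_lo = breaks[-(k + 1)], bin_hi = breaks[-1], area_m2 = areas)
}

#' First detection per transit event
#'
#' Range and bearing analyses are based on the position of the first detected
#' surfacing within each transit event. Returns exactly one position row per
#' event: the earliest-timestamped resolved observation, ties broken by
#' smallest \code{obs_id}; the result is invariant to input row order.
#'
#' @param positions Output of \code{\link{estimate_position}} (rows with
#'   status != "ok" are ignored).
#' @param events Optional data.frame with \code{transit_event_id}; every
#'   listed event must have at least one resolved observation.
#' @return data.frame of first-detection position rows, one per event,
#'   ordered by event id.
#' @export
first_detections <- function(positions, events = NULL) {
  ok <- positions[positions$status == "ok" & !is.na(positions$transit_event_id), ,
                  drop = FALSE]
  if (!is.null(events)) {
    missing <- setdiff(events$transit_event_id, ok$transit_event_id)
    if (length(missing))
      stop_data("transit events with no resolved observations: ",
                paste(missing, collapse = ", "))
  }
  ok <- ok[order(ok$transit_event_id, as.numeric(ok$timestamp), ok$obs_id), ,
           drop = FALSE]
  first <- ok[!duplicated(ok$transit_event_id), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Detection counts by range and bearing
#'
#' Histograms of first-detection positions in half-open bins [lo, hi),
#' anchored at 0 for range and at multiples of the bin width for bearing.
#' Defaults of 10 m and 5 degrees match the granularity at which detection
#' peaks are usually reported for this kind of survey.
#'
#' @param first data.frame with \code{range_m} and \code{bearing_true}
#'   (e.g. from \code{\link{first_detections}}).
#' @param range_bin Range bin width, m (> 0).
#' @param bearing_bin Bearing bin width, degrees (> 0).
#' @return list of class \code{detection_histograms}: \code{range} and
#'   \code{bearing} data.frames (\code{bin_lo}, \code{bin_hi}, \code{count})
#'   and \code{n} total detections.
#' @export
detection_histograms <- function(first, range_bin = 10, bearing_bin = 5) {
  if (range_bin <= 0 || bearing_bin <= 0)
    stop("bin widths must be positive")
  hist1 <- function(x, w) {
    if (length(x) == 0)
      return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                        count = integer(0)))
    idx <- floor(x / w)
    lo <- seq(min(idx), max(idx)) * w
    cnt <- as.integer(table(factor(idx, levels = seq(min(idx), max(idx)))))
    data.frame(bin_lo = lo, bin_hi = lo + w, count = cnt)
  }
  structure(list(range = hist1(first$range_m, range_bin),
                 bearing = hist1(first$bearing_true, bearing_bin),
                 n = nrow(first),
                 range_bin = range_bin, bearing_bin = bearing_bin),
            class = "detection_histograms")
}

#' @export
print.detection_histograms <- function(x, ...) {
  cat(sprintf("Detection histograms: %d first detections\n", x$n))
  if (nrow(x$range)) {
    pk <- x$range[which.max(x$range$count), ]
    cat(sprintf("  range peak: %d detections in [%.0f, %.0f) m\n",
                pk$count, pk$bin_lo, pk$bin_hi))
  }
  if (nrow(x$bearing)) {
    pk <- x$bearing[which.max(x$bearing$count), ]
    cat(sprintf("  bearing peak: %d detections in [%.0f, %.0f) deg\n",
                pk$count, pk$bin_lo, pk$bin_hi))
  }
  invisible(x)
}

#' Test whether points lie inside a rig's field of view
#'
#' Polar containment test against the FOV fan: bearing within the image's
#' bearing span and range short of the wharf waterline.
#'
#' @param rig A \code{\link{camera_rig}}.
#' @param lat,lon Point coordinates.
#' @return Logical vector.
#' @export
in_fov <- function(rig, lat, lon) {
  en <- latlon_to_enu(rig$lat, rig$lon, lat, lon)
  pol <- enu_to_polar(en$x_east, en$y_north)
  b0 <- as.numeric(pixel_to_bearing(rig, 0))
  b1 <- as.numeric(pixel_to_bearing(rig, rig$image_width))
  pol$bearing_deg >= min(b0, b1) & pol$bearing_deg <= max(b0, b1) &
    pol$range_m < wharf_distance(rig, pol$bearing_deg)
}
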