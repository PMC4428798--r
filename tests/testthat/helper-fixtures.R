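# fixtures built in code: small rigs, tide series, hourly-record tables

# rig looking roughly west across a 150-450 m channel, video-style scale
test_rig <- function(height = 5, horizon_row = 200, still = FALSE) {
  lmk <- data.frame(
    name = c("l1", "light1", "l3", "light2", "l5"),
    bearing_true = c(250, 260, 280, 300, 310),
    pixel_col = c(50, 217, 550, 883, 1050),
    pixel_row_top = NA_real_, pixel_row_base = NA_real_,
    physical_height = NA_real_)
  wharf <- data.frame(bearing_deg = c(245, 275, 315),
                      distance_m = c(150, 300, 450))
  s <- 0.03   # true degrees per pixel used to place the light rows
  for (i in c(2, 4)) {
    D <- approx(wharf$bearing_deg, wharf$distance_m,
                xout = lmk$bearing_true[i], rule = 2)$y
    wd <- atan(height / D) * 180 / pi
    span <- (atan(height / D) + atan((18 - height) / D)) * 180 / pi
    lmk$pixel_row_base[i] <- horizon_row + wd / s
    lmk$pixel_row_top[i] <- lmk$pixel_row_base[i] - span / s
    lmk$physical_height[i] <- 18
  }
  camera_rig(camera_id = if (still) "still" else "video",
             lat = -32.04, lon = 115.75,
             height_above_datum = height,
             image_width = 1100, image_height = 900,
             horizon_row = horizon_row,
             landmarks = lmk, wharf_profile = wharf,
             focal_length = if (still) 5.7 else NULL,
             pixel_pitch = if (still) 0.0017 else NULL)
}

# rig whose bearing span covers due north and east, for axis-aligned checks
north_rig <- function() {
  camera_rig(camera_id = "north", lat = -32.04, lon = 115.75,
             height_above_datum = 5,
             image_width = 1000, image_height = 900, horizon_row = 200,
             landmarks = data.frame(name = c("a", "b", "c"),
                                    bearing_true = c(0, 60, 120),
                                    pixel_col = c(50, 500, 950),
                                    pixel_row_top = c(260, NA, NA),
                                    pixel_row_base = c(330, NA, NA),
                                    physical_height = c(18, NA, NA)),
             wharf_profile = data.frame(bearing_deg = c(0, 120),
                                        distance_m = c(350, 350)))
}

flat_tide <- function(level = 0, t0 = as.POSIXct("2010-05-01 00:00:00",
                                                 tz = "Etc/GMT-8")) {
  data.frame(timestamp = t0 + seq(0, 86400, by = 600), level_m = level)
}

# hourly-record table with controllable level counts; one record per hour
make_hourly <- function(glare_counts, beaufort = NULL,
                        t0 = as.POSIXct("2010-04-16 06:00:00",
                                        tz = "Etc/GMT-8")) {
  glare <- rep(as.integer(names(glare_counts)), glare_counts)
  n <- length(glare)
  if (is.null(beaufort)) beaufort <- rep(2L, n)
  data.frame(timestamp = t0 + (seq_len(n) - 1) * 3600,
             time_block_id = 1L, wave = seq_len(n),
             presence = rep_len(c(0L, 1L), n),
             glare = glare, beaufort = beaufort)
}

# independently coded great-circle distance check (via geosphere)
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

# sample n points uniformly over a rig's field of view by rejection
sample_fov_points <- function(rig, n) {
  fov <- build_fov(rig)
  xr <- range(fov$polygon$x_east); yr <- range(fov$polygon$y_north)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    cx <- runif(2 * n, xr[1], xr[2]); cy <- runif(2 * n, yr[1], yr[2])
    ll <- harbourcam:::enu_to_latlon(rig$lat, rig$lon, cx, cy)
    keep <- in_fov(rig, ll$lat, ll$lon)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  ll <- harbourcam:::enu_to_latlon(rig$lat, rig$lon, xs[1:n], ys[1:n])
  data.frame(x_east = xs[1:n], y_north = ys[1:n], lat = ll$lat, lon = ll$lon)
}
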