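test_that("bearing interpolation is exact at nodes, linear between, flagged beyond", {
  rig <- test_rig()
  lmk <- rig$landmarks
  # node identity
  expect_equal(as.numeric(pixel_to_bearing(rig, lmk$pixel_col)),
               lmk$bearing_true, tolerance = 1e-12)
  # midpoint between landmarks at 250 and 260 degrees
  mid <- mean(lmk$pixel_col[1:2])
  expect_equal(as.numeric(pixel_to_bearing(rig, mid)), 255, tolerance = 1e-12)
  # random columns against an independently solved two-point line equation
  set.seed(1)
  for (q in runif(25, min(lmk$pixel_col), max(lmk$pixel_col))) {
    i <- max(which(lmk$pixel_col <= q))
    i <- min(i, nrow(lmk) - 1)
    slope <- (lmk$bearing_true[i + 1] - lmk$bearing_true[i]) /
      (lmk$pixel_col[i + 1] - lmk$pixel_col[i])
    expect_equal(as.numeric(pixel_to_bearing(rig, q)),
                 lmk$bearing_true[i] + slope * (q - lmk$pixel_col[i]),
                 tolerance = 1e-9)
  }
  # extrapolation beyond the outermost landmarks is flagged
  b <- pixel_to_bearing(rig, c(10, 600, 1090))
  expect_identical(attr(b, "extrapolated"), c(TRUE, FALSE, TRUE))
  # order preservation between nodes
  bb <- as.numeric(pixel_to_bearing(rig, seq(0, 1100, by = 25)))
  expect_true(all(diff(bb) > 0))
  # inverse is consistent
  expect_equal(as.numeric(bearing_to_pixel(rig, bb[10])), seq(0, 1100, 25)[10],
               tolerance = 1e-9)
})

test_that("rig configuration errors are caught", {
  lmk1 <- data.frame(name = "a", bearing_true = 250, pixel_col = 100)
  expect_error(
    camera_rig("x", -32, 115, 5, 1000, 800, 200, lmk1,
               data.frame(bearing_deg = c(240, 260), distance_m = c(100, 200))),
    "at least 2 landmarks")
  lmk2 <- data.frame(name = c("a", "b", "c"), bearing_true = c(250, 270, 260),
                     pixel_col = c(100, 500, 900))
  expect_error(
    camera_rig("x", -32, 115, 5, 1000, 800, 200, lmk2,
               data.frame(bearing_deg = c(240, 260), distance_m = c(100, 200))),
    "monotone")
  expect_error(
    camera_rig("x", -32, 115, -1, 1000, 800, 200, lmk2[1:2, ],
               data.frame(bearing_deg = c(240, 260), distance_m = c(100, 200))),
    "height_above_datum")
})

test_that("effective height applies the tide correction by interpolation", {
  rig <- test_rig(height = 3)
  t0 <- as.POSIXct("2010-05-01 06:00:00", tz = "Etc/GMT-8")
  # zero tide: identity
  expect_equal(effective_height(rig, flat_tide(0), t0), 3)
  # simple arithmetic
  expect_equal(effective_height(rig, flat_tide(0.8), t0), 2.2)
  # interpolated level against an independent linear interpolation
  tide <- data.frame(timestamp = t0 + c(0, 1200), level_m = c(0.4, 1.0))
  tq <- t0 + 450
  manual <- 0.4 + (1.0 - 0.4) * 450 / 1200
  expect_equal(effective_height(rig, tide, tq), 3 - manual, tolerance = 1e-12)
  # camera submerged
  expect_error(effective_height(rig, flat_tide(3.5), t0), "height <= 0")
  # outside the series beyond tolerance
  expect_error(effective_height(rig, tide, t0 + 7200, extrapolation_tol = 60),
               "outside the tide series")
})

test_that("still-camera pixel-to-degrees follows the pinhole model", {
  rig <- test_rig(still = TRUE)
  expect_equal(pixel_to_degrees_still(rig, 0), 0)
  # offset such that offset * pitch = focal length gives 45 degrees
  off45 <- rig$focal_length / rig$pixel_pitch
  expect_equal(pixel_to_degrees_still(rig, off45), 45)
  # small-angle limit within 0.5% below 5 degrees
  for (off in c(10, 50, 150, 280)) {
    exact <- pixel_to_degrees_still(rig, off)
    approx_deg <- off * rig$pixel_pitch / rig$focal_length * 180 / pi
    if (exact < 5)
      expect_lt(abs(exact - approx_deg) / approx_deg, 0.005)
  }
  # missing metadata points the caller to the video calibration
  expect_error(pixel_to_degrees_still(test_rig(), 10), "video")
})

test_that("video pixel scale comes from landmark heights and matches the forward model", {
  rig <- test_rig()
  s <- video_pixel_scale(rig)
  # self-consistency: a landmark spanning k pixels maps back to its own span
  lmk <- rig$landmarks[!is.na(rig$landmarks$physical_height), ]
  k <- lmk$pixel_row_base[1] - lmk$pixel_row_top[1]
  expect_equal(pixel_to_degrees_video(rig, k), k * s)
  # both lights were placed with the same true scale, so the mean equals it
  expect_equal(s, 0.03, tolerance = 1e-10)
  # per-landmark scales are equal, so the mean equals either one alone
  one <- rig
  one$landmarks$physical_height[4] <- NA
  expect_equal(video_pixel_scale(one), s, tolerance = 1e-10)
  # no height-calibrated landmark
  none <- rig
  none$landmarks$physical_height <- NA_real_
  expect_error(video_pixel_scale(none), "height-calibrated")
})

test_that("depression angle converts to range by the artificial-horizon equation", {
  expect_equal(depression_to_range(2.5, 45), 2.5)
  expect_error(depression_to_range(2.5, 0), "artificial horizon")
  expect_error(depression_to_range(2.5, -1), "artificial horizon")
  # a pixel exactly on the wharf waterline returns the wharf distance
  rig <- test_rig()
  tide <- flat_tide(0)
  t0 <- tide$timestamp[1]
  col <- 620
  h <- effective_height(rig, tide, t0)
  row <- waterline_row(rig, col, h)
  obs <- data.frame(obs_id = 1, timestamp = t0, pixel_col = col,
                    pixel_row = row)
  est <- estimate_position(rig, obs, tide)
  b <- as.numeric(pixel_to_bearing(rig, col))
  expect_equal(est$range_m, wharf_distance(rig, b), tolerance = 1e-9)
})

test_that("estimated positions agree with an independent great-circle oracle", {
  rig <- north_rig()
  tide <- flat_tide(0.3)
  t0 <- tide$timestamp[10]
  # due north, 100 m: haversine distance and bearing check
  tgt <- geosphere::destPoint(c(rig$lon, rig$lat), 0, 100, r = 6378137)
  pj <- project_forward(rig, tgt[2], tgt[1], tide, t0)
  expect_true(pj$in_view)
  est <- estimate_position(rig, data.frame(obs_id = 1, timestamp = t0,
                                           pixel_col = pj$pixel_col,
                                           pixel_row = pj$pixel_row), tide)
  expect_equal(est$status, "ok")
  d <- haversine_m(est$lat, est$lon, tgt[2], tgt[1])
  expect_lt(d, 0.05)
  expect_lt(abs(haversine_m(est$lat, est$lon, rig$lat, rig$lon) - 100), 0.05)
  # due east: latitude unchanged to < 1e-7 degrees
  tgt90 <- geosphere::destPoint(c(rig$lon, rig$lat), 90, 150, r = 6378137)
  pj90 <- project_forward(rig, tgt90[2], tgt90[1], tide, t0)
  est90 <- estimate_position(rig, data.frame(obs_id = 1, timestamp = t0,
                                             pixel_col = pj90$pixel_col,
                                             pixel_row = pj90$pixel_row), tide)
  expect_lt(abs(est90$lat - rig$lat), 1e-7)
})

test_that("range-bearing invariants: range grows with depression, tide shifts height", {
  rig <- test_rig()
  tide <- flat_tide(0.5)
  t0 <- tide$timestamp[1]
  h <- effective_height(rig, tide, t0)
  col <- 500
  wl <- waterline_row(rig, col, h)
  rows <- seq(wl + 5, wl + 200, by = 5)
  obs <- data.frame(obs_id = seq_along(rows), timestamp = t0,
                    pixel_col = col, pixel_row = rows)
  est <- estimate_position(rig, obs, tide)
  # moving the pixel downward strictly shortens the range
  expect_true(all(diff(est$range_m) < 0))
  # raising the water by delta lowers effective height by exactly delta
  delta <- 0.3
  h2 <- effective_height(rig, flat_tide(0.5 + delta), t0)
  expect_equal(h - h2, delta, tolerance = 1e-12)
  # and shortens the range at fixed total depression
  expect_true(all(depression_to_range(h2, est$depression_deg) <
                    depression_to_range(h, est$depression_deg)))
})

test_that("forward projection and inversion are mutual inverses across rigs", {
  tide <- flat_tide(0.4)
  t0 <- tide$timestamp[5]
  set.seed(42)
  for (rig in list(test_rig(), test_rig(height = 3, horizon_row = 120),
                   test_rig(height = 8, horizon_row = 260, still = TRUE))) {
    b <- runif(60, 252, 308)
    r <- runif(60, 40, 0.9 * wharf_distance(rig, b))
    en <- harbourcam:::polar_to_enu(r, b)
    ll <- harbourcam:::enu_to_latlon(rig$lat, rig$lon, en$x_east, en$y_north)
    pj <- project_forward(rig, ll$lat, ll$lon, tide, rep(t0, 60))
    expect_true(all(pj$in_view))
    est <- estimate_position(rig, data.frame(obs_id = 1:60, timestamp = t0,
                                             pixel_col = pj$pixel_col,
                                             pixel_row = pj$pixel_row), tide)
    expect_true(all(est$status == "ok"))
    err <- haversine_m(est$lat, est$lon, ll$lat, ll$lon)
    expect_lt(max(err), 0.1)
    # pixel-space round trip
    pj2 <- project_forward(rig, est$lat, est$lon, tide, rep(t0, 60))
    expect_lt(max(abs(pj2$pixel_col - pj$pixel_col)), 0.5)
    expect_lt(max(abs(pj2$pixel_row - pj$pixel_row)), 0.5)
    # a point at a landmark's bearing projects onto the landmark's column
    lmk <- rig$landmarks
    enl <- harbourcam:::polar_to_enu(100, lmk$bearing_true[2])
    lll <- harbourcam:::enu_to_latlon(rig$lat, rig$lon, enl$x_east,
                                      enl$y_north)
    pjl <- project_forward(rig, lll$lat, lll$lon, tide, t0)
    expect_lt(abs(pjl$pixel_col - lmk$pixel_col[2]), 0.5)
  }
})

test_that("unresolvable observations become flagged skip records, not drops", {
  rig <- test_rig()
  tide <- flat_tide(0)
  t0 <- tide$timestamp[1]
  obs <- data.frame(obs_id = 1:3, timestamp = t0,
                    pixel_col = c(500, 500, 5000),
                    pixel_row = c(400, 100, 400))  # ok, above horizon, out of image
  est <- estimate_position(rig, obs, tide)
  expect_equal(nrow(est), 3)
  expect_equal(est$status[1], "ok")
  expect_match(est$status[2], "skipped")
  expect_match(est$status[3], "skipped.*bounds")
  expect_true(all(is.na(est$range_m[2:3])))
})

test_that("position error from pixel noise grows with range", {
  rig <- test_rig()
  tide <- flat_tide(0)
  t0 <- tide$timestamp[1]
  set.seed(7)
  med_err <- sapply(c(50, 200, 400), function(r0) {
    b <- runif(120, 270, 290)
    r <- pmin(r0, 0.92 * wharf_distance(rig, b))
    en <- harbourcam:::polar_to_enu(r, b)
    ll <- harbourcam:::enu_to_latlon(rig$lat, rig$lon, en$x_east, en$y_north)
    pj <- project_forward(rig, ll$lat, ll$lon, tide, rep(t0, 120))
    est <- estimate_position(rig, data.frame(
      obs_id = 1:120, timestamp = t0,
      pixel_col = pj$pixel_col + rnorm(120),
      pixel_row = pj$pixel_row + rnorm(120)), tide)
    ok <- est$status == "ok"
    median(haversine_m(est$lat[ok], est$lon[ok], ll$lat[ok], ll$lon[ok]))
  })
  expect_true(all(diff(med_err) > 0))
})
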