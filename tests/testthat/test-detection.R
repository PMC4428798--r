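test_that("a triangular field of view has the textbook area", {
  # straight wharf 200 m away (perpendicular), rays 100 m apart at the wharf:
  # a triangle of area 0.5 * 100 * 200 = 10,000 m^2
  half <- atan(50 / 200) * 180 / pi
  bs <- seq(270 - half, 270 + half, by = 0.05)
  wharf <- data.frame(bearing_deg = bs,
                      distance_m = 200 / cos((bs - 270) * pi / 180))
  rig <- camera_rig("tri", -32.04, 115.75, 5, 1000, 800, 200,
                    landmarks = data.frame(
                      name = c("a", "b"),
                      bearing_true = c(270 - half, 270 + half),
                      pixel_col = c(0, 1000)),
                    wharf_profile = wharf)
  fov <- build_fov(rig, step_deg = 0.05)
  expect_equal(fov$area_m2, 10000, tolerance = 1e-3)
})

test_that("polygon area agrees with a Monte-Carlo point-in-polygon estimate", {
  skip_if_not_installed("mgcv")
  rig <- test_rig()
  fov <- build_fov(rig)
  set.seed(123)
  n <- 1e5
  xr <- range(fov$polygon$x_east); yr <- range(fov$polygon$y_north)
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  inside <- mgcv::in.out(as.matrix(fov$polygon[, c("x_east", "y_north")]),
                         cbind(px, py))
  mc_area <- mean(inside) * diff(xr) * diff(yr)
  expect_lt(abs(mc_area - fov$area_m2) / fov$area_m2, 0.01)
})

test_that("a wider bearing span strictly contains a narrower one", {
  wide <- test_rig()                      # landmarks 250-310
  lmk <- wide$landmarks[c(2, 3, 4), ]     # 260-300
  narrow <- camera_rig("videoN", wide$lat, wide$lon,
                       wide$height_above_datum, 700, 900, 200,
                       landmarks = transform(lmk, pixel_col = c(30, 350, 670)),
                       wharf_profile = wide$wharf_profile)
  fw <- build_fov(wide); fn <- build_fov(narrow)
  expect_gt(fw$area_m2, fn$area_m2)
  expect_true(fn$bearing_min >= fw$bearing_min &&
                fn$bearing_max <= fw$bearing_max)
  # every vertex of the narrow FOV lies inside (or on) the wide FOV
  pts <- fn$polygon[-1, ]
  pol <- harbourcam:::enu_to_polar(pts$x_east, pts$y_north)
  expect_true(all(pol$bearing_deg >= fw$bearing_min &
                    pol$bearing_deg <= fw$bearing_max))
  expect_true(all(pol$range_m <=
                    wharf_distance(wide, pol$bearing_deg) * (1 + 1e-9)))
})

test_that("first detections pick the earliest surfacing, deterministically", {
  t0 <- as.POSIXct("2010-05-02 08:00:00", tz = "Etc/GMT-8")
  pos <- data.frame(obs_id = c(3L, 1L, 2L, 10L),
                    timestamp = t0 + c(2, 0, 1, 50),
                    transit_event_id = c(1L, 1L, 1L, 2L),
                    range_m = c(100, 110, 120, 200),
                    bearing_true = c(280, 281, 282, 290),
                    lat = -32.04, lon = 115.75, status = "ok")
  fd <- first_detections(pos)
  expect_equal(nrow(fd), 2)
  expect_equal(fd$obs_id, c(1L, 10L))        # earliest per event
  # singleton event returns its only observation
  expect_equal(fd$range_m[fd$transit_event_id == 2], 200)
  # order invariance
  set.seed(4)
  for (i in 1:5) {
    fd2 <- first_detections(pos[sample(nrow(pos)), ])
    expect_identical(fd2$obs_id, fd$obs_id)
  }
  # timestamp ties broken by smallest obs_id
  tie <- pos
  tie$timestamp <- t0
  expect_equal(first_detections(tie)$obs_id, c(1L, 10L))
  # events with no observations are reported
  ev <- data.frame(transit_event_id = c(1L, 2L, 3L))
  expect_error(first_detections(pos, ev), "3")
})

test_that("detection histograms conserve counts in half-open bins", {
  empty <- detection_histograms(data.frame(range_m = numeric(0),
                                           bearing_true = numeric(0)))
  expect_equal(empty$n, 0)
  expect_equal(sum(empty$range$count), 0)

  fd <- data.frame(range_m = c(5, 10, 10.01, 109.9, 110, 463),
                   bearing_true = c(280, 280.1, 284.9, 285, 290, 299))
  h <- detection_histograms(fd, range_bin = 10, bearing_bin = 5)
  expect_equal(sum(h$range$count), nrow(fd))
  expect_equal(sum(h$bearing$count), nrow(fd))
  # half-open binning: 110 falls in [110, 120), 285 in [285, 290)
  expect_equal(h$range$count[h$range$bin_lo == 100], 1)
  expect_equal(h$range$count[h$range$bin_lo == 110], 1)
  expect_equal(h$bearing$count[h$bearing$bin_lo == 280], 3)
  expect_equal(h$bearing$count[h$bearing$bin_lo == 285], 1)
  expect_error(detection_histograms(fd, range_bin = 0), "positive")
})

test_that("uniform positions over the FOV give area-weighted bin counts", {
  rig <- test_rig()
  set.seed(31)
  pts <- sample_fov_points(rig, 5000)
  pol <- harbourcam:::enu_to_polar(pts$x_east, pts$y_north)
  breaks <- seq(0, 460, by = 46)
  areas <- fov_range_bin_areas(rig, breaks)
  counts <- as.vector(table(cut(pol$range_m, breaks, right = FALSE)))
  keep <- areas$area_m2 > 0
  chi <- chisq.test(counts[keep], p = areas$area_m2[keep] /
                      sum(areas$area_m2[keep]))
  expect_gt(chi$p.value, 0.01)
  # every sampled point is inside the FOV polygon by construction; the
  # bearing span of points respects the FOV bearing limits
  fov <- build_fov(rig)
  expect_true(all(pol$bearing_deg >= fov$bearing_min &
                    pol$bearing_deg <= fov$bearing_max))
})

test_that("simulated first detections lie inside the field of view", {
  cfg <- sim_config(seed = 13)
  sc <- simulate_scene(cfg)
  tr <- simulate_transits(cfg, sc, n_hours = 60)
  est <- estimate_position(sc$rig, tr$observations, sc$tide)
  fd <- first_detections(est, tr$events)
  expect_equal(nrow(fd), nrow(tr$events))
  h <- detection_histograms(fd)
  expect_equal(h$n, nrow(tr$events))
  expect_equal(sum(h$range$count), nrow(tr$events))
  # truth positions of all observations are inside the FOV
  expect_true(all(in_fov(sc$rig, tr$truth$lat, tr$truth$lon)))
})
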