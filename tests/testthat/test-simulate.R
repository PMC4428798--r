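test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5)
  s1 <- simulate_scene(cfg); s2 <- simulate_scene(cfg)
  expect_identical(s1$tide, s2$tide)
  expect_identical(s1$rig$landmarks, s2$rig$landmarks)
  h1 <- simulate_hourly_presence(cfg, n_hours = 200)
  h2 <- simulate_hourly_presence(cfg, n_hours = 200)
  expect_identical(h1, h2)
  t1 <- simulate_transits(cfg, s1, n_hours = 48)
  t2 <- simulate_transits(cfg, s2, n_hours = 48)
  expect_identical(t1$observations, t2$observations)
  c1 <- simulate_calibration_run(cfg, s1)
  c2 <- simulate_calibration_run(cfg, s2)
  expect_identical(c1, c2)
  # a different seed changes the draws
  expect_false(identical(simulate_hourly_presence(sim_config(seed = 6),
                                                  n_hours = 200), h1))
})

test_that("the tide stays within its configured envelope and the scene is consistent", {
  cfg <- sim_config(seed = 19)
  sc <- simulate_scene(cfg)
  dev <- abs(sc$tide$level_m - cfg$tide$mean_level)
  expect_lt(max(dev), cfg$tide$amplitude + 5 * cfg$tide$noise_sd)
  # the rig's landmark-height calibration recovers the configured scale:
  # the forward-projection model and the video calibration agree
  expect_equal(video_pixel_scale(sc$rig), cfg$rig$deg_per_px,
               tolerance = 1e-10)
  # wharf waterline depression matches the closed form at a light's bearing
  b <- cfg$rig$light_bearings[1]
  D <- wharf_distance(sc$rig, b)
  expect_equal(wharf_depression(sc$rig, b, 5), atan(5 / D) * 180 / pi,
               tolerance = 1e-12)
})

test_that("transit counts follow the thinned-Poisson expectation", {
  # fast surfacing so essentially no event goes undetected
  cfg <- sim_config(seed = 23, transits = list(surfacing_mean_s = 5))
  sc <- simulate_scene(cfg)
  tr <- simulate_transits(cfg, sc, n_hours = 400)
  set.seed(cfg$seed + 2L)   # the covariate stream used inside the generator
  sched <- harbourcam:::truncate_grid(
    harbourcam:::covariate_schedule(cfg), 400)
  # regenerate the same thinning probabilities
  pr <- cfg$presence
  p <- plogis(pr$beta0 + pr$beta_glare * sched$glare +
                pr$beta_beaufort * sched$beaufort)
  expected <- cfg$transits$rate_per_hour * sum(p)
  expect_lt(abs(nrow(tr$events) - expected), 3.5 * sqrt(expected) + 2)
  # group-size triples are ordered
  expect_true(all(tr$events$group_size_min <= tr$events$group_size_best &
                    tr$events$group_size_best <= tr$events$group_size_max))
  expect_true(all(tr$events$first_detection_time <=
                    tr$events$last_detection_time))
})

test_that("noiseless surfacings round-trip to centimetre accuracy", {
  cfg <- sim_config(seed = 29, transits = list(pixel_noise_sd = 0))
  sc <- simulate_scene(cfg)
  tr <- simulate_transits(cfg, sc, n_hours = 48)
  est <- estimate_position(sc$rig, tr$observations, sc$tide)
  expect_true(all(est$status == "ok"))
  err <- haversine_m(est$lat, est$lon, tr$truth$lat, tr$truth$lon)
  expect_lt(max(err), 0.1)
})

test_that("the presence series honours its marginal and serial targets", {
  long <- list(block1 = c("2009-06-01", "2010-05-31"),
               block2 = c("2010-06-10", "2010-12-31"))
  cfg <- sim_config(seed = 37, study = long)
  d <- simulate_hourly_presence(cfg, n_hours = 5200)
  expect_gte(nrow(d), 5000)
  truth <- attr(d, "truth")
  # marginal rate matches the logistic closed form within sampling error
  # (allowing for the AR-1 design effect on the variance of the mean)
  pbar <- mean(truth$marginal_p)
  de <- (1 + truth$alpha) / (1 - truth$alpha)
  expect_lt(abs(mean(d$presence) - pbar),
            4 * sqrt(pbar * (1 - pbar) * de / nrow(d)))
  # realised lag-1 correlation close to the target alpha
  adj <- which(diff(d$wave) == 1 & diff(d$time_block_id) == 0)
  r <- cor(d$presence[adj], d$presence[adj + 1])
  expect_lt(abs(r - 0.4), 0.05)
})

test_that("alpha = 0 yields a serially independent presence series", {
  long <- list(block1 = c("2009-06-01", "2010-05-31"),
               block2 = c("2010-06-10", "2010-12-31"))
  cfg <- sim_config(seed = 41, study = long, presence = list(alpha = 0))
  d <- simulate_hourly_presence(cfg, n_hours = 5000)
  adj <- which(diff(d$wave) == 1 & diff(d$time_block_id) == 0)
  r <- cor(d$presence[adj], d$presence[adj + 1])
  expect_lt(abs(r), 0.03)
})

test_that("infeasible binary-correlation targets are rejected with the bound", {
  expect_error(latent_ar1_rho(0.99, 0.5), "infeasible")
  expect_error(simulate_hourly_presence(sim_config(seed = 1,
                                                   presence = list(alpha = 0.999))),
               "infeasible")
  # the calibration itself is accurate: the realised latent correlation
  # reproduces the requested binary correlation
  rho <- latent_ar1_rho(0.4, 0.5)
  expect_equal(harbourcam:::binary_lag1_corr(rho, 0.5), 0.4,
               tolerance = 1e-6)
})

test_that("calibration fixes sweep the range strictly upward", {
  cfg <- sim_config(seed = 43)
  sc <- simulate_scene(cfg)
  cal <- simulate_calibration_run(cfg, sc)
  expect_equal(nrow(cal), 9)
  expect_true(all(diff(cal$range_m) > 0))
  # covariate scales stay on their stated ranges
  d <- simulate_hourly_presence(cfg, n_hours = 500)
  expect_true(all(d$glare %in% 0:4))
  expect_true(all(d$beaufort >= 1 & d$beaufort <= 3))
  expect_true(all(d$cloud %in% 0:8))
  expect_true(all(d$light %in% 1:2))
  expect_true(all(d$haze %in% 0:3))
  expect_true(all(d$rain %in% 0:1))
  expect_true(all(d$droplets %in% 0:4))
  expect_true(all(d$presence %in% 0:1))
})
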