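#' Simulation configuration for the synthetic harbour
#'
#' Defaults describe a shore camera on a 5 m rig overlooking a harbour
#' channel whose opposite wharf lies 120-450 m away, recording 06:00-18:00
#' over two survey blocks separated by a gap, with semidiurnal tide, hourly
#' environmental covariates (glare following a diurnal profile that is zero
#' in the middle of the day, Beaufort a bounded random walk), and a marginal
#' logistic presence model with AR-1 serial dependence.
#'
#' @param seed Integer RNG seed; all generators are deterministic given the
#'   configuration.
#' @param ... Named overrides of the default fields (see the returned list).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    rig = list(
      camera_id = "video", lat = -32.04, lon = 115.75,
      height_above_datum = 5,
      image_width = 1440, image_height = 1020, horizon_row = 280,
      deg_per_px = 0.03,                      # true vertical pixel scale
      landmark_bearings = c(250, 265, 280, 295, 310),
      landmark_cols = c(60, 380, 700, 1020, 1340),
      light_bearings = c(265, 295),           # height-calibrated lights
      light_height = 18,
      wharf_bearings = c(245, 260, 275, 290, 315),
      wharf_distances = c(120, 180, 260, 350, 450)),
    tide = list(mean_level = 0.8, amplitude = 0.4, period_h = 12.42,
                noise_sd = 0.02, step_s = 600),
    study = list(
      block1 = c("2010-04-16", "2010-06-02"),
      block2 = c("2010-06-29", "2010-08-02"),
      hours = 6:17, tz = "Etc/GMT-8"),
    presence = list(beta0 = 0.25, beta_glare = -0.26, beta_beaufort = 0,
                    alpha = 0.4),
    covariates = list(
      glare_base = c(3, 2, 1, 0, 0, 0, 0, 0, 0, 1, 2, 3),
      beaufort_range = c(1, 3), cloud_glare_cut = 6),
    transits = list(rate_per_hour = 1.5, speed_m_s = 2,
                    surfacing_mean_s = 25, group_lambda = 1.5,
                    pixel_noise_sd = 1, still_interval_s = 20),
    calibration = list(n_fixes = 9, ranges = seq(60, 380, length.out = 9),
                       gps_noise_sd = 2))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the harbour scene: camera rig and tide series
#'
#' Builds the camera rig (landmarks, height-calibrated wharf lights, wharf
#' waterline profile) and a semidiurnal sinusoid-plus-noise tide series
#' spanning both survey blocks. Deterministic given the configuration seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return list of class \code{harbour_scene}: \code{rig}, \code{tide},
#'   \code{config}.
#' @export
simulate_scene <- function(config = sim_config()) {
  set.seed(config$seed)
  rc <- config$rig
  s <- rc$deg_per_px
  wharf <- data.frame(bearing_deg = rc$wharf_bearings,
                      distance_m = rc$wharf_distances)
  Dlight <- stats::approx(wharf$bearing_deg, wharf$distance_m,
                          xout = rc$light_bearings, rule = 2)$y
  h <- rc$height_above_datum
  wd <- rad2deg(atan(h / Dlight))
  span <- rad2deg(atan(h / Dlight) + atan((rc$light_height - h) / Dlight))
  row_base <- rc$horizon_row + wd / s
  row_top <- row_base - span / s
  nlm <- length(rc$landmark_bearings)
  lmk <- data.frame(
    name = paste0("lmk", seq_len(nlm)),
    bearing_true = rc$landmark_bearings,
    pixel_col = rc$landmark_cols,
    pixel_row_top = NA_real_, pixel_row_base = NA_real_,
    physical_height = NA_real_)
  li <- match(rc$light_bearings, rc$landmark_bearings)
  if (any(is.na(li)))
    stop_config("light_bearings must be a subset of landmark_bearings")
  lmk$pixel_row_top[li] <- row_top
  lmk$pixel_row_base[li] <- row_base
  lmk$physical_height[li] <- rc$light_height
  lmk$name[li] <- paste0("light", seq_along(li))
  rig <- camera_rig(camera_id = rc$camera_id, lat = rc$lat, lon = rc$lon,
                    height_above_datum = h,
                    image_width = rc$image_width,
                    image_height = rc$image_height,
                    horizon_row = rc$horizon_row,
                    landmarks = lmk, wharf_profile = wharf)
  tz <- config$study$tz
  t0 <- as.POSIXct(paste(config$study$block1[1], "00:00:00"), tz = tz) - 3600
  t1 <- as.POSIXct(paste(config$study$block2[2], "23:59:59"), tz = tz) + 3600
  tt <- seq(t0, t1, by = config$tide$step_s)
  level <- config$tide$mean_level +
    config$tide$amplitude * sin(2 * pi * as.numeric(tt) /
                                (config$tide$period_h * 3600)) +
    stats::rnorm(length(tt), sd = config$tide$noise_sd)
  structure(list(rig = rig,
                 tide = data.frame(timestamp = tt, level_m = level),
                 config = config),
            class = "harbour_scene")
}

#' @export
print.harbour_scene <- function(x, ...) {
  cat("Synthetic harbour scene (seed ", x$config$seed, ")\n", sep = "")
  print(x$rig)
  cat(sprintf("  tide: %d gauge readings, %.2f-%.2f m\n", nrow(x$tide),
              min(x$tide$level_m), max(x$tide$level_m)))
  invisible(x)
}

# -- correlated binary machinery ------------------------------------------

# bivariate standard normal CDF P(Z1 <= h, Z2 <= k) with correlation rho,
# by 1-D quadrature of the conditional probability
pnorm2 <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((k - rho * z) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, h, rel.tol = 1e-10)$value
}

# lag-1 correlation of the thresholded binary series at marginal p when the
# latent Gaussian AR-1 has correlation rho
binary_lag1_corr <- function(rho, p) {
  q <- stats::qnorm(p)
  (pnorm2(q, q, rho) - p^2) / (p * (1 - p))
}

#' Latent-Gaussian correlation matching a target binary autocorrelation
#'
#' The simulator generates correlated presence/absence by thresholding a
#' latent AR-1 Gaussian process. This solves for the latent lag-1
#' correlation rho such that the binary series at marginal probability
#' \code{p} has lag-1 correlation \code{alpha}.
#'
#' @param alpha Target binary lag-1 correlation, |alpha| < 1.
#' @param p Marginal presence probability.
#' @return Latent correlation rho.
#' @export
latent_ar1_rho <- function(alpha, p) {
  if (abs(alpha) >= 1) stop_config("|alpha| must be < 1")
  if (abs(alpha) < 1e-10) return(0)
  upper <- binary_lag1_corr(0.999, p)
  lower <- binary_lag1_corr(-0.999, p)
  if (alpha >= upper || alpha <= lower)
    stop_config(sprintf(
      "alpha = %.3f is infeasible for a thresholded binary series at p = %.3f: achievable lag-1 correlation is (%.3f, %.3f)",
      alpha, p, lower, upper))
  stats::uniroot(function(r) binary_lag1_corr(r, p) - alpha,
                 c(-0.999, 0.999), tol = 1e-9)$root
}

# latent AR-1 Gaussian series across integer calendar gaps
latent_ar1_series <- function(rho, gaps) {
  m <- length(gaps) + 1
  z <- numeric(m)
  z[1] <- stats::rnorm(1)
  if (m > 1) {
    r <- rho^gaps
    z[-1] <- stats::rnorm(m - 1) * sqrt(1 - r^2)
    for (k in 2:m) z[k] <- r[k - 1] * z[k - 1] + z[k]
  }
  z
}

# truncate the study grid to n rows, drawing from both blocks
# proportionally so the grouping structure is preserved
truncate_grid <- function(d, n_hours) {
  if (is.null(n_hours) || n_hours >= nrow(d)) return(d)
  idx <- split(seq_len(nrow(d)), d$time_block_id)
  sizes <- lengths(idx)
  take <- pmin(sizes, round(n_hours * sizes / sum(sizes)))
  short <- n_hours - sum(take)
  if (short != 0) take[1] <- take[1] + short
  keep <- sort(unlist(mapply(function(i, k) i[seq_len(k)], idx, take,
                             SIMPLIFY = FALSE)))
  d[keep, , drop = FALSE]
}

# hourly covariate schedule over the study grid (internal)
covariate_schedule <- function(config) {
  st <- config$study
  tz <- st$tz
  grid <- do.call(rbind, lapply(c("block1", "block2"), function(bk) {
    days <- seq(as.Date(st[[bk]][1]), as.Date(st[[bk]][2]), by = "day")
    expand.grid(hour = st$hours, day = days)[, c("day", "hour")]
  }))
  block <- rep(c(1L, 2L), times = c(
    length(seq(as.Date(st$block1[1]), as.Date(st$block1[2]), by = "day")) *
      length(st$hours),
    length(seq(as.Date(st$block2[1]), as.Date(st$block2[2]), by = "day")) *
      length(st$hours)))
  ts <- as.POSIXct(paste(grid$day, sprintf("%02d:00:00", grid$hour)), tz = tz)
  n <- length(ts)
  cv <- config$covariates
  step <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  cloud <- abs(((cumsum(step) + 4) %% 16) - 8)           # reflecting walk 0..8
  bstep <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                  prob = c(0.2, 0.6, 0.2))
  brange <- cv$beaufort_range
  beaufort <- abs(((cumsum(bstep) + brange[1]) %% (2 * diff(brange))) -
                    diff(brange)) + brange[1]
  base <- cv$glare_base[match(grid$hour, config$study$hours)]
  jitter <- sample(c(-1L, 0L, 0L, 1L), n, replace = TRUE)
  glare <- ifelse(cloud >= cv$cloud_glare_cut, 0L,
                  pmin(pmax(base + jitter, 0L), 4L))
  glare <- ifelse(base == 0, 0L, glare)   # no glare in the midday window
  light <- ifelse(grid$hour %in% range(config$study$hours), 1L, 2L)
  haze <- stats::rbinom(n, 1, 0.05) * sample(1:3, n, replace = TRUE)
  rain <- stats::rbinom(n, 1, 0.04)
  droplets <- ifelse(rain == 1, sample(0:2, n, replace = TRUE), 0L)
  block_start <- as.POSIXct(paste(ifelse(block == 1, st$block1[1],
                                         st$block2[1]), "00:00:00"), tz = tz)
  wave <- as.integer(round(as.numeric(ts - block_start, units = "hours")))
  data.frame(time_block_id = block, timestamp = ts, wave = wave,
             glare = as.integer(glare), beaufort = as.integer(beaufort),
             cloud = as.integer(cloud), light = light,
             haze = as.integer(haze), rain = rain,
             droplets = as.integer(droplets))
}

#' Simulate an hourly presence/absence record table
#'
#' Generates the hourly covariate schedule and a binary presence series
#' whose marginal follows logit P(present) = beta0 + beta_glare * glare +
#' beaufort term, with lag-1 serial correlation alpha obtained by
#' thresholding a latent AR-1 Gaussian process whose correlation is
#' calibrated to the target binary correlation at the mean marginal
#' probability. Gaps in the record (overnight, between blocks) advance the
#' calendar lag, weakening the dependence accordingly.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_hours Optional truncation: keep only the first \code{n_hours}
#'   records of the study grid.
#' @return data.frame of hourly records (\code{time_block_id},
#'   \code{timestamp}, \code{wave}, \code{presence}, covariates) with the
#'   truth parameters attached as attribute \code{"truth"}.
#' @export
simulate_hourly_presence <- function(config = sim_config(), n_hours = NULL) {
  set.seed(config$seed + 1L)
  d <- covariate_schedule(config)
  d <- truncate_grid(d, n_hours)
  pr <- config$presence
  p <- stats::plogis(pr$beta0 + pr$beta_glare * d$glare +
                       pr$beta_beaufort * d$beaufort)
  rho <- latent_ar1_rho(pr$alpha, mean(p))
  d$presence <- 0L
  for (bk in split(seq_len(nrow(d)), d$time_block_id)) {
    z <- latent_ar1_series(rho, diff(d$wave[bk]))
    d$presence[bk] <- as.integer(stats::pnorm(z) < p[bk])
  }
  d <- d[c("time_block_id", "timestamp", "wave", "presence", "glare",
           "beaufort", "cloud", "light", "haze", "rain", "droplets")]
  attr(d, "truth") <- c(pr, list(latent_rho = rho, marginal_p = p))
  d
}

#' Simulate dolphin transit events and surfacing observations
#'
#' Candidate transits arrive as a Poisson process over recording hours and
#' are thinned by the hourly presence model; each retained event crosses the
#' field of view on a straight line at constant speed, surfacing at
#' exponentially-spaced intervals. Surfacings are projected into pixel
#' coordinates through the exact forward camera model, with optional pixel
#' noise; ground-truth positions are retained for recovery checks.
#'
#' @param config A \code{\link{sim_config}}.
#' @param scene A \code{\link{simulate_scene}} result.
#' @param n_hours Optional truncation of the study grid (see
#'   \code{\link{simulate_hourly_presence}}).
#' @return list with \code{events} (transit_event_id, camera_id,
#'   first/last detection times, group_size_min/best/max, n_surfacings),
#'   \code{observations} (obs_id, camera_id, timestamp, pixel_col,
#'   pixel_row, transit_event_id), and \code{truth} (obs_id, lat, lon,
#'   range_m, bearing_true).
#' @export
simulate_transits <- function(config = sim_config(), scene = simulate_scene(config),
                              n_hours = NULL) {
  set.seed(config$seed + 2L)
  rig <- scene$rig
  tc <- config$transits
  sched <- truncate_grid(covariate_schedule(config), n_hours)
  pr <- config$presence
  p <- stats::plogis(pr$beta0 + pr$beta_glare * sched$glare +
                       pr$beta_beaufort * sched$beaufort)
  b0 <- as.numeric(pixel_to_bearing(rig, 0))
  b1 <- as.numeric(pixel_to_bearing(rig, rig$image_width))
  bmin <- min(b0, b1) + 1; bmax <- max(b0, b1) - 1
  if (bmax - bmin < 5)
    stop_config("field of view too narrow for transit paths")
  ev_list <- list(); obs_list <- list(); truth_list <- list()
  ev_id <- 0L; obs_id <- 0L
  for (i in seq_len(nrow(sched))) {
    ncand <- stats::rpois(1, tc$rate_per_hour)
    if (ncand == 0) next
    keep <- stats::runif(ncand) < p[i]
    for (k in seq_len(ncand)) {
      if (!keep[k]) next
      t_start <- sched$timestamp[i] + stats::runif(1, 0, 3000)
      ba <- bmin; bb <- bmax
      if (stats::runif(1) < 0.5) { ba <- bmax; bb <- bmin }
      r1 <- stats::runif(1, 0.15, 0.85) * wharf_distance(rig, ba)
      r2 <- stats::runif(1, 0.15, 0.85) * wharf_distance(rig, bb)
      e1 <- polar_to_enu(r1, ba); e2 <- polar_to_enu(r2, bb)
      len <- sqrt((e2$x_east - e1$x_east)^2 + (e2$y_north - e1$y_north)^2)
      dur <- len / tc$speed_m_s
      st <- cumsum(stats::rexp(ceiling(dur / tc$surfacing_mean_s) + 10,
                               rate = 1 / tc$surfacing_mean_s))
      st <- st[st < dur]
      if (length(st) == 0) next
      fr <- st / dur
      xs <- e1$x_east + fr * (e2$x_east - e1$x_east)
      ys <- e1$y_north + fr * (e2$y_north - e1$y_north)
      ll <- enu_to_latlon(rig$lat, rig$lon, xs, ys)
      tms <- t_start + st
      pj <- project_forward(rig, ll$lat, ll$lon, scene$tide, tms)
      vis <- pj$in_view
      if (tc$pixel_noise_sd > 0) {
        pj$pixel_col <- pj$pixel_col + stats::rnorm(nrow(pj),
                                                    sd = tc$pixel_noise_sd)
        pj$pixel_row <- pj$pixel_row + stats::rnorm(nrow(pj),
                                                    sd = tc$pixel_noise_sd)
        vis <- vis & pj$pixel_col >= 0 & pj$pixel_col <= rig$image_width &
          pj$pixel_row >= 0 & pj$pixel_row <= rig$image_height
      }
      if (!any(vis)) next
      ev_id <- ev_id + 1L
      ids <- obs_id + seq_len(sum(vis))
      obs_id <- obs_id + sum(vis)
      best <- 1L + stats::rpois(1, tc$group_lambda)
      gmin <- max(1L, best - stats::rbinom(1, best - 1L, 0.3))
      gmax <- best + stats::rpois(1, 0.5)
      ev_list[[ev_id]] <- data.frame(
        transit_event_id = ev_id, camera_id = rig$camera_id,
        first_detection_time = min(tms[vis]),
        last_detection_time = max(tms[vis]),
        group_size_min = gmin, group_size_best = best, group_size_max = gmax,
        n_surfacings = sum(vis))
      obs_list[[ev_id]] <- data.frame(
        obs_id = ids, camera_id = rig$camera_id, timestamp = tms[vis],
        pixel_col = pj$pixel_col[vis], pixel_row = pj$pixel_row[vis],
        transit_event_id = ev_id)
      truth_list[[ev_id]] <- data.frame(
        obs_id = ids, lat = ll$lat[vis], lon = ll$lon[vis],
        range_m = pj$range_m[vis], bearing_true = pj$bearing_true[vis])
    }
  }
  if (ev_id == 0L)
    stop_data("no transit events generated; increase the rate or study span")
  list(events = do.call(rbind, ev_list),
       observations = do.call(rbind, obs_list),
       truth = do.call(rbind, truth_list))
}

#' Simulate a boat-based GPS calibration run
#'
#' Generates a range sweep of calibration fixes across the field of view:
#' true positions on the water, GPS readings with configurable jitter, and
#' the matched pixel observations with pixel noise.
#'
#' @param config A \code{\link{sim_config}}.
#' @param scene A \code{\link{simulate_scene}} result.
#' @return data.frame of fixes: \code{fix_id}, \code{timestamp},
#'   \code{gps_lat}, \code{gps_lon}, \code{pixel_col}, \code{pixel_row},
#'   \code{camera_id}, plus true \code{range_m} and \code{true_lat},
#'   \code{true_lon} for recovery checks.
#' @export
simulate_calibration_run <- function(config = sim_config(),
                                     scene = simulate_scene(config)) {
  set.seed(config$seed + 3L)
  rig <- scene$rig
  cal <- config$calibration
  n <- cal$n_fixes
  ranges <- cal$ranges
  if (length(ranges) != n) ranges <- seq(min(ranges), max(ranges),
                                         length.out = n)
  # place each fix at a bearing whose wharf distance comfortably exceeds it
  wp <- rig$wharf_profile
  need <- ranges / 0.85
  bearings <- stats::approx(wp$distance_m, wp$bearing_deg, xout = need,
                            rule = 2)$y
  bv0 <- as.numeric(pixel_to_bearing(rig, 0))
  bv1 <- as.numeric(pixel_to_bearing(rig, rig$image_width))
  bearings <- pmin(pmax(bearings, min(bv0, bv1) + 2), max(bv0, bv1) - 2)
  ll <- with(polar_to_enu(ranges, bearings),
             enu_to_latlon(rig$lat, rig$lon, x_east, y_north))
  tms <- scene$tide$timestamp[1] + 3600 + (seq_len(n) - 1) * 300
  pj <- project_forward(rig, ll$lat, ll$lon, scene$tide, tms)
  if (any(!pj$in_view))
    stop_config("calibration fixes fall outside the field of view")
  gps <- enu_to_latlon(rig$lat, rig$lon,
                       with(latlon_to_enu(rig$lat, rig$lon, ll$lat, ll$lon),
                            x_east) + stats::rnorm(n, sd = cal$gps_noise_sd),
                       with(latlon_to_enu(rig$lat, rig$lon, ll$lat, ll$lon),
                            y_north) + stats::rnorm(n, sd = cal$gps_noise_sd))
  px_sd <- config$transits$pixel_noise_sd
  data.frame(fix_id = seq_len(n), timestamp = tms,
             gps_lat = gps$lat, gps_lon = gps$lon,
             pixel_col = pj$pixel_col + stats::rnorm(n, sd = px_sd),
             pixel_row = pj$pixel_row + stats::rnorm(n, sd = px_sd),
             camera_id = rig$camera_id,
             range_m = pj$range_m, true_lat = ll$lat, true_lon = ll$lon)
}
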