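#' Match GPS calibration fixes to camera observations
#'
#' Boat-based calibration: a flag is raised at known GPS positions while the
#' cameras record; each fix is matched to the camera observation nearest in
#' time within a window.
#'
#' @param fixes data.frame with \code{fix_id}, \code{timestamp},
#'   \code{gps_lat}, \code{gps_lon}, optional \code{camera_id}.
#' @param observations data.frame with \code{obs_id}, \code{timestamp},
#'   \code{pixel_col}, \code{pixel_row}.
#' @param window_s Matching window, seconds (default +/- 5 s).
#' @return \code{fixes} with matched \code{obs_id}, \code{pixel_col},
#'   \code{pixel_row} columns appended.
#' @export
match_fixes <- function(fixes, observations, window_s = 5) {
  ft <- as.numeric(fixes$timestamp)
  ot <- as.numeric(observations$timestamp)
  idx <- integer(nrow(fixes))
  for (i in seq_along(ft)) {
    dt <- abs(ot - ft[i])
    cand <- which(dt <= window_s)
    if (length(cand) == 0)
      stop_data("no observation within ", window_s, " s of fix ",
                fixes$fix_id[i])
    best <- cand[dt[cand] == min(dt[cand])]
    if (length(best) > 1)
      stop_data("ambiguous match for fix ", fixes$fix_id[i],
                ": observations ",
                paste(observations$obs_id[best], collapse = ", "),
                " are equally near in time")
    idx[i] <- best
  }
  fixes$obs_id <- observations$obs_id[idx]
  fixes$pixel_col <- observations$pixel_col[idx]
  fixes$pixel_row <- observations$pixel_row[idx]
  fixes
}

#' Score estimated positions against GPS ground truth
#'
#' Per-fix horizontal great-circle distance between the photogrammetric
#' estimate and the GPS position, with per-camera minimum / mean / maximum
#' error and an ordinary least-squares test of whether error grows with
#' range (two-sided, alpha = 0.05).
#'
#' @param estimates Output of \code{\link{estimate_position}} for the matched
#'   observations (must contain \code{obs_id}, \code{lat}, \code{lon},
#'   \code{range_m}; rows with status != "ok" are rejected).
#' @param fixes Matched fixes (see \code{\link{match_fixes}}): \code{fix_id},
#'   \code{obs_id}, \code{gps_lat}, \code{gps_lon}, optional
#'   \code{camera_id}.
#' @return Object of class \code{calibration_report}: per-fix table
#'   (\code{fix_id}, \code{camera_id}, \code{range_m}, \code{error_m}),
#'   per-camera summary (min/mean/max, n), and the error-vs-range regression
#'   (slope m per m, correlation, p-value, significance flag).
#' @export
score_calibration <- function(estimates, fixes) {
  m <- merge(fixes, estimates, by = "obs_id", suffixes = c("", ".est"))
  if (nrow(m) < 2) stop_data("fewer than 2 matched calibration fixes")
  bad <- m$status != "ok"
  if (any(bad))
    stop_data("unresolved position estimates for fixes: ",
              paste(m$fix_id[bad], collapse = ", "))
  err <- geosphere::distHaversine(cbind(m$lon, m$lat),
                                  cbind(m$gps_lon, m$gps_lat))
  cam <- m$camera_id %||% rep("camera", nrow(m))
  per_fix <- data.frame(fix_id = m$fix_id, camera_id = cam,
                        range_m = m$range_m, error_m = err,
                        stringsAsFactors = FALSE)
  per_camera <- do.call(rbind, lapply(split(per_fix, per_fix$camera_id),
    function(d) data.frame(camera_id = d$camera_id[1], n = nrow(d),
                           min_error_m = min(d$error_m),
                           mean_error_m = mean(d$error_m),
                           max_error_m = max(d$error_m),
                           stringsAsFactors = FALSE)))
  rownames(per_camera) <- NULL
  fit <- stats::lm(error_m ~ range_m, data = per_fix)
  sm <- summary(fit)
  p <- if (nrow(per_fix) >= 3) sm$coefficients["range_m", "Pr(>|t|)"]
       else NA_real_
  rcor <- if (stats::sd(per_fix$error_m) > 0 && stats::sd(per_fix$range_m) > 0)
    stats::cor(per_fix$range_m, per_fix$error_m) else NA_real_
  trend <- list(slope = unname(stats::coef(fit)["range_m"]),
                correlation = rcor,
                p_value = p,
                significant = isTRUE(p < 0.05))
  structure(list(per_fix = per_fix, per_camera = per_camera,
                 range_trend = trend),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration against GPS fixes\n")
  for (i in seq_len(nrow(x$per_camera))) {
    d <- x$per_camera[i, ]
    cat(sprintf("  %s: n = %d, error %.1f-%.1f m, mean %.1f m\n",
                d$camera_id, d$n, d$min_error_m, d$max_error_m,
                d$mean_error_m))
  }
  tr <- x$range_trend
  cat(sprintf("  error vs range: slope %.4f m/m, r = %.2f, p = %s (%s)\n",
              tr$slope, tr$correlation,
              ifelse(is.na(tr$p_value), "NA", sprintf("%.3f", tr$p_value)),
              if (tr$significant) "significant at 0.05" else "not significant"))
  invisible(x)
}
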