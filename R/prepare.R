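#' Prepare an hourly presence/absence dataset for modelling
#'
#' Two deterministic preparation rules, each logged row by row:
#' \enumerate{
#'   \item Hourly subsample: keep the first (earliest) record of each clock
#'     hour, per camera if a \code{camera_id} column is present.
#'   \item Sparse-level filter: drop records whose level of any filtered
#'     covariate has \code{<= min_level_n} observations, repeating until no
#'     level is sparse (so the operation is idempotent).
#' }
#' Every input row is accounted for: kept + dropped = input.
#'
#' @param records data.frame of hourly records with a POSIXct
#'   \code{timestamp} column and the covariates named in \code{level_vars}.
#' @param min_level_n Levels with this many observations or fewer are
#'   dropped (default 20, i.e. only levels with more than 20 observations
#'   are retained).
#' @param level_vars Covariates whose levels are subject to the sparse-level
#'   filter (default \code{c("glare", "beaufort")}, intersected with the
#'   columns present).
#' @return Object of class \code{prepared_hourly}: list with \code{data}
#'   (retained rows), \code{log} (data.frame \code{row}, \code{stage},
#'   \code{reason} for each dropped row), \code{n_input}, \code{n_kept},
#'   \code{n_dropped}.
#' @export
prepare_hourly <- function(records, min_level_n = 20,
                           level_vars = c("glare", "beaufort")) {
  if (!"timestamp" %in% names(records))
    stop_config("records need a timestamp column")
  level_vars <- intersect(level_vars, names(records))
  n_input <- nrow(records)
  rows <- seq_len(n_input)
  log <- data.frame(row = integer(0), stage = character(0),
                    reason = character(0), stringsAsFactors = FALSE)

  # stage 1: first record of each hour
  lt <- as.POSIXlt(records$timestamp)
  hour_key <- paste(if (!is.null(records$camera_id)) records$camera_id else "",
                    format(records$timestamp, "%Y-%m-%d %H"))
  ord <- order(hour_key, as.numeric(records$timestamp), rows)
  dup <- duplicated(hour_key[ord])
  drop1 <- sort(rows[ord][dup])
  if (length(drop1))
    log <- rbind(log, data.frame(row = drop1, stage = "hourly_subsample",
                                 reason = "not the first record of its hour",
                                 stringsAsFactors = FALSE))
  keep <- setdiff(rows, drop1)

  # stage 2: iterative sparse-level filter
  repeat {
    dropped_any <- FALSE
    for (v in level_vars) {
      vals <- records[[v]][keep]
      tab <- table(vals)
      sparse <- names(tab)[tab <= min_level_n]
      if (length(sparse)) {
        bad <- keep[as.character(vals) %in% sparse]
        log <- rbind(log, data.frame(
          row = bad, stage = "sparse_level_filter",
          reason = paste0(v, " level ", as.character(records[[v]][bad]),
                          " has <= ", min_level_n, " observations"),
          stringsAsFactors = FALSE))
        keep <- setdiff(keep, bad)
        dropped_any <- TRUE
      }
    }
    if (!dropped_any) break
  }
  if (length(keep) == 0)
    stop_data("no records survive preparation")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(data = out, log = log, n_input = n_input,
                 n_kept = length(keep), n_dropped = nrow(log),
                 min_level_n = min_level_n, level_vars = level_vars),
            class = "prepared_hourly")
}

#' @export
print.prepared_hourly <- function(x, ...) {
  cat(sprintf("Prepared hourly dataset: %d of %d records retained (%d dropped)\n",
              x$n_kept, x$n_input, x$n_dropped))
  if (nrow(x$log)) {
    tab <- table(x$log$stage)
    for (s in names(tab)) cat(sprintf("  %s: %d dropped\n", s, tab[[s]]))
  }
  invisible(x)
}

#' Collinearity screen by variance inflation factors
#'
#' VIF_j = 1 / (1 - R_j^2) from the auxiliary linear regression of covariate
#' j on the remaining covariates. Covariates with VIF above the threshold
#' are dropped one at a time (highest first, recomputing after each drop);
#' when several covariates are flagged together, those named in
#' \code{priority} are preferentially retained (e.g. keeping Beaufort over
#' cloud cover when the two are collinear). Perfectly collinear covariates
#' get infinite VIF and are dropped with a warning.
#'
#' @param data data.frame containing the covariates.
#' @param covariates Character vector of >= 2 covariate names.
#' @param vif_threshold Covariates with VIF below this are considered
#'   non-collinear (default 3).
#' @param priority Character vector of covariates to retain preferentially,
#'   most-preferred first.
#' @return Object of class \code{vif_screen}: \code{retained},
#'   \code{dropped} (data.frame \code{covariate}, \code{vif}, \code{step}),
#'   \code{vif} (final VIFs), \code{vif_initial}, \code{correlation}
#'   (pairwise correlation matrix of the input covariates).
#' @export
vif_screen <- function(data, covariates, vif_threshold = 3,
                       priority = character()) {
  if (length(covariates) < 2)
    stop_config("need >= 2 candidate covariates")
  if (!all(covariates %in% names(data)))
    stop_config("covariates not found in data: ",
                paste(setdiff(covariates, names(data)), collapse = ", "))
  X <- data[covariates]
  cormat <- stats::cor(as.data.frame(lapply(X, as.numeric)))
  vars <- vapply(X, function(x) stats::var(as.numeric(x)), numeric(1))
  const <- covariates[vars == 0]
  dropped0 <- data.frame(covariate = const,
                         vif = rep(NA_real_, length(const)),
                         step = rep(0L, length(const)),
                         stringsAsFactors = FALSE)
  if (length(const)) {
    warning("zero-variance covariate(s) dropped: ",
            paste(const, collapse = ", "))
    covariates <- setdiff(covariates, const)
    if (length(covariates) < 2)
      stop_config("fewer than 2 covariates with variation remain")
  }
  vif_of <- function(vars) {
    vapply(vars, function(v) {
      fit <- stats::lm(stats::reformulate(vars[vars != v], response = v),
                       data = data)
      # a perfect fit is expected under exact collinearity; it is reported
      # below as an infinite VIF
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vif0 <- vif_of(covariates)
  retained <- covariates
  dropped <- dropped0
  step <- 0L
  repeat {
    if (length(retained) < 2) break
    v <- vif_of(retained)
    flagged <- retained[v > vif_threshold]
    if (length(flagged) == 0) break
    step <- step + 1L
    # prefer to drop non-priority covariates; among equals, the highest VIF
    pr <- match(flagged, priority)
    ord <- order(!is.na(pr), -v[flagged])
    drop <- flagged[ord][1]
    if (is.infinite(v[drop]))
      warning("perfect collinearity: dropping '", drop,
              "' (infinite VIF)")
    dropped <- rbind(dropped, data.frame(covariate = drop, vif = v[[drop]],
                                         step = step,
                                         stringsAsFactors = FALSE))
    retained <- setdiff(retained, drop)
  }
  vfinal <- if (length(retained) >= 2) vif_of(retained)
            else stats::setNames(rep(NA_real_, length(retained)), retained)
  structure(list(retained = retained, dropped = dropped, vif = vfinal,
                 vif_initial = vif0, correlation = cormat,
                 threshold = vif_threshold),
            class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("Variance-inflation-factor screen (threshold ", x$threshold, ")\n",
      sep = "")
  cat("  initial VIF: ",
      paste(sprintf("%s = %.3g", names(x$vif_initial), x$vif_initial),
            collapse = ", "), "\n", sep = "")
  if (nrow(x$dropped))
    cat("  dropped: ",
        paste(sprintf("%s (VIF %.3g)", x$dropped$covariate, x$dropped$vif),
              collapse = ", "), "\n", sep = "")
  cat("  retained: ", paste(x$retained, collapse = ", "), "\n", sep = "")
  invisible(x)
}
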