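#' Backward model reduction by Wald tests
#'
#' Starting from the full model, repeatedly drops the least-significant
#' droppable term — the one with the highest robust Wald p-value above the
#' significance threshold — and refits, recording each step. A main effect is
#' droppable only once no interaction involving it remains (marginality).
#' If every term is eliminated the intercept-only model is returned with a
#' warning.
#'
#' @param formula Full model formula.
#' @param data,id,waves,family,corstr Passed to \code{\link{gee_ar1}}.
#' @param alpha_level Retention threshold for Wald p-values (default 0.05).
#' @return Object of class \code{gee_reduction}: \code{final} (the final
#'   \code{\link{gee_ar1}} fit), \code{trail} (data.frame \code{step},
#'   \code{term}, \code{wald}, \code{df}, \code{p_value}, \code{action}),
#'   \code{formulas} (per-step formulas).
#' @examples
#' set.seed(42)
#' d <- data.frame(block = rep(1:2, each = 120), hour = rep(1:120, 2),
#'                 glare = rbinom(240, 2, 0.3), beaufort = sample(1:3, 240, TRUE))
#' d$presence <- rbinom(240, 1, plogis(0.3 - 0.6 * d$glare))
#' red <- reduce_model(presence ~ glare * beaufort, d, id = block, waves = hour)
#' red$trail
#' @export
reduce_model <- function(formula, data, id, waves = NULL,
                         family = stats::binomial(), corstr = "ar1",
                         alpha_level = 0.05) {
  id <- resolve_var(substitute(id), data, parent.frame())
  waves <- resolve_var(substitute(waves), data, parent.frame())
  current <- formula
  trail <- data.frame(step = integer(0), term = character(0),
                      wald = numeric(0), df = integer(0),
                      p_value = numeric(0), action = character(0),
                      stringsAsFactors = FALSE)
  formulas <- list(current)
  step <- 0L
  repeat {
    fit <- gee_ar1(current, data, id = id, waves = waves, family = family,
                   corstr = corstr)
    tt <- stats::terms(current)
    labs <- attr(tt, "term.labels")
    if (length(labs) == 0) break
    ord <- attr(tt, "order")
    # droppable: not marginal to any higher-order term still in the model
    droppable <- vapply(seq_along(labs), function(k) {
      parts <- strsplit(labs[k], ":", fixed = TRUE)[[1]]
      !any(vapply(seq_along(labs), function(j) {
        if (j == k || ord[j] <= ord[k]) return(FALSE)
        all(parts %in% strsplit(labs[j], ":", fixed = TRUE)[[1]])
      }, logical(1)))
    }, logical(1))
    tests <- lapply(labs[droppable], function(tm) wald_term(fit, tm))
    pvals <- vapply(tests, `[[`, numeric(1), "p_value")
    worst <- which.max(pvals)
    step <- step + 1L
    if (pvals[worst] <= alpha_level) {
      trail <- rbind(trail, data.frame(
        step = step, term = labs[droppable][worst],
        wald = tests[[worst]]$wald, df = tests[[worst]]$df,
        p_value = pvals[worst], action = "retained (stop)",
        stringsAsFactors = FALSE))
      break
    }
    dropped_term <- labs[droppable][worst]
    trail <- rbind(trail, data.frame(
      step = step, term = dropped_term, wald = tests[[worst]]$wald,
      df = tests[[worst]]$df, p_value = pvals[worst], action = "dropped",
      stringsAsFactors = FALSE))
    current <- stats::update(current,
                             stats::as.formula(paste(". ~ . -", dropped_term)))
    formulas <- c(formulas, current)
    if (length(attr(stats::terms(current), "term.labels")) == 0) {
      warning("all terms eliminated: returning intercept-only model")
      fit <- gee_ar1(current, data, id = id, waves = waves, family = family,
                     corstr = corstr)
      break
    }
  }
  structure(list(final = fit, trail = trail, formulas = formulas,
                 alpha_level = alpha_level),
            class = "gee_reduction")
}

#' @export
print.gee_reduction <- function(x, ...) {
  cat("Backward Wald-test model reduction (alpha = ", x$alpha_level, ")\n",
      sep = "")
  if (nrow(x$trail)) {
    for (i in seq_len(nrow(x$trail)))
      cat(sprintf("  step %d: %s %s (W = %.2f, df = %d, p = %.3f)\n",
                  x$trail$step[i], x$trail$term[i],
                  ifelse(x$trail$action[i] == "dropped", "dropped",
                         "retained - stop"),
                  x$trail$wald[i], x$trail$df[i], x$trail$p_value[i]))
  }
  cat("  final model: ", deparse(x$final$formula), "\n", sep = "")
  invisible(x)
}

#' Time-of-day confounding check for the glare effect
#'
#' Glare is absent in the middle of the day, so a glare effect could mask a
#' diurnal pattern in dolphin transits. This check refits the final model on
#' the records outside a configurable midday window (default 09:00-13:00),
#' i.e. on hours in which glare can be either present or absent, and reports
#' whether the glare term keeps its significance. It also returns jittered
#' presence-over-time and glare-over-time series for visual inspection.
#'
#' @param formula Final model formula (must contain \code{term}).
#' @param data Hourly records with \code{timestamp}, the response and
#'   covariates.
#' @param id,waves,family,corstr Passed to \code{\link{gee_ar1}}; \code{id}
#'   and \code{waves} are column names or vectors aligned with \code{data}.
#' @param exclude_hours Two clock hours \code{c(from, to)}: records with
#'   hour in [from, to) are excluded (default \code{c(9, 13)}).
#' @param term Term whose significance is checked (default "glare").
#' @param alpha_level Significance threshold.
#' @return Object of class \code{confound_check}: \code{fit} (submodel),
#'   \code{term_p}, \code{significant}, \code{n_excluded}, and
#'   \code{plot_data} (timestamp, jittered presence, glare).
#' @export
glare_confound_check <- function(formula, data, id, waves = NULL,
                                 family = stats::binomial(), corstr = "ar1",
                                 exclude_hours = c(9, 13), term = "glare",
                                 alpha_level = 0.05) {
  id <- resolve_var(substitute(id), data, parent.frame())
  waves <- resolve_var(substitute(waves), data, parent.frame())
  hr <- as.POSIXlt(data$timestamp)$hour
  excl <- hr >= exclude_hours[1] & hr < exclude_hours[2]
  keep <- !excl
  if (!any(keep))
    stop_data("excluding hours ", exclude_hours[1], "-", exclude_hours[2],
              " leaves no records")
  sub <- data[keep, , drop = FALSE]
  sid <- if (length(id) == nrow(data)) id[keep] else id
  sw <- if (!is.null(waves) && length(waves) == nrow(data)) waves[keep]
        else waves
  fit <- gee_ar1(formula, sub, id = sid, waves = sw, family = family,
                 corstr = corstr)
  wt <- wald_term(fit, term)
  resp <- all.vars(formula)[1]
  pd <- data.frame(timestamp = data$timestamp,
                   presence_jitter = data[[resp]] +
                     stats::runif(nrow(data), -0.1, 0.1),
                   glare = data[[term]] %||% NA_real_,
                   excluded = excl)
  structure(list(fit = fit, term = term, term_wald = wt$wald,
                 term_p = wt$p_value,
                 significant = wt$p_value < alpha_level,
                 n_excluded = sum(excl), exclude_hours = exclude_hours,
                 plot_data = pd),
            class = "confound_check")
}

#' @export
print.confound_check <- function(x, ...) {
  cat(sprintf("Submodel excluding hours %02d:00-%02d:00 (%d records removed)\n",
              x$exclude_hours[1], x$exclude_hours[2], x$n_excluded))
  cat(sprintf("  %s: W = %.2f, p = %.4f -> %s\n", x$term, x$term_wald,
              x$term_p,
              if (x$significant) "remains significant" else "not significant"))
  invisible(x)
}

#' @export
plot.confound_check <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  pd <- x$plot_data
  graphics::plot(pd$timestamp, pd$presence_jitter, pch = 16, cex = 0.4,
                 col = ifelse(pd$excluded, "grey70", "black"),
                 xlab = "", ylab = "presence (jittered)")
  graphics::plot(pd$timestamp, pd$glare, pch = 16, cex = 0.4,
                 col = ifelse(pd$excluded, "grey70", "black"),
                 xlab = "", ylab = "glare level")
  invisible(x)
}
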