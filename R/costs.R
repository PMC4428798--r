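#' Summarise and compare monitoring cost line items
#'
#' Aggregates line-item costs for the camera-based and field-personnel
#' monitoring methods. Amounts are carried internally in integer cents so
#' totals are exact and order-invariant.
#'
#' @param items data.frame with columns \code{method} ("camera" or
#'   "field"), \code{category} ("gear", "labour" or "expendables"),
#'   \code{label}, \code{amount} (USD, >= 0), and optionally
#'   \code{labour_hours} (>= 0 or NA).
#' @return Object of class \code{cost_comparison}: \code{totals} (per-method
#'   totals, USD), \code{by_category} (per method x category subtotals, with
#'   the field-minus-camera difference and the field/camera ratio where
#'   defined), \code{hours} (per-method total labour hours), \code{items}.
#' @examples
#' summarise_costs(default_cost_items())
#' @export
summarise_costs <- function(items) {
  req <- c("method", "category", "label", "amount")
  if (!all(req %in% names(items)))
    stop_config("cost items need columns ", paste(req, collapse = ", "))
  if (any(!items$method %in% c("camera", "field")))
    stop_config("method must be 'camera' or 'field'")
  if (any(!items$category %in% c("gear", "labour", "expendables")))
    stop_config("category must be gear, labour or expendables")
  if (any(items$amount < 0)) stop_data("negative cost amounts")
  if (!is.null(items$labour_hours) &&
      any(items$labour_hours < 0, na.rm = TRUE))
    stop_data("negative labour hours")
  for (m in c("camera", "field"))
    if (!any(items$method == m))
      stop_data("no line items for method '", m, "'")
  cents <- round(items$amount * 100)
  tot <- tapply(cents, items$method, sum) / 100
  totals <- data.frame(method = names(tot), total_usd = as.numeric(tot),
                       stringsAsFactors = FALSE)
  cats <- c("gear", "labour", "expendables")
  sub <- sapply(c("camera", "field"), function(m) {
    vapply(cats, function(cc)
      sum(cents[items$method == m & items$category == cc]) / 100, numeric(1))
  })
  by_category <- data.frame(
    category = cats,
    camera_usd = sub[, "camera"], field_usd = sub[, "field"],
    difference_usd = sub[, "field"] - sub[, "camera"],
    ratio = ifelse(sub[, "camera"] > 0, sub[, "field"] / sub[, "camera"],
                   NA_real_),
    stringsAsFactors = FALSE)
  hours <- if (is.null(items$labour_hours)) NULL else {
    h <- tapply(items$labour_hours, items$method, sum, na.rm = TRUE)
    data.frame(method = names(h), hours = as.numeric(h),
               stringsAsFactors = FALSE)
  }
  structure(list(totals = totals, by_category = by_category, hours = hours,
                 items = items),
            class = "cost_comparison")
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat("Cost comparison (USD)\n")
  for (m in x$totals$method) {
    cat(sprintf("  %s method: total %s\n", m,
                format(x$totals$total_usd[x$totals$method == m],
                       big.mark = ",")))
    it <- x$items[x$items$method == m, ]
    for (i in seq_len(nrow(it)))
      cat(sprintf("    %-40s %10s\n", it$label[i],
                  format(it$amount[i], big.mark = ",")))
  }
  cat("  largest per-category difference: ",
      x$by_category$category[which.max(abs(x$by_category$difference_usd))],
      sprintf(" (%s USD)\n",
              format(max(abs(x$by_category$difference_usd)),
                     big.mark = ",")), sep = "")
  if (!is.null(x$hours))
    for (m in x$hours$method)
      cat(sprintf("  %s method hours: %s\n", m,
                  format(x$hours$hours[x$hours$method == m])))
  invisible(x)
}

#' Minimum video perusal time at accelerated playback
#'
#' Footage reviewed at an accelerated playback speed takes at least
#' footage_hours / speed_factor, optionally inflated by an overhead fraction
#' for rewinding, pausing and normal-speed re-checks. The whole-hour
#' convenience value rounds half up.
#'
#' @param footage_hours Hours of footage (>= 0).
#' @param speed_factor Playback speed multiple (>= 1; default 1.75, the
#'   fastest speed at which detections are not missed).
#' @param overhead_fraction Fractional overhead added to the raw review time
#'   (default 0).
#' @return list with \code{hours} (exact) and \code{rounded_hours}
#'   (round-half-up whole hours).
#' @examples
#' perusal_time(12)           # 12 h of footage -> 6.857 h, rounds to 7
#' @export
perusal_time <- function(footage_hours, speed_factor = 1.75,
                         overhead_fraction = 0) {
  if (any(speed_factor < 1)) stop("speed_factor must be >= 1")
  if (any(footage_hours < 0)) stop("footage_hours must be >= 0")
  h <- footage_hours / speed_factor * (1 + overhead_fraction)
  list(hours = h, rounded_hours = floor(h + 0.5))
}

#' Example cost line items for a camera vs field-personnel programme
#'
#' The line items bundled with the package (in
#' \code{inst/extdata/cost_items.csv}): gear, labour and expendables for a
#' camera-based monitoring method and for an equivalent field-personnel
#' method, in USD.
#'
#' @return data.frame of cost line items suitable for
#'   \code{\link{summarise_costs}}.
#' @export
default_cost_items <- function() {
  path <- system.file("extdata", "cost_items.csv", package = "harbourcam",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
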