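#' Binomial GEE with AR-1 working correlation
#'
#' Fits a marginal (population-averaged) regression model by generalised
#' estimating equations with an autoregressive working correlation indexed by
#' calendar time: corr(y_s, y_{s-k}) = alpha^k within a grouping block, where
#' the lag k counts elapsed observation periods (so gaps in the record weaken
#' the working correlation accordingly). Intended for hourly presence/absence
#' series where responses close in time are dependent; robust (sandwich)
#' standard errors are reported, so inference does not rely on the working
#' correlation being correct.
#'
#' Estimation alternates Fisher-scoring updates of the regression
#' coefficients with moment estimation of the scale (from squared Pearson
#' residuals) and of alpha (from lag-1 products of Pearson residuals). The
#' AR-1 structure is Markov in calendar time, so each block's working
#' correlation is inverted analytically (tridiagonal precision), keeping the
#' fit linear-time in the number of observations. The fit is deterministic.
#'
#' @param formula Model formula, e.g. \code{presence ~ glare + beaufort}.
#' @param data data.frame containing the model variables, the grouping
#'   variable and the wave variable.
#' @param id Grouping (block) variable: name of a column in \code{data}, or a
#'   vector. Observations are dependent within a block and independent
#'   between blocks.
#' @param waves Integer-valued time index within block (calendar observation
#'   period); name of a column or a vector. Defaults to observation order
#'   within block. Must be unique within block.
#' @param family A \code{\link[stats]{family}} object; default
#'   \code{binomial()} (logit link).
#' @param corstr Working correlation: \code{"ar1"} or \code{"independence"}.
#' @param maxit,tol Iteration control for the coefficient update.
#' @return Object of class \code{gee_ar1} with components
#'   \code{coefficients}, \code{vcov} (robust), \code{vcov_naive},
#'   \code{scale} and \code{scale_se}, \code{alpha} and \code{alpha_se},
#'   \code{fitted.values}, \code{residuals} (Pearson), \code{n},
#'   \code{n_blocks}, \code{converged}, and the usual formula/call metadata.
#' @seealso \code{\link{reduce_model}}, \code{\link{prepare_hourly}},
#'   \code{\link{simulate_hourly_presence}}
#' @examples
#' set.seed(1)
#' d <- data.frame(block = rep(1:2, each = 60), hour = rep(1:60, 2),
#'                 glare = rbinom(120, 1, 0.4))
#' d$presence <- rbinom(120, 1, plogis(0.25 - 0.3 * d$glare))
#' fit <- gee_ar1(presence ~ glare, d, id = block, waves = hour)
#' summary(fit)
#' @export
gee_ar1 <- function(formula, data, id, waves = NULL, family = stats::binomial(),
                    corstr = c("ar1", "independence"), maxit = 50, tol = 1e-8) {
  corstr <- match.arg(corstr)
  cl <- match.call()
  id <- resolve_var(substitute(id), data, parent.frame())
  waves <- resolve_var(substitute(waves), data, parent.frame())
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula), mf)
  n <- length(y)
  if (length(id) != n) stop_data("id length does not match the model frame")
  if (is.null(waves)) waves <- stats::ave(rep(1, n), id, FUN = cumsum)
  if (length(waves) != n) stop_data("waves length does not match the model frame")
  blocks <- split(seq_len(n), id)
  if (length(blocks) < 2 && n < 10)
    stop_data("need >= 2 blocks, or a single block with >= 10 observations")
  for (b in blocks)
    if (anyDuplicated(waves[b]))
      stop_data("waves must be unique within a block")
  # order within block by wave
  blocks <- lapply(blocks, function(b) b[order(waves[b])])
  p <- ncol(X)

  beta <- stats::glm.fit(X, y, family = family)$coefficients
  alpha <- 0; phi <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- family$linkinv(eta)
    A <- family$variance(mu)
    e <- (y - mu) / sqrt(A)
    phi <- sum(e^2) / (n - p)
    if (corstr == "ar1") {
      prod1 <- numeric(0)
      for (b in blocks) {
        if (length(b) < 2) next
        gap <- diff(waves[b])
        adj <- which(gap == 1)
        prod1 <- c(prod1, e[b][adj] * e[b][adj + 1])
      }
      n1 <- length(prod1)
      if (n1 <= p) stop_data("too few lag-1 pairs to estimate alpha")
      alpha <- sum(prod1) / ((n1 - p) * phi)
      alpha <- max(min(alpha, 0.95), -0.95)
    }
    G <- matrix(0, p, p); U <- numeric(p)
    dmu <- family$mu.eta(eta)
    for (b in blocks) {
      Mb <- X[b, , drop = FALSE] * (dmu[b] / sqrt(A[b]))
      sb <- (y[b] - mu[b]) / sqrt(A[b])
      rho <- alpha^diff(waves[b])
      RinvM <- ar1_prec_mult(rho, cbind(Mb, sb))
      G <- G + crossprod(Mb, RinvM[, seq_len(p), drop = FALSE])
      U <- U + drop(crossprod(Mb, RinvM[, p + 1]))
    }
    delta <- solve(G, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 50)
      warning("possible separation: coefficients diverging")
  }
  if (!converged)
    stop(errorCondition(
      paste0("GEE did not converge in ", maxit,
             " iterations (last step ", format(max(abs(delta))), ")"),
      class = c("harbourcam_convergence_error", "error")))

  # final quantities at the solution. The robust (sandwich) variance needs
  # many effectively-independent replication units; with a design of a few
  # long blocks the block-level sandwich has almost no degrees of freedom.
  # Under the calendar-lag AR-1 the working correlation across a recording
  # gap of g periods is alpha^g, so blocks are split into replication
  # segments wherever that correlation is negligible (< 0.05) and the
  # sandwich is accumulated over segments.
  eta <- drop(X %*% beta); mu <- family$linkinv(eta)
  A <- family$variance(mu); dmu <- family$mu.eta(eta)
  e <- (y - mu) / sqrt(A)
  phi <- sum(e^2) / (n - p)
  a_eff <- min(max(abs(alpha), 1e-6), 0.95)
  segments <- list()
  for (b in blocks) {
    gap <- diff(waves[b])
    cut <- c(FALSE, a_eff^gap < 0.05)
    segments <- c(segments, split(b, cumsum(cut)))
  }
  if (length(segments) < 5)
    warning("fewer than 5 replication segments: robust variance unstable")
  G <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (b in segments) {
    Mb <- X[b, , drop = FALSE] * (dmu[b] / sqrt(A[b]))
    sb <- (y[b] - mu[b]) / sqrt(A[b])
    rho <- if (corstr == "ar1") alpha^diff(waves[b]) else rep(0, length(b) - 1)
    RinvM <- ar1_prec_mult(rho, cbind(Mb, sb))
    G <- G + crossprod(Mb, RinvM[, seq_len(p), drop = FALSE])
    u <- drop(crossprod(Mb, RinvM[, p + 1]))
    meat <- meat + tcrossprod(u)
  }
  G <- G / phi; meat <- meat / phi^2
  bread <- solve(G)
  vcov_rob <- bread %*% meat %*% bread
  dimnames(vcov_rob) <- list(colnames(X), colnames(X))
  # moment-based (approximate) standard errors for scale and alpha
  scale_se <- stats::sd(e^2) / sqrt(n)
  alpha_se <- NA_real_
  if (corstr == "ar1") {
    prod1 <- numeric(0)
    for (b in blocks) {
      if (length(b) < 2) next
      adj <- which(diff(waves[b]) == 1)
      prod1 <- c(prod1, e[b][adj] * e[b][adj + 1] / phi)
    }
    alpha_se <- stats::sd(prod1) / sqrt(length(prod1))
  }
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    vcov = vcov_rob, vcov_naive = bread,
    scale = phi, scale_se = scale_se,
    alpha = if (corstr == "ar1") alpha else 0, alpha_se = alpha_se,
    fitted.values = mu, linear.predictors = eta,
    residuals = e, y = y, model.matrix = X,
    id = id, waves = waves, blocks = blocks,
    formula = formula, terms = stats::terms(formula), family = family,
    corstr = corstr, n = n, n_blocks = length(blocks),
    converged = converged, iterations = iter, call = cl,
    data = data
  ), class = "gee_ar1")
}

# name-or-vector resolution for id/waves arguments
resolve_var <- function(expr, data, env) {
  if (is.null(expr) || identical(expr, quote(expr =))) return(NULL)
  v <- tryCatch(eval(expr, data, env), error = function(e) NULL)
  if (is.null(v)) v <- eval(expr, env)
  v
}

# multiply the inverse of a Markov (AR-1, possibly gapped) correlation
# matrix by a matrix M, using the tridiagonal precision of the chain with
# adjacent correlations rho_k (length m - 1)
ar1_prec_mult <- function(rho, M) {
  m <- nrow(M)
  if (m == 1) return(M)
  s2 <- 1 - rho^2
  dg <- c(1, 1 / s2) + c(rho^2 / s2, 0)
  od <- -rho / s2
  out <- dg * M
  out[-m, ] <- out[-m, , drop = FALSE] + od * M[-1, , drop = FALSE]
  out[-1, ] <- out[-1, , drop = FALSE] + od * M[-m, , drop = FALSE]
  out
}

#' @export
coef.gee_ar1 <- function(object, ...) object$coefficients

#' @export
vcov.gee_ar1 <- function(object, ...) object$vcov

#' @export
fitted.gee_ar1 <- function(object, ...) object$fitted.values

#' @export
nobs.gee_ar1 <- function(object, ...) object$n

#' @export
residuals.gee_ar1 <- function(object,
                              type = c("pearson", "response", "link"), ...) {
  type <- match.arg(type)
  switch(type,
         pearson = object$residuals,
         response = object$y - object$fitted.values,
         link = (object$y - object$fitted.values) /
                  object$family$mu.eta(object$linear.predictors))
}

#' @export
predict.gee_ar1 <- function(object, newdata = NULL,
                            type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") object$family$linkinv(eta) else eta
}

#' Wald test for a model term
#'
#' Robust Wald test of the null that all coefficients belonging to one term
#' of the model formula are zero: W = b' V^-1 b against chi-square with as
#' many degrees of freedom as the term has columns.
#'
#' @param object A \code{\link{gee_ar1}} fit.
#' @param term Character name of a term in the model formula.
#' @return list with \code{wald}, \code{df}, \code{p_value}.
#' @export
wald_term <- function(object, term) {
  labs <- attr(object$terms, "term.labels")
  k <- match(term, labs)
  if (is.na(k)) stop_data("term '", term, "' not in the model")
  idx <- which(attr(object$model.matrix, "assign") == k)
  b <- object$coefficients[idx]
  W <- drop(t(b) %*% solve(object$vcov[idx, idx, drop = FALSE]) %*% b)
  list(wald = W, df = length(idx),
       p_value = stats::pchisq(W, df = length(idx), lower.tail = FALSE))
}

#' @export
print.gee_ar1 <- function(x, ...) {
  cat("AR-1 binomial GEE", if (x$corstr == "independence")
      "(independence working correlation)", "\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("  n = %d in %d block(s); scale %.3f; alpha %.3f\n",
              x$n, x$n_blocks, x$scale, x$alpha))
  invisible(x)
}

#' @export
summary.gee_ar1 <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  wald <- (object$coefficients / se)^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  coefs <- cbind(Estimate = object$coefficients, `Std.err` = se,
                 Wald = wald, `Pr(>|W|)` = p)
  structure(list(call = object$call, coefficients = coefs,
                 scale = object$scale, scale_se = object$scale_se,
                 alpha = object$alpha, alpha_se = object$alpha_se,
                 corstr = object$corstr, n = object$n,
                 n_blocks = object$n_blocks),
            class = "summary.gee_ar1")
}

#' @export
print.summary.gee_ar1 <- function(x, ...) {
  cat("Call:\n"); print(x$call)
  cat("\nCoefficients (robust SEs):\n")
  stats::printCoefmat(x$coefficients, digits = 4, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nEstimated Scale Parameter: %.4g (SE %.3g)\n",
              x$scale, x$scale_se))
  if (x$corstr == "ar1")
    cat(sprintf("Estimated Correlation Parameter (alpha): %.4g (SE %.3g)\n",
                x$alpha, x$alpha_se))
  cat(sprintf("Number of observations: %d in %d block(s)\n", x$n, x$n_blocks))
  invisible(x)
}

#' @export
#' @importFrom stats simulate
simulate.gee_ar1 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted.values
  out <- matrix(0L, object$n, nsim)
  rho <- latent_ar1_rho(object$alpha, mean(p))
  for (s in seq_len(nsim)) {
    for (b in object$blocks) {
      z <- latent_ar1_series(rho, diff(object$waves[b]))
      out[b, s] <- as.integer(stats::pnorm(z) < p[b])
    }
  }
  as.data.frame(out)
}
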