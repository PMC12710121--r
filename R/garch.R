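#' Autoregressive prewhitening of a tremor series
#'
#' Fits AR models of order 1..`max_order` by Yule-Walker and selects the
#' order minimising AIC; returns the chosen order, its coefficients, and
#' the prediction residuals. This is the "ar" stage feeding the GARCH(1,1)
#' residual-distribution feature.
#'
#' @param x Numeric series (finite).
#' @param max_order Maximum AR order considered (default 8).
#' @return List with `order`, `coefficients`, `residuals` (leading
#'   `order` samples dropped), `aic` (named vector over candidate orders).
#' @export
fit_ar_residuals <- function(x, max_order = 8) {
  if (any(!is.finite(x))) stop("non-finite samples", call. = FALSE)
  n <- length(x)
  if (n <= 10 * max_order)
    stop(sprintf("series too short (%d) for AR order up to %d", n, max_order),
         call. = FALSE)
  aic <- setNames(numeric(max_order), seq_len(max_order))
  fits <- vector("list", max_order)
  for (p in seq_len(max_order)) {
    fits[[p]] <- ar(x, aic = FALSE, order.max = p, method = "yule-walker")
    aic[p] <- n * log(fits[[p]]$var.pred) + 2 * p
  }
  best <- which.min(aic)
  fit <- fits[[best]]
  res <- as.numeric(fit$resid)
  res <- res[!is.na(res)]
  list(order = best, coefficients = as.numeric(fit$ar),
       residuals = res - mean(res), aic = aic)
}

#' Fit a GARCH(1,1) model by Gaussian quasi-maximum likelihood
#'
#' Estimates the conditional-variance recursion
#' `sigma2[t] = omega + alpha1 * e[t-1]^2 + beta1 * sigma2[t-1]`
#' for zero-mean residuals `e` by numerical QML (Nelder-Mead on
#' log-parameters, multiple deterministic starts, stationarity constraint
#' `alpha1 + beta1 < 1`). The residuals are internally scaled to unit
#' variance before fitting, which leaves the standardised residuals
#' `e[t]/sigma[t]` exactly invariant to any positive rescaling of the
#' input; `omega` is reported back on the input scale.
#'
#' @param e Numeric residual series, approximately zero-mean, length >= 300.
#' @return A `garch_fit` list: `omega`, `alpha1`, `beta1`,
#'   `standardized_residuals`, `log_likelihood`, `converged`.
#' @export
fit_garch11 <- function(e) {
  n <- length(e)
  if (n < 300) stop("need at least 300 residuals for GARCH(1,1)", call. = FALSE)
  s <- sd(e)
  if (!is.finite(s) || s == 0) stop("zero-variance input", call. = FALSE)
  z <- (e - mean(e)) / s
  z2 <- z^2

  negll <- function(theta) {
    w <- exp(theta[1]); a <- exp(theta[2]); b <- exp(theta[3])
    if (a + b > 0.9995 || w > 100) return(1e10)
    s2 <- garch11_sigma2(z2, w, a, b)
    if (any(s2 <= 0) || any(!is.finite(s2))) return(1e10)
    0.5 * sum(log(2 * pi) + log(s2) + z2 / s2)
  }

  starts <- list(c(0.05, 0.05, 0.90), c(0.10, 0.10, 0.80),
                 c(0.30, 0.10, 0.50), c(0.90, 0.05, 0.05))
  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      optim(log(st), negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e9) {
    return(structure(list(omega = NA_real_, alpha1 = NA_real_,
                          beta1 = NA_real_, standardized_residuals = NULL,
                          log_likelihood = NA_real_, converged = FALSE),
                     class = "garch_fit"))
  }
  w <- exp(best$par[1]); a <- exp(best$par[2]); b <- exp(best$par[3])
  s2 <- garch11_sigma2(z2, w, a, b)
  structure(list(
    omega = w * s^2, alpha1 = a, beta1 = b,
    standardized_residuals = z / sqrt(s2),
    log_likelihood = -best$value,
    converged = best$convergence == 0
  ), class = "garch_fit")
}

# sigma^2 recursion, vectorised through the linear recursive filter
# y_t = x_t + b * y_{t-1}; sigma2_1 is set to the unconditional variance.
garch11_sigma2 <- function(z2, w, a, b) {
  n <- length(z2)
  s2_1 <- mean(z2)
  rest <- stats::filter(w + a * z2[-n], filter = b, method = "recursive",
                        init = s2_1)
  c(s2_1, as.numeric(rest))
}

#' @export
print.garch_fit <- function(x, ...) {
  cat(sprintf("<garch_fit> omega=%.4g alpha1=%.3f beta1=%.3f (logLik %.2f, %s)\n",
              x$omega, x$alpha1, x$beta1, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' GARCH-residual normality feature
#'
#' The waveform-asymmetry feature separating PD from ET tremor: the series
#' is AR-prewhitened ([fit_ar_residuals()]), a GARCH(1,1) model is fitted to
#' the residuals ([fit_garch11()]), and the Kolmogorov-Smirnov statistic of
#' the standardised residuals against a standard normal distribution is
#' returned. Larger values mean a less Gaussian (e.g. skewed) residual
#' distribution, as produced by asymmetric harmonic content; the feature is
#' invariant to positive amplitude rescaling of the input.
#'
#' @param x A `preprocessed_series` or numeric vector.
#' @param max_order Maximum AR order (default 8).
#' @return KS statistic in `[0, 1]`, or `NA` with attribute `reason` when
#'   the GARCH fit does not converge.
#' @export
garch_ks_feature <- function(x, max_order = 8) {
  if (inherits(x, "preprocessed_series")) x <- x$samples
  arf <- fit_ar_residuals(x, max_order)
  g <- fit_garch11(arf$residuals)
  if (!g$converged || is.null(g$standardized_residuals))
    return(structure(NA_real_, reason = "garch_nonconvergence"))
  unname(suppressWarnings(
    ks.test(g$standardized_residuals, "pnorm")$statistic))
}
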