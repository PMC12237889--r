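#' Segmented (broken-stick) regression with profiled breakpoint
#'
#' Fits the continuous two-segment model
#' `y = a + b * x + c * max(0, x - psi)` by exhaustive profiling: every
#' interior observed `x` value with at least `min_seg` points on each side
#' is a candidate breakpoint; for each candidate an OLS fit in
#' `(x, max(0, x - psi))` is evaluated and the candidate with minimal
#' residual sum of squares wins (SSE ties broken by the smallest `psi`).
#' The search is deterministic and global — no starting values.
#'
#' The fit is compared against the single-line model by AIC, charging the
#' segmented model one extra parameter for the profiled breakpoint.  A
#' change point is flagged "significant" when `Delta AIC > 2` in favour of
#' the segmented model and the overall F-test p-value is below 0.05; data
#' that are already exactly linear are flagged as having no change point.
#'
#' @param x numeric driver vector (non-constant).
#' @param y numeric response vector.
#' @param min_seg minimum observations on each side of the breakpoint.
#' @return object of class `segmented_fit` with components `psi`,
#'   `intercept`, `slope_left`, `slope_right`, `r_squared`, `p_value`, `n`,
#'   `delta_aic`, `significant`, `no_change_point`, `r_squared_linear`,
#'   `candidates`, `model` (the underlying `lm`), `data`.
#' @examples
#' d <- simulate_piecewise_response(60, psi_true = 5, slopes = c(2, -1),
#'                                  noise_sd = 0, seed = 7)
#' f <- segmented_fit(d$x, d$y)
#' coef(f)
#' @export
segmented_fit <- function(x, y, min_seg = 3) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 * min_seg) stop("need at least 2 * min_seg observations")
  if (var(x) == 0) stop("x is constant")
  xs <- sort(unique(x))
  cand <- xs[vapply(xs, function(p)
    sum(x <= p) >= min_seg && sum(x > p) >= min_seg, TRUE)]
  if (!length(cand)) stop("insufficient interior points for any breakpoint")

  lin <- lm(y ~ x)
  sse_lin <- sum(residuals(lin)^2)

  sse <- vapply(cand, function(p) {
    h <- pmax(0, x - p)
    f <- lm.fit(cbind(1, x, h), y)
    sum(f$residuals^2)
  }, 0)
  best <- which(sse <= min(sse) + 1e-12)[1]  # ties -> smallest psi
  psi <- cand[best]
  h <- pmax(0, x - psi)
  fit <- lm(y ~ x + h)
  sse_seg <- sum(residuals(fit)^2)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0

  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse_seg / sst else 0
  r2_lin <- if (sst > 0) 1 - sse_lin / sst else 0
  # overall F-test p of the segmented model (perfect fits handled explicitly)
  p_value <- if (sst <= 0) 1
  else if (sse_seg <= 1e-12 * max(1, sst)) 0
  else {
    fs <- summary(fit)$fstatistic
    if (is.null(fs)) 1 else unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }

  # Gaussian AIC; the profiled breakpoint costs one parameter on top of lm's
  aic_of <- function(sse, k) {
    if (sse <= 1e-12 * max(1, sst)) return(-Inf)
    n * log(sse / n) + 2 * k
  }
  perfectly_linear <- sse_lin <= 1e-12 * max(1, sst)
  if (perfectly_linear) {
    delta_aic <- NA_real_
    no_cp <- TRUE
  } else {
    delta_aic <- aic_of(sse_lin, 3) - (aic_of(sse_seg, 4) + 2)
    no_cp <- is.finite(delta_aic) && delta_aic <= 0
  }
  significant <- !no_cp && !is.na(delta_aic) &&
    (is.infinite(delta_aic) || delta_aic > 2) && p_value < 0.05

  structure(list(psi = psi,
                 intercept = unname(cf[1]),
                 slope_left = unname(cf[2]),
                 slope_right = unname(cf[2] + cf[3]),
                 r_squared = r2, p_value = p_value, n = n,
                 delta_aic = delta_aic, significant = significant,
                 no_change_point = no_cp,
                 r_squared_linear = r2_lin,
                 candidates = cand, model = fit,
                 data = data.frame(x = x, y = y)),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented regression (continuous broken-stick)\n")
  cat(sprintf("  breakpoint psi = %.6g  (n = %d, %d candidates)\n",
              x$psi, x$n, length(x$candidates)))
  cat(sprintf("  slopes: left %.6g, right %.6g; intercept %.6g\n",
              x$slope_left, x$slope_right, x$intercept))
  cat(sprintf("  r^2 = %.4f (linear fit: %.4f), p = %.4g, delta AIC = %s\n",
              x$r_squared, x$r_squared_linear, x$p_value,
              if (is.na(x$delta_aic)) "NA" else sprintf("%.2f", x$delta_aic)))
  if (x$no_change_point) cat("  flagged: no change point (linear model preferred)\n")
  else cat(sprintf("  change point %s\n",
                   if (x$significant) "significant (delta AIC > 2, p < 0.05)"
                   else "not significant"))
  invisible(x)
}

#' @export
summary.segmented_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model at the selected breakpoint:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.segmented_fit <- function(object, ...) {
  c(intercept = object$intercept, slope_left = object$slope_left,
    slope_right = object$slope_right, psi = object$psi)
}

#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  object$intercept + object$slope_left * x +
    (object$slope_right - object$slope_left) * pmax(0, x - object$psi)
}

#' @export
residuals.segmented_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
fitted.segmented_fit <- function(object, ...) predict(object)

#' @export
plot.segmented_fit <- function(x, ...) {
  ord <- order(x$data$x)
  plot(x$data$x, x$data$y, xlab = "driver", ylab = "response", ...)
  graphics::lines(x$data$x[ord], predict(x)[ord], col = "red", lwd = 2)
  abline(v = x$psi, lty = 2, col = "grey40")
  invisible(x)
}
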