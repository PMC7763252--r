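#' Accumulated generating operation (1-AGO)
#'
#' The running sum `x1[k] = x1[k-1] + x0[k]` that turns a noisy positive
#' series into a quasi-exponential one; the starting point of every GM(1,1)
#' fit. [iago()] is its exact inverse (first differencing keeping the first
#' element).
#'
#' @param x numeric vector.
#' @return Cumulative-sum vector of the same length.
#' @export
ago <- function(x) {
  if (length(x) == 0) stop("empty series")
  cumsum(x)
}

#' Inverse accumulated generating operation
#' @param x1 numeric vector (a 1-AGO series).
#' @return The differenced series, same length; `iago(ago(x))` equals `x`.
#' @export
iago <- function(x1) {
  if (length(x1) == 0) stop("empty series")
  c(x1[1], diff(x1))
}

#' Adjacent-pair mean sequence of a 1-AGO series
#'
#' `z[k] = 0.5 * x1[k] + 0.5 * x1[k-1]` for `k = 2..n`; the background value
#' against which the grey difference equation is linear.
#'
#' @param x1 numeric vector of length at least 2.
#' @return Vector of length `length(x1) - 1`.
#' @export
mean_sequence <- function(x1) {
  n <- length(x1)
  if (n < 2) stop("mean sequence needs at least 2 values")
  0.5 * (x1[-1] + x1[-n])
}

#' Fit a GM(1,1) grey model
#'
#' Fits the grey difference equation `x0[k] + a * z[k] = b` (k = 2..n) by
#' ordinary least squares on the design matrix with rows `(-z[k], 1)`, where
#' `z` is the adjacent-pair mean of the 1-AGO series. `a` is the development
#' coefficient (negative for a growing series) and `b` the grey input. The
#' time-response function of the whitened differential equation is
#' `x1hat(k+1) = (x0[1] - b/a) * exp(-a*k) + b/a`, and fitted values on the
#' original scale are recovered by [restore_fitted()]; the difference
#' (inverse-AGO) restoration is the default.
#'
#' @param x positive numeric series, length >= 4.
#' @param years optional integer year labels (defaults to `1..n`).
#' @param restore in-sample restoration method, `"difference"` (default) or
#'   `"derivative"`; see [restore_fitted()].
#' @return An object of class `"gm11"`: a list with elements `x0`, `years`,
#'   `x1`, `z`, `a`, `b`, `c1` (`= x0[1] - b/a`), `c0` (`= b/a`), `fitted`,
#'   `residuals`, `restore`.
#' @examples
#' fit <- gm11(c(0.19, 0.29, 0.35, 0.58, 0.72, 0.78, 0.80, 0.88))
#' fit$a
#' @export
gm11 <- function(x, years = NULL, restore = c("difference", "derivative")) {
  restore <- match.arg(restore)
  n <- length(x)
  if (n < 4) stop("GM(1,1) needs at least 4 observations, got ", n)
  if (any(!is.finite(x))) stop("series has non-finite values")
  if (any(x <= 0)) stop("GM(1,1) requires a strictly positive series")
  if (is.null(years)) years <- seq_len(n)
  if (length(years) != n) stop("years must match the series length")
  x1 <- ago(x)
  z <- mean_sequence(x1)
  if (max(z) - min(z) < .Machine$double.eps * max(abs(z)))
    stop("degenerate fit: mean sequence is constant")
  B <- cbind(a = -z, b = 1)
  sol <- stats::lm.fit(B, x[-1])
  a <- unname(sol$coefficients["a"])
  b <- unname(sol$coefficients["b"])
  fit <- structure(list(x0 = x, years = years, x1 = x1, z = z, a = a, b = b,
                        c1 = x[1] - b / a, c0 = b / a, restore = restore),
                   class = "gm11")
  fit$fitted <- restore_fitted(fit, restore)
  fit$residuals <- x - fit$fitted
  fit
}

# time-response values x1hat(k) at 1-based indices k (k = 1 gives x0[1])
time_response <- function(fit, k) {
  fit$c1 * exp(-fit$a * (k - 1)) + fit$c0
}

#' Restore fitted values on the original scale
#'
#' Two equivalent-in-spirit restorations of the time-response curve:
#' `"difference"` takes successive differences of `x1hat` (exact inverse
#' AGO), `"derivative"` evaluates `-a * (x0[1] - b/a) * exp(-a*(k-1))`, the
#' derivative of the whitened solution. Both pin `fitted[1] = x0[1]`.
#'
#' @param fit a `"gm11"` object.
#' @param method `"difference"` or `"derivative"`.
#' @return Numeric vector of fitted values, same length as the input series.
#' @export
restore_fitted <- function(fit, method = c("difference", "derivative")) {
  method <- match.arg(method)
  n <- length(fit$x0)
  k <- seq_len(n)
  out <- if (method == "difference") iago(time_response(fit, k))
         else c(fit$x0[1], -fit$a * fit$c1 * exp(-fit$a * (k[-n]))[seq_len(n - 1)])
  out[1] <- fit$x0[1]
  out
}

#' Forecast future values from a GM(1,1) fit
#'
#' Continues the restored sequence beyond the sample. The default
#' `"derivative"` method evaluates the prediction formula
#' `x0hat(k+1) = -a * (x0[1] - b/a) * exp(-a*k)`; `"difference"` differences
#' the time-response curve instead. Forecasts of a bounded index may exceed
#' 1; they are reported unclamped (grading clamps, with a warning).
#'
#' @param object a `"gm11"` object.
#' @param horizon number of steps ahead (>= 0); 0 gives an empty forecast.
#' @param method `"derivative"` (default) or `"difference"`.
#' @param ... unused.
#' @return Data frame with columns `year`, `k` (1-based time index) and
#'   `predicted`.
#' @export
predict.gm11 <- function(object, horizon = 3,
                         method = c("derivative", "difference"), ...) {
  method <- match.arg(method)
  if (length(horizon) != 1 || is.na(horizon) || horizon < 0)
    stop("horizon must be a non-negative integer")
  horizon <- as.integer(horizon)
  n <- length(object$x0)
  k <- seq_len(horizon) + n          # forecast indices n+1 .. n+horizon
  pred <- if (horizon == 0) numeric(0)
          else if (method == "derivative")
            -object$a * object$c1 * exp(-object$a * (k - 1))
          else time_response(object, k) - time_response(object, k - 1)
  data.frame(year = object$years[n] + seq_len(horizon), k = k,
             predicted = pred)
}

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey model, n =", length(x$x0), "\n")
  cat(sprintf("  development coefficient a = %.6f\n", x$a))
  cat(sprintf("  grey input             b = %.8f\n", x$b))
  cat(sprintf("  time response: x1hat(k+1) = %.7f * exp(%.6f k) %+.7f\n",
              x$c1, -x$a, x$c0))
  cat("  restore method:", x$restore, "\n")
  invisible(x)
}

#' Serialize a GM(1,1) fit (observed, fitted, residuals) to CSV
#' @param fit a `"gm11"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gm11 <- function(fit, path) {
  utils::write.csv(
    data.frame(year = fit$years, observed = fit$x0, fitted = fit$fitted,
               residual = fit$residuals,
               relative_error = abs(fit$residuals) / fit$x0),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
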