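#' Residual, absolute-error and relative-error series of a grey fit
#'
#' `residual[k] = observed[k] - fitted[k]`, `abs_error = |residual|`,
#' `relative_error = abs_error / observed` (a fraction). Because the fit pins
#' `fitted[1] = observed[1]`, the first residual is structurally zero; all
#' summary statistics therefore run over `k = 2..n`.
#'
#' @param observed positive numeric series.
#' @param fitted fitted values, same length, with `fitted[1] == observed[1]`.
#' @return List with vectors `residuals`, `abs_errors`, `relative_errors` and
#'   scalars `mean_rel_err`, `max_rel_err` (fractions, over `k = 2..n`).
#' @export
residual_stats <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("observed and fitted lengths differ")
  if (abs(fitted[1] - observed[1]) > 1e-12)
    stop("fitted[1] must equal observed[1] (boundary condition)")
  res <- observed - fitted
  abs_err <- abs(res)
  rel <- abs_err / observed
  list(residuals = res, abs_errors = abs_err, relative_errors = rel,
       mean_rel_err = mean(rel[-1]), max_rel_err = max(rel[-1]))
}

#' Posterior-error test of a grey fit
#'
#' The posterior-error ratio is `C = S2 / S1` with `S1` the population
#' standard deviation of the observed series and `S2` that of the residuals,
#' both over `k = 2..n` (the first residual is structurally zero and is
#' excluded). The small-error probability `p` is the fraction of residuals
#' within `0.6745 * S1` of their mean. Smaller `C` and larger `p` mean a
#' better fit.
#'
#' @param observed positive numeric series.
#' @param residuals residual series from [residual_stats()], same length.
#' @return List with `C`, `p`, `S1`, `S2`.
#' @export
posterior_error_test <- function(observed, residuals) {
  n <- length(observed)
  if (length(residuals) != n) stop("observed and residuals lengths differ")
  if (n - 1 < 3) stop("posterior-error test needs at least 3 residual points")
  x <- observed[-1]
  e <- residuals[-1]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  S1 <- pop_sd(x)
  if (S1 == 0) stop("degenerate: observed series is constant over k = 2..n")
  S2 <- pop_sd(e)
  list(C = S2 / S1, p = mean(abs(e - mean(e)) < 0.6745 * S1), S1 = S1, S2 = S2)
}

#' Stage-ratio deviation of a series against a development coefficient
#'
#' For the class ratios `lambda[k] = x[k-1] / x[k]`, a series exactly
#' obeying the grey difference equation with development coefficient `a` has
#' `lambda[k] = (1 + 0.5 a) / (1 - 0.5 a)` for all k, so the deviations
#' `rho[k] = |1 - lambda[k] * (1 - 0.5 a) / (1 + 0.5 a)|` measure how far the
#' series departs from grey-model form. A maximum below 0.2 is the customary
#' applicability threshold; it is computed and reported, never enforced as a
#' fitting pre-check.
#'
#' @param observed positive numeric series, length >= 2.
#' @param a development coefficient (`a != -2`).
#' @return List with vector `rho` (length `n - 1`) and scalars `mean_rho`,
#'   `max_rho`, and logical `ratio_ok` (`max_rho < 0.2`).
#' @export
stage_ratio_deviation <- function(observed, a) {
  n <- length(observed)
  if (n < 2) stop("stage-ratio deviation needs at least 2 values")
  if (any(observed <= 0)) stop("series must be strictly positive")
  if (abs(1 + 0.5 * a) < .Machine$double.eps)
    stop("a = -2 makes the smoothing factor undefined")
  lambda <- observed[-n] / observed[-1]
  rho <- abs(1 - lambda * (1 - 0.5 * a) / (1 + 0.5 * a))
  list(rho = rho, mean_rho = mean(rho), max_rho = max(rho),
       ratio_ok = max(rho) < 0.2)
}

#' Accuracy bands for the posterior-error test
#'
#' `p`: Excellent `>= 0.95`, Good `[0.80, 0.95)`, Accepted `[0.70, 0.80)`,
#' Failed `< 0.70`. `C`: Excellent `<= 0.35`, Good `(0.35, 0.50]`, Accepted
#' `(0.50, 0.65]`, Failed `> 0.65`.
#'
#' @param p small-error probability.
#' @param C posterior-error ratio.
#' @return Character vector `c(grade_p, grade_C)`.
#' @export
accuracy_bands <- function(p, C) {
  gp <- if (p >= 0.95) "Excellent" else if (p >= 0.80) "Good"
        else if (p >= 0.70) "Accepted" else "Failed"
  gc <- if (C <= 0.35) "Excellent" else if (C <= 0.50) "Good"
        else if (C <= 0.65) "Accepted" else "Failed"
  c(grade_p = gp, grade_C = gc)
}

#' Overall accuracy verdict of a grey fit
#'
#' Grades `p` and `C` separately via [accuracy_bands()] and returns the worse
#' of the two as the overall verdict. The residual-side checks — mean
#' relative error below 20% and maximum stage-ratio deviation below 0.2 — are
#' reported as pass/fail flags alongside, not folded into the verdict.
#'
#' @param C posterior-error ratio.
#' @param p small-error probability.
#' @param relative_errors relative-error series (fractions) from
#'   [residual_stats()].
#' @param rho stage-ratio deviation series from [stage_ratio_deviation()].
#' @return List with `verdict`, `grade_p`, `grade_C`, `residual_ok`,
#'   `ratio_ok`.
#' @export
accuracy_verdict <- function(C, p, relative_errors, rho) {
  bands <- accuracy_bands(p, C)
  order_ <- c(Excellent = 1, Good = 2, Accepted = 3, Failed = 4)
  verdict <- names(order_)[max(order_[bands])]
  list(verdict = verdict, grade_p = unname(bands["grade_p"]),
       grade_C = unname(bands["grade_C"]),
       residual_ok = mean(relative_errors[-1]) < 0.20,
       ratio_ok = max(rho) < 0.2)
}

#' Full double accuracy test of a GM(1,1) fit
#'
#' Combines the residual test (relative errors), the posterior-error test
#' (C and p) and the stage-ratio check into one report with the overall
#' verdict.
#'
#' @param fit a `"gm11"` object.
#' @return Object of class `"gm11_diagnostics"`: a list with all statistics
#'   from [residual_stats()], [posterior_error_test()],
#'   [stage_ratio_deviation()] and [accuracy_verdict()], plus `a`, `b`.
#' @examples
#' fit <- gm11(c(0.19, 0.29, 0.35, 0.58, 0.72, 0.78, 0.80, 0.88))
#' diagnose(fit)
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "gm11"))
  rs <- residual_stats(fit$x0, fit$fitted)
  pe <- posterior_error_test(fit$x0, rs$residuals)
  sr <- stage_ratio_deviation(fit$x0, fit$a)
  vd <- accuracy_verdict(pe$C, pe$p, rs$relative_errors, sr$rho)
  structure(c(list(a = fit$a, b = fit$b), rs, pe, sr, vd),
            class = "gm11_diagnostics")
}

#' @export
print.gm11_diagnostics <- function(x, ...) {
  cat("GM(1,1) double accuracy test\n")
  cat(sprintf("  posterior error ratio C = %.4f (%s)\n", x$C, x$grade_C))
  cat(sprintf("  small-error probability p = %.4f (%s)\n", x$p, x$grade_p))
  cat(sprintf("  mean relative error = %.2f%% (max %.2f%%) [%s]\n",
              100 * x$mean_rel_err, 100 * x$max_rel_err,
              if (x$residual_ok) "pass" else "fail"))
  cat(sprintf("  stage-ratio deviation: mean %.4f, max %.4f [%s]\n",
              x$mean_rho, x$max_rho, if (x$ratio_ok) "pass" else "fail"))
  cat("  overall verdict:", x$verdict, "\n")
  invisible(x)
}

#' One-row summary of a diagnostics report
#' @param report a `"gm11_diagnostics"` object.
#' @param region optional region label for the row.
#' @return One-row data frame suitable for rbind-ing across regions.
#' @export
diagnostics_row <- function(report, region = NA_character_) {
  data.frame(region = region, a = report$a, b = report$b, C = report$C,
             p = report$p,
             mean_rel_err_pct = 100 * report$mean_rel_err,
             max_rel_err_pct = 100 * report$max_rel_err,
             mean_rho = report$mean_rho, max_rho = report$max_rho,
             grade_C = report$grade_C, grade_p = report$grade_p,
             verdict = report$verdict, stringsAsFactors = FALSE)
}
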