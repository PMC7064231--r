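#' Adjusted coefficient of determination
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - k - 1)}, penalising the
#' plain (pseudo-)R-squared for the number of independent variables.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of samples.
#' @param k Number of independent variables in the model.
#' @return The adjusted R-squared.
#' @examples
#' r2_adjusted(0.98, 9, 4) # 0.96
#' @export
r2_adjusted <- function(r2, n, k) {
  if (n <= k + 1) stop("r2_adjusted undefined: need n > k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Root mean square error (population form)
#'
#' \eqn{RMSE = \sqrt{\sum e^2 / n}} with divisor `n` (not `n - k`).
#'
#' @param residuals Numeric vector of residuals (response units, kg).
#' @return The RMSE in the residual units.
#' @examples
#' rmse(c(3, 4)) # sqrt(12.5)
#' @export
rmse <- function(residuals) {
  if (!length(residuals)) stop("empty residual vector")
  sqrt(sum(residuals^2) / length(residuals))
}

#' Mean percentage error
#'
#' \eqn{MPE = \frac{\sum e / n}{\bar{M}_{obs}} \times 100} with
#' \eqn{e = \hat{y} - y}, so negative values indicate underestimation and
#' positive values overestimation.
#'
#' @param observed,predicted Numeric vectors of equal length; the mean of
#'   `observed` must be non-zero.
#' @return The mean percentage error, in percent.
#' @examples
#' mpe(c(10, 10), c(9, 9)) # -10
#' @export
mpe <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  m_obs <- mean(observed)
  if (m_obs == 0) stop("mean of observed values is zero; MPE undefined")
  e <- predicted - observed
  (sum(e) / length(e)) / m_obs * 100
}

#' Akaike's information criterion from a residual sum of squares
#'
#' \eqn{AIC = n \ln(\sum e^2 / n) + 2(k + 1) + c}. The additive constant
#' `c` is rank-invariant within a candidate set and defaults to 0.
#' A perfect fit (`sse = 0`) returns `-Inf` with a warning.
#'
#' @param sse Sum of squared residuals (kg^2), non-negative.
#' @param n Number of samples.
#' @param k Number of independent variables.
#' @param c Additive constant (default 0).
#' @return The AIC value.
#' @examples
#' aic_sse(2.5, 5, 2) # 5*log(0.5) + 6
#' @export
aic_sse <- function(sse, n, k, c = 0) {
  if (n < 1) stop("n must be at least 1")
  if (sse < 0) stop("sse must be non-negative")
  if (sse == 0) {
    warning("sse is zero (perfect fit); AIC is -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * (k + 1) + c
}

#' Fit metrics for an allometric model
#'
#' Bundles the four selection criteria (adjusted R-squared, RMSE, MPE,
#' AIC) plus the quantities they derive from. R-squared for nonlinear
#' fits is the pseudo form \eqn{1 - SSE/SS_{tot}} about the observed
#' mean.
#'
#' @param observed,predicted Numeric vectors of observed and fitted
#'   responses (kg).
#' @param k Number of independent variables in the model.
#' @param aic_c Additive AIC constant (default 0).
#' @return An object of class `fit_metrics`: a list with `n`, `k`,
#'   `sse`, `r2`, `r2_adj`, `rmse`, `mpe_pct`, `aic` and a `data_id`
#'   fingerprint of the observed responses used to detect mixed-dataset
#'   model comparisons.
#' @export
fit_metrics <- function(observed, predicted, k, aic_c = 0) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed/predicted length mismatch")
  e <- observed - predicted
  sse <- sum(e^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - sse / ss_tot else NA_real_
  structure(
    list(
      n = n, k = k, sse = sse, r2 = r2,
      r2_adj = if (n > k + 1 && is.finite(r2)) r2_adjusted(r2, n, k) else NA_real_,
      rmse = rmse(e),
      mpe_pct = mpe(observed, predicted),
      aic = suppressWarnings(aic_sse(sse, n, k, aic_c)),
      data_id = c(n = n, sum = sum(observed), ssq = sum(observed^2))
    ),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf(
    "Fit metrics: n=%d k=%d R2=%.4f R2adj=%.4f RMSE=%.4g MPE=%.3g%% AIC=%.4g\n",
    x$n, x$k, x$r2, x$r2_adj, x$rmse, x$mpe_pct, x$aic))
  invisible(x)
}
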