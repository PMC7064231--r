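#' Construct an allometric model object
#'
#' The four functional forms used for scrub-mangrove biomass estimation:
#'
#' * `POWER`: \eqn{y = a x^b}, one predictor, coefficients `(a, b)`.
#' * `QUADRATIC`: \eqn{y = a x^2 + b x + c}, one predictor,
#'   coefficients `(a, b, c)` (note `a` multiplies the squared term).
#' * `LINEAR_MULTI`: \eqn{y = a + \sum_i c_i x_i}, an intercept `a`
#'   followed by one coefficient per predictor.
#' * `POWER_MULTI`: \eqn{y = a \prod_i x_i^{e_i}}, a multiplicative
#'   scale `a` followed by one exponent per predictor.
#'
#' The response is a dry mass in kg; predictions are made in arithmetic
#' (untransformed) space with an additive-error convention, so no
#' back-transform correction applies. Models carrying a correction factor
#' `cf` (published above-ground equations fitted in log space) have their
#' prediction multiplied by `cf`.
#'
#' @param form One of `"POWER"`, `"QUADRATIC"`, `"LINEAR_MULTI"`,
#'   `"POWER_MULTI"`.
#' @param coefficients Numeric vector whose length must match the form's
#'   arity given the number of predictors.
#' @param predictors Character vector of predictor names, e.g. `"x"`
#'   (root basal diameter, cm), `"D"` (stem diameter, cm), `"h"` (height,
#'   cm), `"V"` (crown volume, cm^3), `"rho"` (wood density, g cm^-3).
#' @param response Label for the response (default `"dry_mass_kg"`).
#' @param scope Height class `"C1"`/`"C2"`/`"C3"` or `"GENERALIST"`, or
#'   `NA` for ad-hoc fits.
#' @param compartment Which biomass compartment the model predicts
#'   (e.g. `"TOTAL_BGB"`, `"ROOT"`, `"ROOT_CROWN"`,
#'   `"UNEXCAVATED_PRIMARY"`, `"UNEXCAVATED_SECONDARY"`, `"AGB"`).
#' @param cf Optional multiplicative correction factor (log-space fits).
#' @param calibration_range Optional numeric `c(min, max)` of the single
#'   predictor over the fitting data; predictions outside it warn.
#' @param fit Optional [fit_metrics()] object.
#' @param provenance Optional free-text source label.
#' @return An object of class `allometric_model`.
#' @examples
#' m <- allometric_model("POWER", c(a = 0.07577, b = 1.98745), "D")
#' predict(m, data.frame(D = 4))
#' @export
allometric_model <- function(form, coefficients, predictors,
                             response = "dry_mass_kg",
                             scope = NA_character_,
                             compartment = NA_character_,
                             cf = NULL, calibration_range = NULL,
                             fit = NULL, provenance = NULL) {
  form <- match.arg(form, c("POWER", "QUADRATIC", "LINEAR_MULTI", "POWER_MULTI"))
  predictors <- as.character(predictors)
  coefficients <- as.numeric(coefficients)
  arity <- model_arity(form, length(predictors))
  if (length(coefficients) != arity) {
    stop(sprintf("form %s with %d predictor(s) needs %d coefficients, got %d",
                 form, length(predictors), arity, length(coefficients)))
  }
  if (form %in% c("POWER", "QUADRATIC") && length(predictors) != 1) {
    stop(form, " takes exactly one predictor")
  }
  names(coefficients) <- coefficient_names(form, length(predictors))
  structure(
    list(form = form, coefficients = coefficients, predictors = predictors,
         response = response, scope = scope, compartment = compartment,
         cf = cf, calibration_range = calibration_range, fit = fit,
         provenance = provenance),
    class = "allometric_model"
  )
}

model_arity <- function(form, n_pred) {
  switch(form,
         POWER = 2L,
         QUADRATIC = 3L,
         LINEAR_MULTI = n_pred + 1L,
         POWER_MULTI = n_pred + 1L)
}

coefficient_names <- function(form, n_pred) {
  letters[seq_len(model_arity(form, n_pred))]
}

#' @export
print.allometric_model <- function(x, ...) {
  co <- x$coefficients
  eq <- switch(x$form,
    POWER = sprintf("y = %g * %s^%g", co[1], x$predictors, co[2]),
    QUADRATIC = sprintf("y = %g*%s^2 + %g*%s + %g",
                        co[1], x$predictors, co[2], x$predictors, co[3]),
    LINEAR_MULTI = paste0("y = ", format(co[1]), paste0(
      sprintf(" + %g*%s", co[-1], x$predictors), collapse = "")),
    POWER_MULTI = paste0("y = ", format(co[1]), paste0(
      sprintf(" * %s^%g", x$predictors, co[-1]), collapse = "")))
  cat("Allometric model [", x$form, "]", sep = "")
  if (!is.na(x$scope)) cat(" scope=", x$scope, sep = "")
  if (!is.na(x$compartment)) cat(" compartment=", x$compartment, sep = "")
  cat("\n  ", eq, "\n", sep = "")
  if (!is.null(x$cf)) cat("  correction factor CF =", x$cf, "\n")
  if (!is.null(x$fit)) {
    f <- x$fit
    cat(sprintf("  n=%d k=%d R2adj=%.4f RMSE=%.4g MPE=%.3g%% AIC=%.4g\n",
                f$n, f$k, f$r2_adj, f$rmse, f$mpe_pct, f$aic))
  }
  invisible(x)
}

#' Predict dry mass from an allometric model
#'
#' @param object An [allometric_model()].
#' @param newdata A `data.frame` (or named list) containing every
#'   predictor the model names; extra columns are ignored.
#' @param ... Unused.
#' @return Numeric vector of predicted dry masses (kg).
#' @export
predict.allometric_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) {
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  }
  X <- lapply(object$predictors, function(p) {
    v <- as.numeric(newdata[[p]])
    if (any(!is.finite(v))) stop("non-finite values in predictor ", p)
    v
  })
  names(X) <- object$predictors
  co <- unname(object$coefficients)
  y <- switch(object$form,
    POWER = {
      check_power_base(X[[1]], co[2], object$predictors[1])
      co[1] * X[[1]]^co[2]
    },
    QUADRATIC = co[1] * X[[1]]^2 + co[2] * X[[1]] + co[3],
    LINEAR_MULTI = {
      co[1] + Reduce(`+`, Map(function(b, x) b * x,
                              as.list(co[-1]), X))
    },
    POWER_MULTI = {
      Map(function(e, x, nm) check_power_base(x, e, nm),
          as.list(co[-1]), X, object$predictors)
      co[1] * Reduce(`*`, Map(function(e, x) x^e, as.list(co[-1]), X))
    })
  if (!is.null(object$cf)) y <- y * object$cf
  rng <- object$calibration_range
  if (!is.null(rng) && length(object$predictors) == 1) {
    x1 <- X[[1]]
    if (any(x1 < rng[1] | x1 > rng[2])) {
      warning(sprintf(
        "predictor %s outside the calibration range [%g, %g] (extrapolation)",
        object$predictors[1], rng[1], rng[2]))
    }
  }
  y
}

check_power_base <- function(x, exponent, name) {
  if (exponent != round(exponent) && any(x <= 0)) {
    stop("non-positive value of ", name,
         " with fractional exponent ", exponent)
  }
  invisible(TRUE)
}
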