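#' Fit an allometric model by least squares
#'
#' Coefficients minimise the sum of squared residuals in arithmetic
#' (untransformed) space, matching the additive-error convention of the
#' candidate forms. The linear-in-coefficients forms (`QUADRATIC`,
#' `LINEAR_MULTI`) are solved exactly by ordinary least squares; the
#' power forms use Levenberg-Marquardt nonlinear least squares
#' (\code{minpack.lm::nlsLM}) seeded from a log-log ordinary
#' least-squares pre-fit, with up to five deterministically jittered
#' restarts before declaring non-convergence.
#'
#' @param data A `data.frame` holding the response and predictor columns.
#' @param form Model form, see [allometric_model()].
#' @param response Name of the response column (dry mass, kg).
#' @param predictors Character vector of predictor column names.
#' @param start Optional named/ordered numeric start vector for the
#'   nonlinear forms; `"auto"` (default) derives one from a log-space
#'   pre-fit.
#' @param aic_c Additive AIC constant passed to [fit_metrics()].
#' @param maxiter,ftol Convergence controls for the nonlinear solver:
#'   iteration cap and relative SSE-change tolerance.
#' @param scope,compartment Optional labels stored on the fitted model.
#' @return A fitted [allometric_model()] with populated `fit` metrics and
#'   (single-predictor forms) the data's `calibration_range`.
#' @examples
#' d <- data.frame(x = 1:10, y = 0.05 * (1:10)^3)
#' fit_allometric(d, "POWER", "y", "x")
#' @export
fit_allometric <- function(data, form, response, predictors,
                           start = "auto", aic_c = 0,
                           maxiter = 500, ftol = 1e-10,
                           scope = NA_character_,
                           compartment = NA_character_) {
  form <- match.arg(form, c("POWER", "QUADRATIC", "LINEAR_MULTI", "POWER_MULTI"))
  data <- as.data.frame(data)
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  y <- as.numeric(data[[response]])
  X <- data[predictors]
  n <- length(y)
  arity <- model_arity(form, length(predictors))
  if (n < arity + 1) {
    stop(sprintf("need at least %d observations to fit %s, got %d",
                 arity + 1, form, n))
  }
  if (form %in% c("POWER", "POWER_MULTI")) {
    if (any(y <= 0)) stop("power forms require strictly positive responses")
    if (any(as.matrix(X) <= 0)) {
      stop("power forms require strictly positive predictors")
    }
  }

  co <- switch(form,
    QUADRATIC = fit_quadratic(y, X[[1]]),
    LINEAR_MULTI = fit_linear_multi(y, X),
    POWER = fit_power_family(y, X, form, start, maxiter, ftol),
    POWER_MULTI = fit_power_family(y, X, form, start, maxiter, ftol))

  model <- allometric_model(
    form, co, predictors,
    scope = scope, compartment = compartment,
    calibration_range = if (length(predictors) == 1) range(X[[1]]) else NULL
  )
  pred <- predict(model, X)
  model$fit <- fit_metrics(y, pred, k = length(predictors), aic_c = aic_c)
  model
}

fit_quadratic <- function(y, x) {
  fit <- stats::lm(y ~ I(x^2) + x)
  b <- stats::coef(fit)
  if (any(is.na(b))) stop("singular design for QUADRATIC fit")
  c(b[["I(x^2)"]], b[["x"]], b[["(Intercept)"]])
}

fit_linear_multi <- function(y, X) {
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  b <- stats::coef(fit)
  if (any(is.na(b))) stop("singular design for LINEAR_MULTI fit")
  unname(c(b[1], b[-1][names(X)]))
}

# Shared NLS driver for POWER and POWER_MULTI.
fit_power_family <- function(y, X, form, start, maxiter, ftol) {
  p <- ncol(X)
  # internal predictor aliases p1..pk keep the dynamic formula simple
  df <- stats::setNames(as.data.frame(X), paste0("p", seq_len(p)))
  df$y <- y
  exps <- coefficient_names(form, p)[-1]
  rhs <- paste0("a * ", paste(sprintf("p%d^%s", seq_len(p), exps),
                              collapse = " * "))
  fml <- stats::as.formula(paste("y ~", rhs))

  if (identical(start, "auto")) {
    # log-log OLS pre-fit: log y = log a + sum b_i log x_i
    lf <- stats::lm(stats::reformulate(sprintf("log(p%d)", seq_len(p)),
                                       response = "log(y)"), data = df)
    b <- stats::coef(lf)
    start_vec <- c(exp(b[[1]]), unname(b[-1]))
  } else {
    start_vec <- as.numeric(start)
    if (length(start_vec) != p + 1) stop("start vector has wrong length")
  }
  names(start_vec) <- c("a", exps)

  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol)
  best <- NULL
  best_sse <- Inf
  # deterministic jitter ladder: restart j scales the start by +/-10% j
  jitter <- c(1, 0.9, 1.1, 0.8, 1.2, 0.7)
  for (j in jitter) {
    st <- start_vec * j
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = as.list(st), control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (sse < best_sse) {
        best <- fit
        best_sse <- sse
      }
      # accept the first convergent fit; later restarts only run on failure
      break
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "nonlinear least squares failed to converge after %d restarts (form %s; start a=%g)",
      length(jitter), form, start_vec[["a"]]))
  }
  unname(stats::coef(best))
}

#' Rank fitted models and select the best
#'
#' Candidates (fitted on the same data) are ranked by ascending AIC;
#' AIC ties closer than `1e-9` are broken by ascending RMSE, then by
#' descending adjusted R-squared.
#'
#' @param candidates A list of fitted [allometric_model()] objects.
#' @return A list with `best` (the winning model) and `ranking`, a
#'   `data.frame` listing every candidate with all four criteria in rank
#'   order.
#' @export
select_best <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  fits <- lapply(candidates, function(m) {
    if (!inherits(m, "allometric_model") || is.null(m$fit)) {
      stop("every candidate must be a fitted allometric_model")
    }
    m$fit
  })
  ids <- vapply(fits, function(f) paste(signif(f$data_id, 12), collapse = "|"),
                character(1))
  if (length(unique(ids)) > 1) {
    stop("candidates were fitted on different datasets; ranking undefined")
  }
  idx <- seq_along(candidates)
  less_than <- function(i, j) {
    d <- fits[[i]]$aic - fits[[j]]$aic
    if (is.nan(d)) d <- 0  # both -Inf (perfect fits): fall through to RMSE
    if (abs(d) >= 1e-9) return(d < 0)
    if (fits[[i]]$rmse != fits[[j]]$rmse) {
      return(fits[[i]]$rmse < fits[[j]]$rmse)
    }
    isTRUE(fits[[i]]$r2_adj > fits[[j]]$r2_adj)
  }
  # insertion sort with the criterion comparator (candidate lists are short)
  for (i in seq_along(idx)[-1]) {
    j <- i
    while (j > 1 && less_than(idx[j], idx[j - 1])) {
      idx[c(j - 1, j)] <- idx[c(j, j - 1)]
      j <- j - 1
    }
  }
  ranking <- data.frame(
    rank = seq_along(idx),
    candidate = idx,
    form = vapply(candidates[idx], `[[`, character(1), "form"),
    aic = vapply(fits[idx], `[[`, numeric(1), "aic"),
    rmse = vapply(fits[idx], `[[`, numeric(1), "rmse"),
    r2_adj = vapply(fits[idx], `[[`, numeric(1), "r2_adj"),
    mpe_pct = vapply(fits[idx], `[[`, numeric(1), "mpe_pct"),
    stringsAsFactors = FALSE
  )
  list(best = candidates[[idx[1]]], ranking = ranking)
}

#' Residual diagnostics for a fitted model
#'
#' Normality of residuals is assessed with the Shapiro-Wilk test and
#' homoscedasticity with the Breusch-Pagan test of the residuals against
#' the fitted values (both delegated to standard routines). Flags are
#' raised at the 0.05 level. Residuals that are numerically zero
#' everywhere are reported as degenerate (perfect fit; the tests carry no
#' information).
#'
#' @param model A fitted [allometric_model()].
#' @param data The `data.frame` the model was fitted on.
#' @param response Name of the response column.
#' @param alpha Flagging level (default 0.05).
#' @return A list with `normality_p`, `homoscedasticity_p`,
#'   `normality_ok`, `homoscedasticity_ok`, `degenerate` and a
#'   `residual_table` of fitted values vs residuals.
#' @export
residual_diagnostics <- function(model, data, response, alpha = 0.05) {
  data <- as.data.frame(data)
  y <- as.numeric(data[[response]])
  if (length(y) < 3) stop("diagnostics unavailable: need at least 3 observations")
  fitted <- predict(model, data)
  e <- y - fitted
  tab <- data.frame(fitted = fitted, residual = e)
  scale <- max(abs(y), 1)
  if (max(abs(e)) < 1e-10 * scale) {
    return(list(normality_p = NA_real_, homoscedasticity_p = NA_real_,
                normality_ok = NA, homoscedasticity_ok = NA,
                degenerate = TRUE, residual_table = tab))
  }
  sw <- stats::shapiro.test(e)
  bp <- lmtest::bptest(residual ~ fitted, data = tab)
  list(
    normality_p = unname(sw$p.value),
    homoscedasticity_p = unname(bp$p.value),
    normality_ok = unname(sw$p.value) >= alpha,
    homoscedasticity_ok = unname(bp$p.value) >= alpha,
    degenerate = FALSE,
    residual_table = tab
  )
}
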