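test_that("predict evaluates every model form, with domain checks", {
  gen <- allometric_model("POWER", c(0.07577, 1.98745), "D")
  expect_equal(predict(gen, data.frame(D = 1)), 0.07577)
  quad <- allometric_model("QUADRATIC", published_root_quadratic_truth, "x")
  expect_equal(predict(quad, data.frame(x = 1)), sum(published_root_quadratic_truth))
  c2root <- allometric_model("POWER", c(0.465, 1.024), "D")
  expect_equal(predict(c2root, data.frame(D = 1)), 0.465)
  lin <- allometric_model("LINEAR_MULTI", c(1, 2, -3), c("h", "rho"))
  expect_equal(predict(lin, data.frame(h = 10, rho = 0.5)), 1 + 20 - 1.5)
  pm <- allometric_model("POWER_MULTI", c(2, 1, -1), c("D", "h"))
  expect_equal(predict(pm, data.frame(D = 3, h = 4)), 2 * 3 / 4)

  expect_error(predict(gen, data.frame(x = 1)), "missing predictor")
  expect_error(predict(gen, data.frame(D = -1)), "fractional exponent")
  # correction factor multiplies the back-transformed prediction
  agb <- allometric_model("POWER", c(0.25, 2), "D", cf = 1.05)
  expect_equal(predict(agb, data.frame(D = 2)), 0.25 * 4 * 1.05)
})

test_that("predict is continuous in coefficients and predictors", {
  m <- allometric_model("POWER", c(0.5, 2.2), "x")
  base <- predict(m, data.frame(x = 3))
  m2 <- allometric_model("POWER", c(0.5 + 1e-9, 2.2 - 1e-9), "x")
  expect_equal(predict(m2, data.frame(x = 3 + 1e-9)), base, tolerance = 1e-6)
})

test_that("noiseless data are fitted back to the generating coefficients", {
  # power: zero-noise identifiability
  d <- data.frame(x = 1:10, y = 0.05 * (1:10)^3)
  m <- fit_allometric(d, "POWER", "y", "x")
  expect_equal(unname(m$coefficients), c(0.05, 3), tolerance = 1e-6)
  # quadratic: exact polynomial interpolation
  x <- c(0, 1, 2, 3)
  d <- data.frame(x = x, y = 1 * x^2 - 2 * x + 1)
  m <- fit_allometric(d, "QUADRATIC", "y", "x")
  expect_equal(unname(m$coefficients), c(1, -2, 1), tolerance = 1e-9)
  # multi-linear
  set.seed(1)
  d <- data.frame(h = runif(12, 30, 120), rho = runif(12, 0.4, 0.9))
  d$y <- 0.114 + 0.005 * d$h - 0.682 * d$rho
  m <- fit_allometric(d, "LINEAR_MULTI", "y", c("h", "rho"))
  expect_equal(unname(m$coefficients), c(0.114, 0.005, -0.682),
               tolerance = 1e-6)
  # multi-power
  set.seed(2)
  d <- data.frame(D = runif(15, 1, 10), h = runif(15, 250, 800),
                  rho = runif(15, 0.45, 0.9))
  d$y <- 0.002 * d$D^-1.381 * d$h^2.205 * d$rho^4.263
  m <- fit_allometric(d, "POWER_MULTI", "y", c("D", "h", "rho"))
  expect_equal(unname(m$coefficients), c(0.002, -1.381, 2.205, 4.263),
               tolerance = 1e-6)
})

test_that("the nonlinear fit is at least as good as an exhaustive lattice search", {
  x <- c(1, 2, 3)
  y <- 0.5 * x^1.5 + c(0.02, -0.03, 0.01) # fixed perturbation
  m <- fit_allometric(data.frame(x = x, y = y), "POWER", "y", "x")
  oracle_sse <- grid_search_power_sse(x, y, a_range = c(0.3, 0.7),
                                      b_range = c(1.3, 1.7), step = 1e-3)
  expect_lte(m$fit$sse, oracle_sse + 1e-12)
})

test_that("fitting validates its inputs", {
  expect_error(fit_allometric(data.frame(x = 1:2, y = 1:2), "POWER", "y", "x"),
               "at least")
  d <- data.frame(x = 1:5, y = c(-1, 2, 3, 4, 5))
  expect_error(fit_allometric(d, "POWER", "y", "x"), "positive responses")
  d <- data.frame(a = 1:6, b = 2 * (1:6), y = 1:6 + 0.5)
  expect_error(fit_allometric(d, "LINEAR_MULTI", "y", c("a", "b")), "singular")
})

test_that("model selection ranks by AIC with RMSE then R2adj tie-breaks", {
  set.seed(5)
  d <- data.frame(x = seq(1, 8, length.out = 20))
  d$y <- 0.3 * d$x^1.7 * exp(rnorm(20, 0, 0.05))
  pow <- fit_allometric(d, "POWER", "y", "x")
  quad <- fit_allometric(d, "QUADRATIC", "y", "x")
  sel <- select_best(list(pow, quad))
  expect_equal(nrow(sel$ranking), 2)
  expect_equal(sel$ranking$aic, sort(sel$ranking$aic))
  expect_identical(sel$best$form, sel$ranking$form[1])
  # single candidate selects itself
  expect_identical(select_best(list(pow))$best$form, "POWER")
  # exact-AIC tie broken by RMSE
  m1 <- pow; m2 <- pow
  m1$fit$aic <- 1; m1$fit$rmse <- 0.41
  m2$fit$aic <- 1; m2$fit$rmse <- 0.16
  expect_equal(select_best(list(m1, m2))$best$fit$rmse, 0.16)
  # mixed datasets are refused
  other <- fit_allometric(transform(d, y = y * 2), "POWER", "y", "x")
  expect_error(select_best(list(pow, other)), "different datasets")
  expect_error(select_best(list()), "empty")
})

test_that("residual diagnostics pass under the null and detect heteroscedasticity", {
  lin <- allometric_model("LINEAR_MULTI", c(0, 1), "x")
  x <- seq(1, 10, length.out = 200)
  null_pass <- 0; het_fail <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    # homoscedastic normal residuals around the known line
    d <- data.frame(x = x, y = x + rnorm(200, 0, 0.5))
    r <- residual_diagnostics(lin, d, "y")
    if (isTRUE(r$normality_ok) && isTRUE(r$homoscedasticity_ok)) {
      null_pass <- null_pass + 1
    }
    # variance growing as x^2
    d2 <- data.frame(x = x, y = x + rnorm(200, 0, 0.2) * x)
    r2 <- residual_diagnostics(lin, d2, "y")
    if (isFALSE(r2$homoscedasticity_ok)) het_fail <- het_fail + 1
  }
  expect_gte(null_pass, 0.90 * n_seeds)
  expect_gte(het_fail, 0.80 * n_seeds)
})

test_that("degenerate (noiseless) residuals are reported as such", {
  lin <- allometric_model("LINEAR_MULTI", c(2, 3), "x")
  d <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
  r <- residual_diagnostics(lin, d, "y")
  expect_true(r$degenerate)
  expect_true(is.na(r$normality_p))
  expect_error(residual_diagnostics(lin, d[1:2, ], "y"), "at least 3")
})
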