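test_that("model semivariance matches the closed spherical form", {
  m <- variogram_model("spherical", 5.2, 42.8, 3500)
  expect_equal(model_gamma(3500, m), 42.8)
  expect_equal(model_gamma(1750, m), 5.2 + 37.6 * (0.75 - 0.0625))  # 31.05
  expect_equal(model_gamma(1e9, m), 42.8)
  expect_identical(model_gamma(0, m), 0)
  expect_equal(model_gamma(1e-9, m), 5.2, tolerance = 1e-4)  # nugget limit
  e <- variogram_model("exponential", 1, 10, 300)
  g <- variogram_model("gaussian", 1, 10, 300)
  expect_equal(model_gamma(300, e), 1 + 9 * (1 - exp(-3)))
  expect_equal(model_gamma(300, g), 1 + 9 * (1 - exp(-3)))
  h <- seq(0, 2000, by = 10)
  for (mm in list(m, e, g)) expect_true(all(diff(model_gamma(h, mm)) >= -1e-12))
  expect_error(model_gamma(-1, m), ">= 0")
})

test_that("the Matheron estimator reproduces hand-computable cases", {
  pts <- data.frame(x = c(0, 100), y = c(0, 0), value = c(0, 2))
  emp <- empirical_semivariogram(pts, lag_width = 50, max_dist = 200)
  expect_length(emp$gamma_hat, 1)
  expect_equal(emp$gamma_hat, 2)  # (1/2) * (2)^2
  expect_identical(emp$pair_counts, 1L)
})

test_that("a constant field has zero semivariance at every lag", {
  set.seed(41)
  pts <- data.frame(x = runif(40, 0, 500), y = runif(40, 0, 500), value = 3.3)
  emp <- empirical_semivariogram(pts)
  expect_true(all(emp$gamma_hat == 0))
  expect_true(all(diff(emp$lag_centers) > 0))
})

test_that("white noise has a flat semivariogram at the noise variance", {
  set.seed(42)
  pts <- data.frame(x = runif(400, 0, 1000), y = runif(400, 0, 1000),
                    value = rnorm(400, sd = 1))
  emp <- empirical_semivariogram(pts)
  # each binned estimate ~ sigma^2 within 3 SE (pairs overlap, so use the
  # conservative independent-pair SE sqrt(2)*sigma^2/sqrt(N))
  se <- sqrt(2) / sqrt(emp$pair_counts)
  expect_true(all(abs(emp$gamma_hat - 1) < 3.5 * se + 0.05))
})

test_that("fitting a noiseless spherical curve recovers its parameters", {
  truth <- variogram_model("spherical", 2, 12, 700)
  h <- seq(50, 1500, by = 100)
  emp <- structure(list(lag_centers = h, gamma_hat = model_gamma(h, truth),
                        pair_counts = rep(100L, length(h))),
                   class = "empirical_variogram")
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 2, tolerance = 0.02)
  expect_equal(fit$sill, 12, tolerance = 0.02)
  expect_equal(fit$range_m, 700, tolerance = 0.02)
  expect_error(fit_variogram(structure(list(lag_centers = h[1:2],
                                            gamma_hat = c(1, 2),
                                            pair_counts = c(5L, 5L)),
                                       class = "empirical_variogram")),
               "3 retained lags")
})

test_that("single-neighbor and symmetric kriging cases are exact", {
  m <- variogram_model("spherical", 1, 8, 400)
  one <- data.frame(x = 10, y = 10, value = 7)
  r1 <- ok_predict(one, m, c(50, 50))
  expect_identical(r1$prediction, 7)
  expect_identical(r1$weights, 1)
  two <- data.frame(x = c(0, 100), y = c(0, 0), value = c(4, 8))
  r2 <- ok_predict(two, m, c(50, 40))  # equidistant
  expect_equal(r2$weights, c(0.5, 0.5))
  expect_equal(r2$prediction, 6)
})

test_that("kriging interpolates exactly at data points", {
  set.seed(43)
  pts <- data.frame(x = runif(15, 0, 500), y = runif(15, 0, 500),
                    value = rnorm(15))
  m0 <- variogram_model("spherical", 0, 5, 300)
  for (i in c(1, 8, 15)) {
    r <- ok_predict(pts, m0, c(pts$x[i], pts$y[i]))
    expect_equal(r$prediction, pts$value[i], tolerance = 1e-10)
    expect_equal(r$kriging_variance, 0, tolerance = 1e-10)
  }
})

test_that("kriging weights sum to 1 and variance stays nonnegative", {
  set.seed(44)
  m <- variogram_model("exponential", 0.5, 6, 250)
  for (i in 1:20) {
    pts <- data.frame(x = runif(12, 0, 400), y = runif(12, 0, 400),
                      value = rnorm(12))
    r <- ok_predict(pts, m, runif(2, 0, 400))
    expect_equal(sum(r$weights), 1, tolerance = 1e-8)
    expect_gte(r$kriging_variance, 0)
  }
})

test_that("predictions agree with an independent covariance-form oracle", {
  set.seed(45)
  for (i in 1:20) {
    fam <- sample(c("spherical", "exponential", "gaussian"), 1)
    m <- variogram_model(fam, runif(1, 0, 2), runif(1, 3, 10),
                         runif(1, 100, 600))
    pts <- data.frame(x = runif(20, 0, 500), y = runif(20, 0, 500),
                      value = rnorm(20, 5, 2))
    tgt <- runif(2, 50, 450)
    expect_equal(ok_predict(pts, m, tgt)$prediction, ok_oracle(pts, m, tgt),
                 tolerance = 1e-6)
  }
})

test_that("duplicate coordinates are averaged with a warning", {
  m <- variogram_model("spherical", 0.5, 4, 200)
  pts <- data.frame(x = c(0, 0, 100), y = c(0, 0, 0), value = c(2, 4, 6))
  expect_warning(r <- ok_predict(pts, m, c(50, 10)), "duplicate")
  expect_equal(sum(r$weights), 1, tolerance = 1e-8)
})

test_that("kriging a constant field returns the constant everywhere", {
  set.seed(46)
  pts <- data.frame(x = runif(25, 0, 300), y = runif(25, 0, 300), value = 7.5)
  m <- variogram_model("gaussian", 0.2, 3, 150)
  r <- krige_grid(pts, m, c(0, 300, 0, 300), resolution = 30)
  expect_equal(as.vector(r$values), rep(7.5, 100), tolerance = 1e-8)
})

test_that("gridded predictions are deterministic and match point kriging", {
  set.seed(47)
  pts <- data.frame(x = runif(30, 0, 400), y = runif(30, 0, 400),
                    value = rnorm(30, 10, 3))
  m <- variogram_model("spherical", 0.3, 6, 250)
  r1 <- krige_grid(pts, m, c(0, 400, 0, 400), resolution = 40)
  r2 <- krige_grid(pts, m, c(0, 400, 0, 400), resolution = 40)
  expect_identical(r1$values, r2$values)
  cc <- raster_cell_centers(r1)
  for (k in c(1, 37, 100)) {
    direct <- ok_predict(pts, m, c(cc$x[k], cc$y[k]))$prediction
    expect_equal(as.vector(t(r1$values))[k], direct, tolerance = 1e-9)
  }
})

test_that("leave-one-out cross-validation reports ME and RMSE correctly", {
  set.seed(48)
  # perfect predictor: constant field
  pts <- data.frame(x = runif(10, 0, 200), y = runif(10, 0, 200), value = 2)
  m <- variogram_model("spherical", 0, 4, 150)
  cv0 <- loo_cross_validate(pts, m)
  expect_equal(cv0$me, 0, tolerance = 1e-10)
  expect_equal(cv0$rmse, 0, tolerance = 1e-10)
  # general field: definitions and the RMSE >= |ME| inequality
  pts$value <- rnorm(10)
  cv <- loo_cross_validate(pts, m)
  expect_equal(cv$me, mean(cv$residuals))
  expect_equal(cv$rmse, sqrt(mean(cv$residuals^2)))
  expect_gte(cv$rmse, abs(cv$me))
  expect_error(loo_cross_validate(pts[1:2, ], m), "3 points")
})

test_that("model comparison ranks by cross-validation error", {
  set.seed(49)
  m <- variogram_model("spherical", 0, 10, 400)
  pts <- data.frame(x = runif(80, 0, 800), y = runif(80, 0, 800))
  pts$value <- simulate_grf(pts, m, seed = 490)
  cm <- compare_models(pts)
  expect_true(all(diff(cm$rmse) >= 0))  # ranked best-first
  # the true family is always competitive with the winner
  expect_lte(cm$rmse[cm$family == "spherical"], 1.10 * cm$rmse[1])
  single <- compare_models(pts, families = "gaussian")
  expect_identical(single$family, "gaussian")
  expect_identical(nrow(single), 1L)
})
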