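test_that("field simulation is seed-deterministic", {
  m <- variogram_model("spherical", 1, 10, 600)
  pts <- fishnet_sample(c(0, 1000, 0, 500))
  z1 <- simulate_grf(pts, m, seed = 71)
  z2 <- simulate_grf(pts, m, seed = 71)
  z3 <- simulate_grf(pts, m, seed = 72)
  expect_identical(z1, z2)
  expect_false(identical(z1, z3))
})

test_that("a pure-nugget model yields a spatially uncorrelated field", {
  m <- variogram_model("spherical", 4, 4, 500)  # sill == nugget
  pts <- fishnet_sample(c(0, 2000, 0, 1000))
  z <- simulate_grf(pts, m, seed = 73)
  # neighbouring samples (100 m apart) should show no correlation
  g <- matrix(z, nrow = 20, byrow = FALSE)
  left <- as.vector(g[-nrow(g), ]); right <- as.vector(g[-1, ])
  expect_lt(abs(stats::cor(left, right)), 0.15)
  expect_lt(abs(stats::var(z) - 4), 1.5)
})

test_that("one realisation's semivariogram tracks the model curve", {
  m <- variogram_model("spherical", 1, 10, 600)
  pts <- fishnet_sample(c(0, 2500, 0, 1000))
  acc <- NULL
  for (k in 1:10) {
    p <- pts; p$value <- simulate_grf(p, m, seed = 730 + k)
    emp <- empirical_semivariogram(p, lag_width = 150, max_dist = 1200)
    theo <- model_gamma(emp$lag_centers, m)
    acc <- rbind(acc, emp$gamma_hat / theo)
  }
  # Monte-Carlo tolerance on the 10-seed mean ratio per lag
  expect_true(all(abs(colMeans(acc) - 1) < 0.25))
})

test_that("the WLS fit recovers an in-domain model without median bias", {
  m <- variogram_model("spherical", 1, 10, 600)
  pts <- fishnet_sample(c(0, 2500, 0, 1000))
  fits <- t(sapply(1:20, function(k) {
    p <- pts; p$value <- simulate_grf(p, m, seed = 7400 + k)
    emp <- empirical_semivariogram(p, lag_width = 150, max_dist = 1346)
    f <- fit_variogram(emp, "spherical")
    c(sill = f$sill, range = f$range_m)
  }))
  expect_lt(abs(stats::median(fits[, "sill"]) - 10) / 10, 0.25)
  expect_lt(abs(stats::median(fits[, "range"]) - 600) / 600, 0.25)
})

test_that("moment calibration hits its targets and preserves ranks", {
  set.seed(75)
  v <- rnorm(250, 3, 2) + sin(seq_len(250) / 9)
  tgt <- marginal_target(mean = 117.80, sd = 35.14, skew = -0.52,
                         lo = 0, hi = 258.4)
  out <- transform_marginal(v, tgt)
  expect_equal(mean(out), 117.80, tolerance = 0.02 * 117.8)
  expect_equal(sd(out), 35.14, tolerance = 0.02 * 35.14)
  skw <- function(x) mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_lt(abs(skw(out) - (-0.52)), 0.15)
  expect_identical(order(out), order(v))  # monotone
  # near-identity when the target equals the field's own moments
  tgt0 <- marginal_target(mean = mean(v), sd = sd(v), skew = skw(v),
                          lo = min(v) - 10, hi = max(v) + 10)
  out0 <- transform_marginal(v, tgt0)
  expect_gt(stats::cor(out0, v), 0.999)
  expect_error(
    transform_marginal(v, marginal_target(mean = 10, sd = 35, skew = 0,
                                          lo = 0, hi = 20)),
    "infeasible")
})

test_that("range calibration maps ranks onto the configured bounds", {
  set.seed(76)
  v <- rnorm(300)
  tgt <- marginal_target(lo = 7.46, hi = 8.26, method = "range")
  out <- transform_marginal(v, tgt)
  expect_gte(min(out), 7.46)
  expect_lte(max(out), 8.26)
  expect_identical(order(out), order(v))
})

test_that("fishnet sampling places one centred point per hectare cell", {
  pts <- fishnet_sample(c(0, 2500, 0, 1000))
  expect_identical(nrow(pts), 250L)
  one <- fishnet_sample(c(0, 100, 0, 100))
  expect_identical(nrow(one), 1L)
  expect_equal(unlist(one), c(x = 50, y = 50))
  expect_true(all(pts$x > 0 & pts$x < 2500 & pts$y > 0 & pts$y < 1000))
  j1 <- fishnet_sample(c(0, 500, 0, 500), jitter = 10, seed = 77)
  j2 <- fishnet_sample(c(0, 500, 0, 500), jitter = 10, seed = 77)
  expect_identical(j1, j2)
  base <- fishnet_sample(c(0, 500, 0, 500))
  expect_true(all(abs(j1$x - base$x) <= 10 & abs(j1$y - base$y) <= 10))
  expect_error(fishnet_sample(c(0, 250, 0, 130)), "tessellate")
  expect_error(fishnet_sample(c(0, 0, 0, 100)), "degenerate")
})

test_that("the generated study is reproducible byte for byte", {
  st1 <- suppressWarnings(generate_soil_dataset(seed = 78))
  st2 <- suppressWarnings(generate_soil_dataset(seed = 78))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_soil_samples(st1$samples, f1)
  write_soil_samples(st2$samples, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    st1$samples$N,
    suppressWarnings(generate_soil_dataset(seed = 79))$samples$N))
})

test_that("generated samples respect bounds and calibrated moments", {
  st <- default_study()$study
  tg <- default_marginal_targets()
  for (v in names(tg)) {
    x <- st$samples[[v]]
    expect_gte(min(x), tg[[v]]$lo)
    expect_lte(max(x), tg[[v]]$hi)
  }
  # N mean within the sampling band 3*SD/sqrt(n) of the published 117.80
  expect_lt(abs(mean(st$samples$N) - 117.80), 3 * 35.14 / sqrt(250))
  # OC-N latent coupling survives calibration
  expect_gt(stats::cor(st$samples$OC, st$samples$N), 0.2)
  # samples validate against the physical-bounds contract
  expect_silent(fertzone:::validate_soil_samples(st$samples))
})

test_that("yield coupling approaches an exact line as R2 tends to 1", {
  st <- default_study()
  fert <- st$scored$fertility_score
  pts <- st$study$samples[, c("x", "y")]
  y_hi <- generate_yields(pts, fert, "wheat", 0.9999, 2500, 30, seed = 80)
  meas <- y_hi[y_hi$source != "farmer_reported", ]
  ym <- tapply(quadrat_to_hectare(meas$quadrat_mass_kg),
               paste(meas$x, meas$y), mean)
  fm <- fert[match(names(ym), paste(pts$x, pts$y))]
  expect_gt(regress_fertility_yield(fm, as.numeric(ym))$r_squared, 0.999)
  expect_error(generate_yields(pts, fert, "wheat", 1.2, 2500, 30), "target_r2")
  expect_error(generate_yields(pts, rep(5, nrow(pts)), "wheat", 0.9, 2500, 30),
               "variance")
})

test_that("negative synthetic yields are clipped at zero with a warning", {
  pts <- data.frame(x = c(50, 150, 250, 350), y = rep(50, 4))
  fert <- c(10, 20, 30, 40)
  expect_warning(
    y <- generate_yields(pts, fert, "barley", 0.5, -2000, 10, seed = 81),
    "clipped")
  expect_true(all(y$quadrat_mass_kg >= 0))
})
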