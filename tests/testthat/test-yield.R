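test_that("quadrat conversion is the x10,000 scaling and is linear", {
  expect_identical(quadrat_to_hectare(1), 10000)
  expect_identical(quadrat_to_hectare(0), 0)
  expect_identical(quadrat_to_hectare(0.35), 3500)
  a <- 0.12; b <- 0.4
  expect_equal(quadrat_to_hectare(a + b),
               quadrat_to_hectare(a) + quadrat_to_hectare(b))
  expect_error(quadrat_to_hectare(-0.1), ">= 0")
})

test_that("the seasonal mean is the arithmetic mean within its range", {
  expect_identical(mean_seasonal_yield(c(2, 4)), 3)
  expect_identical(mean_seasonal_yield(5), 5)
  set.seed(61)
  y <- runif(7, 0, 4000)
  m <- mean_seasonal_yield(y)
  expect_gte(m, min(y)); expect_lte(m, max(y))
  expect_error(mean_seasonal_yield(numeric(0)), "no seasonal yields")
  expect_error(mean_seasonal_yield(c(1, 2), n_seasons = 3), "n_seasons")
})

test_that("yield RMSE matches its closed form and is order-invariant", {
  expect_identical(yield_rmse(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_identical(yield_rmse(c(1, 0), c(0, 1)), 1)  # differences {1, -1}
  set.seed(62)
  a <- rnorm(20); b <- rnorm(20)
  p <- sample(20)
  expect_equal(yield_rmse(a, b), yield_rmse(a[p], b[p]))
  expect_error(yield_rmse(1:3, 1:4), "equal-length")
})

test_that("IQR fences use interpolated quartiles", {
  # oracle: type-7 quantiles of 1..10 give Q1 3.25, Q3 7.75, IQR 4.5,
  # fences [-3.5, 14.5] -> nothing removed
  f <- iqr_filter(1:10)
  expect_identical(f$kept, 1:10)
  expect_length(f$removed, 0)
  # adding 100: Q1 3.5, Q3 8.5, upper fence 16 -> 100 removed
  f2 <- iqr_filter(c(1:10, 100))
  expect_equal(f2$removed, 100)
  expect_equal(f2$kept, 1:10)
  # constant list: IQR 0 keeps values equal to the quartiles
  f3 <- iqr_filter(rep(4, 6))
  expect_length(f3$removed, 0)
  expect_warning(iqr_filter(c(1, 2, 3)), "fewer than 4")
})

test_that("OLS recovers exact and null relationships", {
  x <- c(10, 20, 30, 40)
  r <- suppressWarnings(regress_fertility_yield(x, 5 + 2 * x))  # exact fit
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 5)
  expect_equal(r$r_squared, 1)
  set.seed(63)
  r0 <- regress_fertility_yield(runif(2000), rnorm(2000))
  expect_lt(r0$r_squared, 0.01)
  # permutation of (x, y) pairs leaves the fit invariant
  set.seed(64)
  x <- runif(50); y <- 3 * x + rnorm(50, sd = 0.2)
  p <- sample(50)
  expect_equal(regress_fertility_yield(x, y),
               regress_fertility_yield(x[p], y[p]))
  expect_error(regress_fertility_yield(rep(1, 5), rnorm(5)), "variance")
})

test_that("Welch's ANOVA matches the reference implementation to 1e-8", {
  set.seed(65)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(4:30, 1), mean = runif(1, 0, 3), sd = runif(1, 0.5, 3)))
    got <- welch_anova(groups)
    ref <- stats::oneway.test(
      values ~ g,
      data = data.frame(values = unlist(groups),
                        g = factor(rep(seq_len(k), lengths(groups)))),
      var.equal = FALSE)
    expect_equal(got$F, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$df1, unname(ref$parameter[1]), tolerance = 1e-8)
    expect_equal(got$df2, unname(ref$parameter[2]), tolerance = 1e-8)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("two-group Welch ANOVA reduces to the squared Welch t", {
  set.seed(66)
  g1 <- rnorm(12, 1, 1); g2 <- rnorm(20, 2, 3)
  wa <- welch_anova(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  expect_equal(wa$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(wa$df2, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(wa$p, tt$p.value, tolerance = 1e-10)
})

test_that("Welch F is near zero for equal means and grows with separation", {
  set.seed(67)
  base <- list(rnorm(30, 5, 1), rnorm(25, 5, 2), rnorm(40, 5, 0.5))
  wa0 <- welch_anova(base)
  expect_lt(wa0$F, 3)
  expect_gt(wa0$p, 0.05)
  ps <- vapply(c(0, 0.5, 1.5, 3), function(d) {
    shifted <- base
    shifted[[2]] <- base[[2]] + d
    welch_anova(shifted)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(welch_anova(list(rep(1, 5), rnorm(5))), "zero-variance")
})

test_that("Games-Howell agrees with the Welch t in the two-group case", {
  set.seed(68)
  g1 <- rnorm(15, 1, 1); g2 <- rnorm(22, 1.8, 2.5)
  gh <- games_howell(list(a = g1, b = g2))
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  # with two means the studentized-range tail equals the two-sided t tail
  expect_equal(gh$p, tt$p.value, tolerance = 1e-6)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-10)
  # identical groups -> p ~ 1; order of groups flips the sign only
  gh_same <- games_howell(list(x = g1, y = g1 + 0))
  expect_gt(gh_same$p, 0.999)
  gh_rev <- games_howell(list(b = g2, a = g1))
  expect_equal(gh_rev$p, gh$p, tolerance = 1e-12)
  expect_equal(gh_rev$diff, -gh$diff, tolerance = 1e-12)
})

test_that("Games-Howell produces one row per pair with bounded p-values", {
  set.seed(69)
  groups <- list(a = rnorm(10, 0), b = rnorm(12, 1), c = rnorm(9, 4, 2))
  gh <- games_howell(groups)
  expect_identical(nrow(gh), 3L)
  expect_true(all(gh$p >= 0 & gh$p <= 1))
  expect_lt(gh$p[gh$group1 == "a" & gh$group2 == "c"],
            gh$p[gh$group1 == "a" & gh$group2 == "b"])
})

test_that("the validation battery ties rasters, yields and statistics together", {
  set.seed(70)
  # fertility surface with two clear bands and yields that track it
  v <- matrix(rep(c(30, 60), each = 50), 10, 10)
  r <- fz_raster(v, 0, 0, 100)
  pts <- raster_cell_centers(r)
  fert <- raster_extract(r, pts$x, pts$y)
  recs <- generate_yields(pts[, c("x", "y")], fert, "wheat", 0.9,
                          2500, 30, seed = 700)
  rep_ <- validate_fertility_yield(recs, r)
  expect_named(rep_, "wheat")
  w <- rep_$wheat
  expect_gt(w$r_squared, 0.8)
  expect_equal(w$slope, 30, tolerance = 0.2 * 30)
  expect_false(is.null(w$welch))
  expect_lt(w$welch$p, 0.001)
  expect_false(is.null(w$games_howell))
  expect_true(is.finite(w$yield_rmse_kg_ha))
  # fewer than 3 matched points -> crop skipped with a warning
  few <- recs[recs$x < 150 & recs$y < 250, ]
  expect_warning(rep2 <- validate_fertility_yield(few, r), "skipped")
  expect_length(rep2, 0)
})
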