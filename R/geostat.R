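#' Construct a semivariogram model
#'
#' Isotropic semivariogram with nugget, sill (total, >= nugget) and range.
#' `spherical` reaches the sill exactly at `range_m`; `exponential` and
#' `gaussian` use practical-range forms (95% of the sill at `range_m`):
#' \deqn{\gamma_{exp}(h) = c_0 + c (1 - e^{-3h/a}),\quad
#'       \gamma_{gau}(h) = c_0 + c (1 - e^{-3h^2/a^2})}
#' with \eqn{c_0} the nugget and \eqn{c} the partial sill. By convention
#' \eqn{\gamma(0) = 0} while \eqn{\lim_{h\to 0^+}\gamma(h) = c_0}.
#'
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget Semivariance at vanishing separation, >= 0.
#' @param sill Plateau semivariance (total sill), >= nugget.
#' @param range_m Range in metres, > 0.
#' @return Object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, sill, range_m) {
  family <- match.arg(family)
  stopifnot(is.finite(nugget), nugget >= 0, is.finite(sill), sill >= nugget,
            is.finite(range_m), range_m > 0)
  structure(list(family = family, nugget = nugget, sill = sill,
                 range_m = range_m),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model %s: nugget %.4g, sill %.4g, range %.4g m>\n",
              x$family, x$nugget, x$sill, x$range_m))
  invisible(x)
}

#' Model semivariance at separation h
#'
#' @param h Numeric vector of separations (m), >= 0.
#' @param model A [variogram_model()].
#' @return Semivariances; `gamma(0) = 0` exactly.
#' @export
#' @examples
#' m <- variogram_model("spherical", 5.2, 42.8, 3500)
#' model_gamma(1750, m)  # 31.05
model_gamma <- function(h, model) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(!is.finite(h)) || any(h < 0))
    stop("separation h must be finite and >= 0", call. = FALSE)
  c0 <- model$nugget
  c1 <- model$sill - model$nugget
  a <- model$range_m
  g <- switch(model$family,
    spherical = {
      u <- pmin(h / a, 1)
      c0 + c1 * (1.5 * u - 0.5 * u^3)
    },
    exponential = c0 + c1 * (1 - exp(-3 * h / a)),
    gaussian = c0 + c1 * (1 - exp(-3 * h^2 / a^2)))
  g[h == 0] <- 0
  g
}

# covariance implied by the model: C(h) = sill - gamma(h) for h > 0,
# C(0) = sill. Used by the GRF simulator and kept valid by construction
# for the three admissible families.
model_cov <- function(h, model) {
  cv <- model$sill - model_gamma(h, model)
  cv[h == 0] <- model$sill
  cv
}

#' Empirical (Matheron) semivariogram
#'
#' Per distance bin \eqn{\hat\gamma(h) = \frac{1}{2N(h)}\sum (z_i-z_j)^2}
#' over point pairs whose separation falls in the bin; bins with no pairs
#' are dropped. Each bin's reported lag is the mean pair separation within
#' it (not the bin midpoint), which avoids binning bias when pair
#' distances cluster away from the midpoint.
#'
#' @param points Data frame with columns `x`, `y`, `value`.
#' @param lag_width Bin width (m), > 0. Default: extent diagonal / 15.
#' @param max_dist Maximum separation retained. Default: half the extent
#'   diagonal.
#' @return Object of class `empirical_variogram` with fields `lag_centers`,
#'   `gamma_hat`, `pair_counts`.
#' @export
empirical_semivariogram <- function(points, lag_width = NULL, max_dist = NULL) {
  stopifnot(nrow(points) >= 2L, all(is.finite(points$x)),
            all(is.finite(points$y)), all(is.finite(points$value)))
  D <- as.matrix(stats::dist(points[, c("x", "y")]))
  diag_len <- sqrt(diff(range(points$x))^2 + diff(range(points$y))^2)
  if (diag_len == 0) stop("all points share one location", call. = FALSE)
  if (is.null(lag_width)) lag_width <- diag_len / 15
  if (is.null(max_dist)) max_dist <- diag_len / 2
  stopifnot(lag_width > 0, max_dist > 0)
  iu <- upper.tri(D)
  d <- D[iu]
  dz2 <- (outer(points$value, points$value, "-")^2)[iu]
  keep <- d > 0 & d <= max_dist
  d <- d[keep]; dz2 <- dz2[keep]
  if (!length(d)) stop("no point pairs within max_dist", call. = FALSE)
  bin <- floor(d / lag_width)
  gh <- tapply(dz2, bin, mean) / 2
  np <- tapply(dz2, bin, length)
  structure(list(lag_centers = as.numeric(tapply(d, bin, mean)),
                 gamma_hat = as.numeric(gh),
                 pair_counts = as.integer(np)),
            class = "empirical_variogram")
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat("<empirical_variogram:", length(x$lag_centers), "lags, ",
      sum(x$pair_counts), "pairs>\n")
  invisible(x)
}

#' Fit a semivariogram model by weighted least squares
#'
#' Minimises \eqn{\sum_k N(h_k)/h_k^2\,(\hat\gamma(h_k)-\gamma(h_k))^2}
#' (Cressie weights) over nugget, partial sill and range with box
#' constraints (nugget >= 0, sill >= nugget, range > 0), multi-start
#' L-BFGS-B. The fitted range is bounded above by `range_upper` — a fit
#' cannot support spatial structure far beyond the sampled extent — and the
#' fitted sill by `sill_upper` times the largest empirical semivariance.
#'
#' @param emp An `empirical_variogram` with >= 3 retained lags.
#' @param family Model family to fit.
#' @param range_upper Upper bound for the fitted range (m). Default: twice
#'   the largest lag.
#' @param sill_upper Multiplier of `max(gamma_hat)` bounding the fitted
#'   partial sill (default 20, effectively unconstrained).
#' @return A [variogram_model()] with attributes `objective` (attained WLS
#'   value) and `convergence` (optimizer code of the best start).
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian"),
                          range_upper = NULL, sill_upper = 20) {
  family <- match.arg(family)
  stopifnot(inherits(emp, "empirical_variogram"))
  if (length(emp$lag_centers) < 3L)
    stop("need at least 3 retained lags to fit a variogram", call. = FALSE)
  h <- emp$lag_centers
  g <- emp$gamma_hat
  w <- emp$pair_counts / h^2
  hmax <- max(h)
  if (is.null(range_upper)) range_upper <- 2 * hmax
  sv <- max(g)
  if (sv <= 0) sv <- 1e-8  # constant field: fit collapses to zero structure
  obj <- function(p) {
    m <- variogram_model(family, p[1], p[1] + p[2], p[3])
    sum(w * (g - model_gamma(h, m))^2)
  }
  lower <- c(0, 1e-10, max(min(h) / 10, 1e-6))
  upper <- c(2 * sv, sill_upper * sv, range_upper)
  starts <- list(c(0.1 * sv, sv, hmax / 2),
                 c(1e-6, sv, hmax),
                 c(0.2 * sv, min(2 * sv, sill_upper * sv * 0.9), 1.5 * hmax),
                 c(0.5 * sv, 0.5 * sv, hmax / 4))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    f <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best))
    stop("variogram WLS optimisation failed for every start", call. = FALSE)
  m <- variogram_model(family, best$par[1], best$par[1] + best$par[2],
                       best$par[3])
  attr(m, "objective") <- best$value
  attr(m, "convergence") <- best$convergence
  m
}

# Average exact-duplicate coordinates into single points (prevents singular
# kriging systems); warns when any merging happened.
dedupe_points <- function(points) {
  key <- paste(points$x, points$y)
  if (!anyDuplicated(key)) return(points)
  agg <- stats::aggregate(value ~ x + y, data = points, FUN = mean)
  warning(nrow(points) - nrow(agg),
          " duplicate coordinate(s) averaged before kriging", call. = FALSE)
  agg
}

# Ordinary-kriging system for a set of data points: returns the factorised
# (n+1) x (n+1) matrix [Gamma 1; 1' 0] ready for repeated solves.
ok_system <- function(points, model) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points[, c("x", "y")]))
  G <- model_gamma(D, model)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

#' Ordinary-kriging prediction at one target location
#'
#' Solves the ordinary-kriging system (semivariance form with Lagrange
#' multiplier); the weights sum to 1 by construction and are checked. With
#' zero nugget and the target coincident with a data point the prediction
#' reproduces that point's value with zero variance (exact interpolation;
#' the nugget, when present, is treated as spatial microstructure, so
#' coincident predictions still honour the data).
#'
#' @param neighbors Data frame with columns `x`, `y`, `value` (>= 1 row).
#' @param model A [variogram_model()].
#' @param target Length-2 numeric `c(x, y)`.
#' @return List with `prediction`, `kriging_variance` (>= 0, clamped at
#'   solver tolerance), `weights`.
#' @export
ok_predict <- function(neighbors, model, target) {
  stopifnot(nrow(neighbors) >= 1L, length(target) == 2L,
            all(is.finite(unlist(neighbors[, c("x", "y", "value")]))),
            all(is.finite(target)))
  neighbors <- dedupe_points(neighbors)
  n <- nrow(neighbors)
  if (n == 1L)
    return(list(prediction = neighbors$value, kriging_variance = model$nugget,
                weights = 1))
  d0 <- sqrt((neighbors$x - target[1])^2 + (neighbors$y - target[2])^2)
  # exact-interpolation convention at coincident locations
  hit <- which(d0 == 0)
  if (length(hit)) {
    w <- numeric(n); w[hit[1]] <- 1
    return(list(prediction = neighbors$value[hit[1]], kriging_variance = 0,
                weights = w))
  }
  A <- ok_system(neighbors, model)
  b <- c(model_gamma(d0, model), 1)
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("singular ordinary-kriging system", call. = FALSE))
  w <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  if (abs(sum(w) - 1) > 1e-8)
    stop("kriging weights do not sum to 1 (ill-conditioned system)",
         call. = FALSE)
  list(prediction = sum(w * neighbors$value),
       kriging_variance = max(0, sum(w * b[seq_len(n)]) + mu),
       weights = unname(w))
}

#' Krige a regular grid
#'
#' Cell-centre ordinary-kriging predictions over a rectangular extent.
#' Global neighbourhoods (all points per target) are used for n <= 500
#' data points; beyond that the nearest `nmax` points per target.
#' Deterministic: the same inputs reproduce the raster bit for bit.
#'
#' @param points Data frame with columns `x`, `y`, `value`.
#' @param model A [variogram_model()].
#' @param extent Numeric length-4 `c(xmin, xmax, ymin, ymax)`; must contain
#'   at least one data point.
#' @param resolution Cell size (m), > 0; default 10.
#' @param nmax Neighbourhood size for the local branch (default 32).
#' @return An [fz_raster()] of predictions.
#' @export
krige_grid <- function(points, model, extent, resolution = 10, nmax = 32L) {
  stopifnot(length(extent) == 4L, extent[1] < extent[2],
            extent[3] < extent[4], resolution > 0)
  points <- dedupe_points(points)
  inx <- points$x >= extent[1] & points$x <= extent[2] &
         points$y >= extent[3] & points$y <= extent[4]
  if (!any(inx)) stop("extent contains no data points", call. = FALSE)
  nc <- max(1L, ceiling((extent[2] - extent[1]) / resolution))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / resolution))
  r <- fz_raster(matrix(NA_real_, nr, nc), extent[1], extent[3], resolution)
  cc <- raster_cell_centers(r)
  n <- nrow(points)
  z <- points$value
  if (n <= 500L) {
    A <- ok_system(points, model)
    Ainv <- solve(A)
    preds <- numeric(nrow(cc))
    chunk <- 4000L
    for (s in seq(1L, nrow(cc), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(cc))
      DX <- outer(points$x, cc$x[idx], "-")
      DY <- outer(points$y, cc$y[idx], "-")
      B <- rbind(model_gamma(sqrt(DX^2 + DY^2), model), 1)
      W <- Ainv %*% B
      preds[idx] <- as.numeric(crossprod(W[seq_len(n), , drop = FALSE], z))
    }
  } else {
    preds <- vapply(seq_len(nrow(cc)), function(i) {
      d <- (points$x - cc$x[i])^2 + (points$y - cc$y[i])^2
      nb <- points[order(d)[seq_len(min(nmax, n))], ]
      ok_predict(nb, model, c(cc$x[i], cc$y[i]))$prediction
    }, numeric(1))
  }
  r$values <- matrix(preds, nr, nc, byrow = TRUE)
  r
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each point is predicted from all the others; reports the mean error
#' \eqn{ME = \frac1n\sum(z_i - z_i^*)}, the root mean square error
#' \eqn{RMSE = \sqrt{\frac1n\sum(z_i - z_i^*)^2}} and per-point residuals.
#' Per-point solver failures are recorded (`NA` residual) without aborting.
#'
#' @param points Data frame with columns `x`, `y`, `value` (>= 3 rows).
#' @param model A [variogram_model()].
#' @return Object of class `crossval_report`: list with `me`, `rmse`,
#'   `residuals`, `failures`.
#' @export
loo_cross_validate <- function(points, model) {
  points <- dedupe_points(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for cross-validation",
                   call. = FALSE)
  res <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- tryCatch(
      ok_predict(points[-i, ], model, c(points$x[i], points$y[i]))$prediction,
      error = function(e) NA_real_)
    res[i] <- points$value[i] - p
  }
  ok <- !is.na(res)
  structure(list(me = mean(res[ok]), rmse = sqrt(mean(res[ok]^2)),
                 residuals = res, failures = which(!ok)),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report: ME %.4g, RMSE %.4g, %d point(s), %d failure(s)>\n",
              x$me, x$rmse, length(x$residuals), length(x$failures)))
  invisible(x)
}

#' Fit and rank competing semivariogram families
#'
#' Fits each family to the empirical semivariogram of the data, runs
#' leave-one-out cross-validation with each fitted model, and ranks by
#' RMSE, then |ME|, then by the documented family order (spherical,
#' exponential, gaussian) as tie-break. A family whose fit fails is
#' recorded and excluded.
#'
#' @param points Data frame with columns `x`, `y`, `value` (>= 3 rows).
#' @param families Character vector of families to compare.
#' @param lag_width,max_dist Passed to [empirical_semivariogram()].
#' @return Data frame ranked best-first with columns `family`, `nugget`,
#'   `sill`, `range_m`, `me`, `rmse`, plus attribute `models` (the fitted
#'   `variogram_model`s) and `failed` (families that errored).
#' @export
compare_models <- function(points,
                           families = c("spherical", "exponential", "gaussian"),
                           lag_width = NULL, max_dist = NULL) {
  families <- match.arg(families, c("spherical", "exponential", "gaussian"),
                        several.ok = TRUE)
  emp <- empirical_semivariogram(points, lag_width, max_dist)
  rows <- list(); models <- list(); failed <- character()
  for (fam in families) {
    fit <- tryCatch({
      m <- fit_variogram(emp, fam)
      cv <- loo_cross_validate(points, m)
      list(m = m, cv = cv)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, fam)
      next
    }
    models[[fam]] <- fit$m
    rows[[fam]] <- data.frame(family = fam, nugget = fit$m$nugget,
                              sill = fit$m$sill, range_m = fit$m$range_m,
                              me = fit$cv$me, rmse = fit$cv$rmse,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("every variogram family failed", call. = FALSE)
  out <- do.call(rbind, rows)
  fam_rank <- match(out$family, c("spherical", "exponential", "gaussian"))
  out <- out[order(out$rmse, abs(out$me), fam_rank), ]
  rownames(out) <- NULL
  attr(out, "models") <- models
  attr(out, "failed") <- failed
  out
}

#' Write a variogram report
#'
#' Delimited text: the lag table (`lag`, `gamma_hat`, `pair_count`)
#' followed by a fitted-parameters block.
#'
#' @param emp An `empirical_variogram`.
#' @param model A fitted [variogram_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variogram_report <- function(emp, model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("lag_m\tgamma_hat\tpair_count", con)
  writeLines(sprintf("%.3f\t%.6g\t%d", emp$lag_centers, emp$gamma_hat,
                     emp$pair_counts), con)
  writeLines(c("# fitted model",
               paste0("family\t", model$family),
               paste0("nugget\t", format(model$nugget)),
               paste0("sill\t", format(model$sill)),
               paste0("range_m\t", format(model$range_m))), con)
  invisible(path)
}
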