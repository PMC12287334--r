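#' Simulate a stationary Gaussian random field at point locations
#'
#' Draws one realisation of a zero-mean Gaussian random field whose
#' covariance is \eqn{C(h) = (sill - nugget)\,\rho(h)} for the model's
#' correlation function, plus independent nugget noise of variance equal to
#' the nugget. Simulation is by Cholesky factorisation of the exact
#' covariance at the requested locations, so a dense-grid simulation
#' restricted to these points has the identical distribution. Deterministic
#' per seed.
#'
#' @param coords Data frame with columns `x`, `y` (metres); at most 8000
#'   locations (dense-matrix Cholesky).
#' @param model A [variogram_model()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of field values, one per row of `coords`.
#' @export
simulate_grf <- function(coords, model, seed = NULL) {
  stopifnot(inherits(model, "variogram_model"), nrow(coords) >= 1L)
  n <- nrow(coords)
  if (n > 8000L)
    stop("too many locations for dense Cholesky simulation (max 8000); ",
         "use a coarser grid", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  psill <- model$sill - model$nugget
  z <- if (psill > 0) {
    D <- as.matrix(stats::dist(coords[, c("x", "y")]))
    # partial-sill covariance: sill - gamma(h) already excludes the nugget
    # for h > 0; only the diagonal needs the nugget removed
    C <- model_cov(D, model)
    C[D == 0] <- psill
    L <- chol(C + diag(1e-8 * psill, n))
    as.vector(crossprod(L, stats::rnorm(n)))
  } else numeric(n)
  if (model$nugget > 0) z <- z + stats::rnorm(n, sd = sqrt(model$nugget))
  z
}

#' Simulate a Gaussian random field raster
#'
#' [simulate_grf()] evaluated at the cell centres of a regular grid.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` (m).
#' @param cellsize Cell size (m).
#' @param model A [variogram_model()].
#' @param seed Integer seed.
#' @return An [fz_raster()].
#' @export
simulate_grf_raster <- function(extent, cellsize, model, seed = NULL) {
  nc <- max(1L, round((extent[2] - extent[1]) / cellsize))
  nr <- max(1L, round((extent[4] - extent[3]) / cellsize))
  r <- fz_raster(matrix(NA_real_, nr, nc), extent[1], extent[3], cellsize)
  cc <- raster_cell_centers(r)
  z <- simulate_grf(cc, model, seed)
  r$values <- matrix(z, nr, nc, byrow = TRUE)
  r
}

#' Marginal calibration target for one soil parameter
#'
#' Two calibration methods:
#' * `"moments"` — match `mean`, `sd` and the sign/magnitude of `skew`
#'   (sinh-arcsinh shape adjustment), then clip to `[lo, hi]`.
#' * `"range"` — rank-map onto a scaled Beta(`shape1`, `shape2`) between
#'   `lo` and `hi` (used when only an observed range is available).
#'
#' @param mean,sd,skew Target moments (`moments` method; `sd > 0`).
#' @param lo,hi Bounds, `lo < hi`.
#' @param method `"moments"` or `"range"`.
#' @param shape1,shape2 Beta shapes for the range method.
#' @return Object of class `marginal_target`.
#' @export
marginal_target <- function(mean = NA_real_, sd = NA_real_, skew = 0,
                            lo, hi, method = c("moments", "range"),
                            shape1 = 2, shape2 = 2) {
  method <- match.arg(method)
  stopifnot(is.finite(lo), is.finite(hi), lo < hi)
  if (method == "moments")
    stopifnot(is.finite(mean), is.finite(sd), sd > 0, is.finite(skew))
  structure(list(mean = mean, sd = sd, skew = skew, lo = lo, hi = hi,
                 method = method, shape1 = shape1, shape2 = shape2),
            class = "marginal_target")
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

#' Rank-preserving marginal transform
#'
#' Calibrates a simulated field to a [marginal_target()] while preserving
#' the rank order of the cells (so the spatial autocorrelation structure is
#' kept). For the `moments` method the standardised field is passed through
#' a sinh-arcsinh shape map \eqn{z \mapsto \sinh(\mathrm{asinh}(z)+\epsilon)}
#' with \eqn{\epsilon} solved so the realised skewness matches the target,
#' then rescaled to the exact target mean and SD and clipped to the bounds
#' (clip fraction above 1% warns; bounds narrower than one target SD are
#' rejected as infeasible). For the `range` method values are rank-mapped
#' onto a scaled Beta distribution between the bounds.
#'
#' @param values Numeric vector (a simulated field).
#' @param target A [marginal_target()].
#' @return Calibrated numeric vector, same length and rank order.
#' @export
transform_marginal <- function(values, target) {
  stopifnot(inherits(target, "marginal_target"))
  n <- length(values)
  if (n < 3L || stats::sd(values) == 0)
    stop("field must have at least 3 distinct values", call. = FALSE)
  if (target$method == "range") {
    p <- (rank(values, ties.method = "average") - 0.5) / n
    return(target$lo + (target$hi - target$lo) *
             stats::qbeta(p, target$shape1, target$shape2))
  }
  if ((target$hi - target$lo) < target$sd)
    stop("infeasible marginal target: bounds narrower than one SD",
         call. = FALSE)
  z <- (values - mean(values)) / stats::sd(values)
  g <- function(eps) sample_skewness(sinh(asinh(z) + eps)) - target$skew
  eps <- tryCatch(stats::uniroot(g, c(-2, 2), extendInt = "upX",
                                 tol = 1e-6, maxiter = 200L)$root,
                  error = function(e) {
                    warning("target skew not attainable; using nearest ",
                            "attainable shape", call. = FALSE)
                    if (g(0) > 0) -4 else 4
                  })
  y <- sinh(asinh(z) + eps)
  y <- (y - mean(y)) / stats::sd(y)
  out <- target$mean + target$sd * y
  clipped <- out < target$lo | out > target$hi
  if (mean(clipped) > 0.01)
    warning(sprintf("marginal clipping affected %.1f%% of values",
                    100 * mean(clipped)), call. = FALSE)
  pmin(pmax(out, target$lo), target$hi)
}

#' Default marginal calibration targets for the twelve soil parameters
#'
#' Nine parameters carry published moments (mean, SD, skewness coefficient)
#' and are calibrated by the `moments` method with plausibility bounds at
#' mean +/- 4 SD (floored at 0). pH, EC and OC have published observed
#' ranges but no moments and use the `range` method between those bounds.
#' The published per-parameter summaries are internally inconsistent (each
#' observed range spans well under 3 SD, impossible for 250 samples), so
#' moments take precedence and the ranges act on the moment-free
#' parameters only; see the methods vignette.
#'
#' @return Named list of [marginal_target()]s.
#' @export
default_marginal_targets <- function() {
  mom <- function(mean, sd, skew)
    marginal_target(mean = mean, sd = sd, skew = skew,
                    lo = max(0, mean - 4 * sd), hi = mean + 4 * sd,
                    method = "moments")
  rng <- function(lo, hi) marginal_target(lo = lo, hi = hi, method = "range")
  list(
    pH = rng(7.46, 8.26),
    EC = rng(0.267, 0.807),
    OC = rng(0.24, 0.56),
    N  = mom(117.80, 35.14, -0.52),
    P  = mom(28.77, 7.09, -0.07),
    K  = mom(135.21, 27.71, 0.02),
    S  = mom(14.52, 6.51, -0.35),
    Fe = mom(3.06, 1.91, -0.06),
    Mn = mom(2.35, 0.29, 0.0025),
    Zn = mom(0.86, 0.17, 1.09),
    B  = mom(0.44, 0.11, 0.2637),
    Cu = mom(0.52, 0.31, 0.16))
}

#' Fishnet sampling locations
#'
#' One point per square fishnet cell (cell centre, optional uniform jitter
#' bounded by `jitter` metres), matching a one-sample-per-hectare survey
#' when `cell = 100`. The extent must tessellate into whole cells.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` (m).
#' @param cell Fishnet cell edge (m), default 100 (1 ha cells).
#' @param jitter Maximum absolute jitter (m), 0-`cell`/2; default 0.
#' @param seed Integer seed (used only when `jitter > 0`).
#' @return Data frame `x`, `y`, one row per cell, row-major from the
#'   south-west cell.
#' @export
#' @examples
#' nrow(fishnet_sample(c(0, 2500, 0, 1000)))  # 250 points = 250 ha
fishnet_sample <- function(extent, cell = 100, jitter = 0, seed = NULL) {
  stopifnot(length(extent) == 4L, cell > 0, jitter >= 0, jitter <= cell / 2)
  w <- extent[2] - extent[1]
  h <- extent[4] - extent[3]
  if (w <= 0 || h <= 0) stop("degenerate extent", call. = FALSE)
  nx <- round(w / cell); ny <- round(h / cell)
  if (nx < 1L || ny < 1L || abs(nx * cell - w) > 1e-6 || abs(ny * cell - h) > 1e-6)
    stop("extent must tessellate into whole fishnet cells", call. = FALSE)
  pts <- expand.grid(x = extent[1] + (seq_len(nx) - 0.5) * cell,
                     y = extent[3] + (seq_len(ny) - 0.5) * cell)
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts$x <- pts$x + stats::runif(nrow(pts), -jitter, jitter)
    pts$y <- pts$y + stats::runif(nrow(pts), -jitter, jitter)
  }
  pts
}

#' Generate a calibrated synthetic soil dataset
#'
#' Builds the full synthetic survey: per-parameter spatially autocorrelated
#' Gaussian random fields at the fishnet sample locations (all sharing the
#' study's spatial model by default), an optional positive latent coupling
#' between OC and N, and rank-preserving marginal calibration to the
#' per-parameter targets. Fully reproducible: the same `seed` and
#' configuration give a bit-identical dataset.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`; default a 2,500 m x 1,000 m
#'   field (250 ha, 250 fishnet samples).
#' @param spatial_model [variogram_model()] shared by the latent fields;
#'   default the study's spherical model (nugget 5.2, sill 42.8, range
#'   3,500 m) — only its correlation shape matters after calibration.
#' @param targets Named list of [marginal_target()]s
#'   (default [default_marginal_targets()]).
#' @param oc_n_rho Latent correlation between OC and N (default 0.6).
#' @param cell Fishnet cell edge (m).
#' @param jitter Sampling jitter (m).
#' @param seed Integer seed.
#' @return Object of class `synthetic_study`: list with `samples` (the
#'   canonical soil-sample data frame), `extent`, `seed`, and `truth`
#'   (per-parameter value vectors at the sample points).
#' @export
generate_soil_dataset <- function(extent = c(0, 2500, 0, 1000),
                                  spatial_model = variogram_model("spherical",
                                                                  5.2, 42.8, 3500),
                                  targets = default_marginal_targets(),
                                  oc_n_rho = 0.6, cell = 100, jitter = 0,
                                  seed = 1L) {
  missing_t <- setdiff(SOIL_VARIABLES, names(targets))
  if (length(missing_t))
    stop("no marginal target for: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  stopifnot(oc_n_rho >= -1, oc_n_rho <= 1)
  set.seed(seed)
  pts <- fishnet_sample(extent, cell = cell, jitter = jitter)
  n <- nrow(pts)
  # one Cholesky factor shared by all latent fields
  psill <- spatial_model$sill - spatial_model$nugget
  D <- as.matrix(stats::dist(pts))
  L <- if (psill > 0) {
    C <- model_cov(D, spatial_model)
    C[D == 0] <- psill
    chol(C + diag(1e-8 * psill, n))
  } else NULL
  draw_latent <- function() {
    z <- if (!is.null(L)) as.vector(crossprod(L, stats::rnorm(n))) else numeric(n)
    if (spatial_model$nugget > 0)
      z <- z + stats::rnorm(n, sd = sqrt(spatial_model$nugget))
    z
  }
  latent <- list()
  for (v in SOIL_VARIABLES) latent[[v]] <- draw_latent()
  # positive latent coupling between organic carbon and nitrogen
  latent$N <- oc_n_rho * scale(latent$OC)[, 1] * stats::sd(latent$N) +
    sqrt(1 - oc_n_rho^2) * latent$N
  truth <- lapply(SOIL_VARIABLES, function(v)
    transform_marginal(latent[[v]], targets[[v]]))
  names(truth) <- SOIL_VARIABLES
  samples <- data.frame(id = sprintf("S%03d", seq_len(n)),
                        x = pts$x, y = pts$y, stringsAsFactors = FALSE)
  for (v in SOIL_VARIABLES) samples[[v]] <- truth[[v]]
  validate_soil_samples(samples)
  structure(list(samples = samples, extent = extent, seed = seed,
                 spatial_model = spatial_model, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d samples over %g ha, seed %d>\n",
              nrow(x$samples),
              (x$extent[2] - x$extent[1]) * (x$extent[4] - x$extent[3]) / 1e4,
              x$seed))
  invisible(x)
}

#' Default crop yield-response parameters
#'
#' Linear yield response `yield = intercept + slope * fertility` (kg/ha per
#' score point) with per-crop target coefficients of determination from the
#' published crop ranking. Baselines reflect typical semi-arid Rajasthan
#' productivity with wheat > mustard > barley > pearl millet.
#'
#' @return Data frame `crop`, `target_r2`, `intercept`, `slope`.
#' @export
default_crop_params <- function() {
  data.frame(
    crop = c("pearl_millet", "mustard", "wheat", "barley"),
    target_r2 = c(0.919, 0.890, 0.863, 0.861),
    intercept = c(900, 1900, 2500, 1500),
    slope = c(18, 22, 30, 20),
    stringsAsFactors = FALSE)
}

#' Generate fertility-coupled synthetic yield records
#'
#' Yields follow `intercept + slope * fertility + noise` with the noise
#' variance set from the target-R-squared identity
#' \eqn{\sigma^2 = \mathrm{var}(slope \cdot fertility)(1-R^2)/R^2}, so the
#' expected OLS R-squared of mean yield on fertility equals `target_r2`.
#' Per-season records are the point's mean yield plus season deviations
#' centred to zero (so the multi-season mean reproduces the coupling
#' exactly); a small fraction is flagged `previous_season_substitute`. One
#' additional `farmer_reported` record per point (season `"survey"`)
#' carries the harvested reference used for the survey-RMSE check.
#'
#' @param points Data frame `x`, `y` of yield locations.
#' @param fertility Fertility score at each point (nonzero variance).
#' @param crop Crop name.
#' @param target_r2 Target coefficient of determination in (0, 1).
#' @param intercept,slope Yield response (kg/ha, kg/ha per score point).
#' @param n_seasons Number of measured seasons (default 3).
#' @param season_sd SD of per-season deviations (kg/ha).
#' @param survey_sd SD of the farmer-reported reference error (kg/ha).
#' @param substitute_frac Fraction of season records flagged as
#'   previous-season substitutes.
#' @param seed Integer seed.
#' @return Data frame of yield records (`x, y, crop, season,
#'   quadrat_mass_kg, source`).
#' @export
generate_yields <- function(points, fertility, crop, target_r2,
                            intercept, slope, n_seasons = 3L,
                            season_sd = 150, survey_sd = 200,
                            substitute_frac = 0.05, seed = 1L) {
  n <- nrow(points)
  stopifnot(length(fertility) == n, n >= 3L)
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must lie in (0, 1)", call. = FALSE)
  if (stats::var(fertility) == 0)
    stop("fertility has zero variance", call. = FALSE)
  set.seed(seed)
  signal <- intercept + slope * fertility
  sigma <- stats::sd(slope * fertility) * sqrt((1 - target_r2) / target_r2)
  ymean <- signal + stats::rnorm(n, sd = sigma)
  if (any(ymean < 0)) {
    warning(sum(ymean < 0), " negative yield(s) clipped at 0", call. = FALSE)
    ymean <- pmax(ymean, 0)
  }
  recs <- list()
  for (s in seq_len(n_seasons)) recs[[s]] <- ymean
  if (n_seasons > 1L) {
    dev <- matrix(stats::rnorm(n * n_seasons, sd = season_sd), n, n_seasons)
    dev <- dev - rowMeans(dev)  # centred: seasonal mean == ymean exactly
    for (s in seq_len(n_seasons)) recs[[s]] <- pmax(ymean + dev[, s], 0)
  }
  sub_flag <- matrix(stats::runif(n * n_seasons) < substitute_frac,
                     n, n_seasons)
  out <- do.call(rbind, lapply(seq_len(n_seasons), function(s)
    data.frame(x = points$x, y = points$y, crop = crop,
               season = sprintf("season_%d", s),
               quadrat_mass_kg = recs[[s]] / 10000,
               source = ifelse(sub_flag[, s], "previous_season_substitute",
                               "measured"),
               stringsAsFactors = FALSE)))
  survey <- data.frame(x = points$x, y = points$y, crop = crop,
                       season = "survey",
                       quadrat_mass_kg = pmax(ymean +
                         stats::rnorm(n, sd = survey_sd), 0) / 10000,
                       source = "farmer_reported", stringsAsFactors = FALSE)
  rbind(out, survey)
}
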