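#' Crops covered by the yield survey
#' @keywords internal
YIELD_CROPS <- c("pearl_millet", "wheat", "mustard", "barley")

YIELD_SOURCES <- c("measured", "previous_season_substitute", "farmer_reported")

#' Convert a 1 m2 quadrat harvest to kg/ha
#'
#' `kg/ha = quadrat mass (kg) x 10,000`.
#'
#' @param mass_kg Harvested mass from a 1 m2 quadrat, >= 0.
#' @return Yield in kg/ha.
#' @export
#' @examples
#' quadrat_to_hectare(0.35)  # 3500
quadrat_to_hectare <- function(mass_kg) {
  if (any(!is.finite(mass_kg)) || any(mass_kg < 0))
    stop("quadrat mass must be finite and >= 0", call. = FALSE)
  mass_kg * 10000
}

#' Multi-season mean yield
#'
#' Arithmetic mean of the per-season yields at one point.
#'
#' @param yields Numeric vector, one value per season (>= 1).
#' @param n_seasons Expected season count; must equal `length(yields)`.
#' @return The mean yield.
#' @export
mean_seasonal_yield <- function(yields, n_seasons = length(yields)) {
  if (!length(yields)) stop("no seasonal yields supplied", call. = FALSE)
  if (n_seasons != length(yields))
    stop("n_seasons (", n_seasons, ") != number of yields (",
         length(yields), ")", call. = FALSE)
  mean(yields)
}

#' Root mean square error between sampled and harvested yields
#'
#' @param sampled,harvested Equal-length numeric vectors.
#' @return \eqn{\sqrt{\frac1n \sum (sampled_i - harvested_i)^2}}.
#' @export
yield_rmse <- function(sampled, harvested) {
  if (length(sampled) != length(harvested) || !length(sampled))
    stop("sampled and harvested must be equal-length, nonempty",
         call. = FALSE)
  sqrt(mean((sampled - harvested)^2))
}

#' Tukey fence (IQR) outlier filter
#'
#' Removes values outside \eqn{[Q_1 - k\,IQR,\; Q_3 + k\,IQR]} with
#' quartiles computed by linear interpolation between order statistics
#' (`stats::quantile` type 7). With fewer than 4 values the input is passed
#' through unchanged with a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (conventional 1.5).
#' @return List with `kept` and `removed`.
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    warning("fewer than 4 values: IQR filter passed through", call. = FALSE)
    return(list(kept = values, removed = numeric(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
  out <- values < fence[1] | values > fence[2]
  list(kept = values[!out], removed = values[out])
}

#' Ordinary least squares of yield on fertility
#'
#' Fits `yield ~ fertility` by OLS (via [stats::lm()]) and reports slope,
#' intercept and \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param fertility Numeric predictor (nonzero variance, >= 3 values).
#' @param yield_kg_ha Numeric response, same length.
#' @return List `slope`, `intercept`, `r_squared`.
#' @export
regress_fertility_yield <- function(fertility, yield_kg_ha) {
  if (length(fertility) != length(yield_kg_ha) || length(fertility) < 3L)
    stop("need equal-length vectors with at least 3 observations",
         call. = FALSE)
  if (stats::var(fertility) == 0)
    stop("fertility has zero variance", call. = FALSE)
  fit <- stats::lm(yield_kg_ha ~ fertility)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F statistic with Satterthwaite-type denominator degrees of
#' freedom, for comparing group means under unequal variances:
#' \deqn{F = \frac{\sum w_i (\bar x_i - \bar x_w)^2 / (k-1)}
#'            {1 + \frac{2(k-2)}{k^2-1} \Lambda}}
#' with \eqn{w_i = n_i/s_i^2}, \eqn{\bar x_w = \sum w_i \bar x_i / \sum w_i}
#' and \eqn{\Lambda = \sum \frac{(1-w_i/\sum w)^2}{n_i - 1}};
#' \eqn{df_2 = (k^2-1)/(3\Lambda)}.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values
#'   with positive variance).
#' @return List `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  s2 <- vapply(groups, stats::var, numeric(1))
  if (any(s2 <= 0)) stop("zero-variance group", call. = FALSE)
  m <- vapply(groups, mean, numeric(1))
  w <- n / s2
  sw <- sum(w)
  xw <- sum(w * m) / sw
  lambda <- sum((1 - w / sw)^2 / (n - 1))
  Fstat <- (sum(w * (m - xw)^2) / (k - 1)) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' For every group pair: mean difference, Welch-type standard error and
#' degrees of freedom, and a studentized-range p-value
#' \eqn{p = P(q_{k,df} > \sqrt{2}\,|t|)} (via [stats::ptukey()]). Suitable
#' after [welch_anova()] under unequal variances.
#'
#' @param groups Named (or unnamed) list of numeric vectors, as for
#'   [welch_anova()].
#' @return Data frame `group1`, `group2`, `diff`, `se`, `df`, `t`, `p`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  s2 <- vapply(groups, stats::var, numeric(1))
  if (any(s2 <= 0)) stop("zero-variance group", call. = FALSE)
  m <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2)
  out <- data.frame(group1 = nms[pairs[1, ]], group2 = nms[pairs[2, ]],
                    diff = NA_real_, se = NA_real_, df = NA_real_,
                    t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    vi <- s2[i] / n[i]; vj <- s2[j] / n[j]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    t <- (m[i] - m[j]) / se
    out$diff[c] <- m[i] - m[j]
    out$se[c] <- se
    out$df[c] <- df
    out$t[c] <- t
    out$p[c] <- stats::ptukey(sqrt(2) * abs(t), nmeans = k, df = df,
                              lower.tail = FALSE)
  }
  out
}

#' Read yield records from delimited text
#'
#' Expects columns `x, y, crop, season, quadrat_mass_kg, source` (crop one
#' of `pearl_millet, wheat, mustard, barley`; source one of `measured,
#' previous_season_substitute, farmer_reported`).
#'
#' @param path CSV file.
#' @return Data frame of validated yield records.
#' @export
read_yield_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "crop", "season", "quadrat_mass_kg", "source")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("yield file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(df$crop %in% YIELD_CROPS))
    stop("unknown crop: ", paste(setdiff(unique(df$crop), YIELD_CROPS),
                                 collapse = ", "), call. = FALSE)
  if (!all(df$source %in% YIELD_SOURCES))
    stop("unknown source: ", paste(setdiff(unique(df$source), YIELD_SOURCES),
                                   collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$quadrat_mass_kg)) || any(df$quadrat_mass_kg < 0))
    stop("quadrat_mass_kg must be finite and >= 0", call. = FALSE)
  df
}

#' Validate fertility zonation against crop yields
#'
#' For each crop: reads the fertility score at every yield point from the
#' kriged raster (cell containing the point), averages the measured
#' per-season yields per point, removes yield outliers with the IQR
#' method, regresses mean yield on fertility, and — across the fertility
#' classes present — runs Welch's ANOVA and Games-Howell post-hoc
#' comparisons of yield. Records flagged `farmer_reported` are used as the
#' harvested reference for the sampled-vs-harvested RMSE;
#' `previous_season_substitute` records are retained in the seasonal mean
#' but counted in the report.
#'
#' Crops with fewer than 3 matched points are skipped with a warning.
#'
#' @param yields Data frame from [read_yield_records()].
#' @param raster An [fz_raster()] of fertility scores.
#' @param iqr_k IQR fence multiplier.
#' @return Object of class `validation_report`: per-crop list with
#'   `n`, `slope`, `intercept`, `r_squared`, `welch` (F/df1/df2/p),
#'   `games_howell` (pairwise table or NULL), `yield_rmse_kg_ha`,
#'   `n_outliers_removed`, `n_substituted`.
#' @export
validate_fertility_yield <- function(yields, raster, iqr_k = 1.5) {
  stopifnot(inherits(raster, "fz_raster"))
  report <- list()
  for (crop in intersect(YIELD_CROPS, unique(yields$crop))) {
    yc <- yields[yields$crop == crop, ]
    meas <- yc[yc$source != "farmer_reported", ]
    if (!nrow(meas)) next
    key <- paste(meas$x, meas$y)
    pts <- !duplicated(key)
    px <- meas$x[pts]; py <- meas$y[pts]
    ymean <- vapply(split(quadrat_to_hectare(meas$quadrat_mass_kg), key),
                    mean, numeric(1))[paste(px, py)]
    fert <- raster_extract(raster, px, py)
    ok <- !is.na(fert) & !is.na(ymean)
    if (sum(ok) < 3L) {
      warning("crop '", crop, "': fewer than 3 matched points, skipped",
              call. = FALSE)
      next
    }
    px <- px[ok]; py <- py[ok]; ymean <- ymean[ok]; fert <- fert[ok]
    filt <- iqr_filter(ymean, k = iqr_k)
    keep <- !(ymean %in% filt$removed)
    ymean <- ymean[keep]; fert <- fert[keep]; px <- px[keep]; py <- py[keep]
    reg <- regress_fertility_yield(fert, ymean)
    cls <- classify_score(pmin(pmax(fert, 0), 100))
    grp <- split(ymean, droplevels(cls))
    grp <- grp[vapply(grp, function(g)
      length(g) >= 2L && stats::var(g) > 0, logical(1))]
    wa <- if (length(grp) >= 2L) welch_anova(grp) else NULL
    gh <- if (length(grp) >= 2L) games_howell(grp) else NULL
    # harvested reference: farmer-reported records at matching points
    farm <- yc[yc$source == "farmer_reported", ]
    rmse <- NA_real_
    if (nrow(farm)) {
      fkey <- paste(farm$x, farm$y)
      mkey <- paste(px, py)
      shared <- intersect(mkey, fkey)
      if (length(shared)) {
        harvested <- quadrat_to_hectare(
          farm$quadrat_mass_kg[match(shared, fkey)])
        rmse <- yield_rmse(ymean[match(shared, mkey)], harvested)
      }
    }
    report[[crop]] <- list(
      n = length(ymean), slope = reg$slope, intercept = reg$intercept,
      r_squared = reg$r_squared, welch = wa, games_howell = gh,
      yield_rmse_kg_ha = rmse,
      n_outliers_removed = length(filt$removed),
      n_substituted = sum(meas$source == "previous_season_substitute"))
  }
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (crop in names(x)) {
    r <- x[[crop]]
    cat(sprintf("  %-12s n=%d R2=%.3f slope=%.2f", crop, r$n, r$r_squared,
                r$slope))
    if (!is.null(r$welch))
      cat(sprintf(" WelchF=%.1f (p=%.3g)", r$welch$F, r$welch$p))
    if (is.finite(r$yield_rmse_kg_ha))
      cat(sprintf(" RMSE=%.0f kg/ha", r$yield_rmse_kg_ha))
    cat("\n")
  }
  invisible(x)
}

#' Write a validation report (text + JSON)
#'
#' @param report A `validation_report`.
#' @param path Output stem; writes `<path>.txt` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"))
  ser <- lapply(unclass(report), function(r) {
    r$games_howell <- if (!is.null(r$games_howell))
      as.list(r$games_howell) else NULL
    r
  })
  jsonlite::write_json(ser, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
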