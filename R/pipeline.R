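#' Default pipeline configuration
#'
#' A plain named list consumed by the `run_*` stage functions. Paths are
#' resolved under `out_dir`; coordinates are projected metres throughout
#' (no CRS transforms — the CRS is metadata only).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param extent Field extent `c(xmin, xmax, ymin, ymax)` (m); default
#'   2,500 m x 1,000 m = 250 ha.
#' @param resolution Kriged-map cell size (m), default 10.
#' @return Named configuration list.
#' @export
fz_config <- function(out_dir = "fertzone_run", seed = 1L,
                      extent = c(0, 2500, 0, 1000), resolution = 10) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    extent = extent,
    resolution = resolution,
    variables_file = NULL,   # NULL = packaged defaults
    rules_file = NULL,
    delta = 0.1,
    variogram = list(family = "spherical", fit = TRUE,
                     nugget = 5.2, sill = 42.8, range_m = 3500,
                     lag_width = NULL, max_dist = NULL),
    zonation = list(min_region_cells = 20L, majority_window = 10L),
    generator = list(
      spatial = list(family = "spherical", nugget = 5.2, sill = 42.8,
                     range_m = 3500),
      oc_n_rho = 0.6, cell = 100, jitter = 0, n_seasons = 3L,
      truth_rasters = TRUE),
    crops = default_crop_params(),
    paths = list(samples = "samples.csv", yields = "yields.csv",
                 scored = "scored.csv", fertility = "fertility.asc",
                 variogram = "variogram.tsv", zones = "zones.asc",
                 zones_contig = "zones_contiguous.asc",
                 areas = "zone_areas.csv",
                 areas_contig = "zone_areas_contiguous.csv",
                 validation = "validation", manifest = "manifest.json"))
}

cfg_path <- function(cfg, key) file.path(cfg$out_dir, cfg$paths[[key]])

cfg_variables <- function(cfg) {
  if (is.null(cfg$variables_file)) default_soil_variables()
  else read_soil_variables(cfg$variables_file)
}

cfg_rules <- function(cfg) {
  if (is.null(cfg$rules_file)) default_rule_base()
  else parse_rules(cfg$rules_file, cfg_variables(cfg))
}

cfg_generator_model <- function(cfg) {
  s <- cfg$generator$spatial
  variogram_model(s$family, s$nugget, s$sill, s$range_m)
}

#' Generate the synthetic study files
#'
#' Writes the soil-sample CSV, the per-crop yield CSV, and (optionally)
#' per-parameter truth rasters. Yield generation needs the fertility truth
#' at the sample points, which is the Mamdani score of the generated
#' samples (yields are surveyed at the same grid locations as the soil
#' samples).
#'
#' @param cfg Configuration from [fz_config()].
#' @return Invisible list of written paths.
#' @export
run_generate <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- cfg$generator
  study <- generate_soil_dataset(
    extent = cfg$extent, spatial_model = cfg_generator_model(cfg),
    oc_n_rho = gen$oc_n_rho, cell = gen$cell, jitter = gen$jitter,
    seed = cfg$seed)
  write_soil_samples(study$samples, cfg_path(cfg, "samples"))
  written <- list(samples = cfg_path(cfg, "samples"))
  if (isTRUE(gen$truth_rasters)) {
    nxc <- round((cfg$extent[2] - cfg$extent[1]) / gen$cell)
    nyc <- round((cfg$extent[4] - cfg$extent[3]) / gen$cell)
    for (v in SOIL_VARIABLES) {
      # samples run row-major from the south-west; raster rows are
      # north-first, so fill by row and flip
      m <- matrix(study$truth[[v]], nyc, nxc, byrow = TRUE)
      r <- fz_raster(m[rev(seq_len(nyc)), , drop = FALSE],
                     cfg$extent[1], cfg$extent[3], gen$cell)
      p <- file.path(cfg$out_dir, paste0("truth_", tolower(v), ".asc"))
      write_ascii_grid(r, p)
      written[[paste0("truth_", v)]] <- p
    }
  }
  scored <- score_samples(study$samples, cfg_variables(cfg), cfg_rules(cfg),
                          delta = cfg$delta)
  fert <- scored$fertility_score
  crops <- cfg$crops
  yields <- do.call(rbind, lapply(seq_len(nrow(crops)), function(i)
    generate_yields(study$samples[, c("x", "y")], fert,
                    crop = crops$crop[i], target_r2 = crops$target_r2[i],
                    intercept = crops$intercept[i], slope = crops$slope[i],
                    n_seasons = cfg$generator$n_seasons,
                    seed = cfg$seed + i)))
  utils::write.csv(yields, cfg_path(cfg, "yields"), row.names = FALSE,
                   quote = FALSE)
  written$yields <- cfg_path(cfg, "yields")
  invisible(written)
}

#' Score the soil samples
#'
#' Reads the sample CSV, runs fuzzification + Mamdani inference + centroid
#' defuzzification, writes the scored CSV. Aborts (with the offending rows
#' listed) if any sample failed.
#'
#' @param cfg Configuration from [fz_config()].
#' @return Invisible path of the scored CSV.
#' @export
run_score <- function(cfg) {
  samples <- read_soil_samples(cfg_path(cfg, "samples"))
  scored <- score_samples(samples, cfg_variables(cfg), cfg_rules(cfg),
                          delta = cfg$delta)
  bad <- which(!is.na(scored$error))
  if (length(bad))
    stop("scoring failed for rows: ", paste(bad, collapse = ", "), " (",
         scored$error[bad[1]], ")", call. = FALSE)
  write_scored_samples(scored, cfg_path(cfg, "scored"))
  invisible(cfg_path(cfg, "scored"))
}

#' Map fertility: variogram, kriging, zonation
#'
#' Reads the scored CSV; fits the configured semivariogram family to the
#' scores (or uses the imposed parameters when `cfg$variogram$fit` is
#' `FALSE`); writes the variogram report, the kriged fertility surface at
#' the configured resolution, the banded zone raster, the contiguous
#' (smoothed) zone raster and both area summaries.
#'
#' @param cfg Configuration from [fz_config()].
#' @return Invisible list with the fitted `model` and written paths.
#' @export
run_map <- function(cfg) {
  sc <- utils::read.csv(cfg_path(cfg, "scored"), stringsAsFactors = FALSE)
  pts <- data.frame(x = sc$x, y = sc$y, value = sc$fertility_score)
  vg <- cfg$variogram
  emp <- empirical_semivariogram(pts, vg$lag_width, vg$max_dist)
  model <- if (isTRUE(vg$fit)) fit_variogram(emp, vg$family)
           else variogram_model(vg$family, vg$nugget, vg$sill, vg$range_m)
  write_variogram_report(emp, model, cfg_path(cfg, "variogram"))
  r <- krige_grid(pts, model, cfg$extent, cfg$resolution)
  r$values <- pmin(pmax(r$values, 0), 100)  # scores live on [0, 100]
  write_ascii_grid(r, cfg_path(cfg, "fertility"))
  z <- classify_raster(r, "bands")
  write_zone_map(z, cfg_path(cfg, "zones"))
  utils::write.csv(area_fractions(z), cfg_path(cfg, "areas"),
                   row.names = FALSE)
  zc <- contiguity_smooth(z, cfg$zonation$min_region_cells,
                          cfg$zonation$majority_window)
  write_zone_map(zc, cfg_path(cfg, "zones_contig"))
  utils::write.csv(area_fractions(zc), cfg_path(cfg, "areas_contig"),
                   row.names = FALSE)
  invisible(list(model = model, fertility = cfg_path(cfg, "fertility")))
}

#' Validate fertility against yields
#'
#' Reads the yield CSV and the kriged fertility raster, runs the per-crop
#' regression / Welch ANOVA / Games-Howell / survey-RMSE battery and
#' writes the validation report (text + JSON).
#'
#' @param cfg Configuration from [fz_config()].
#' @return Invisible `validation_report`.
#' @export
run_validate <- function(cfg) {
  yields <- read_yield_records(cfg_path(cfg, "yields"))
  r <- read_ascii_grid(cfg_path(cfg, "fertility"))
  report <- validate_fertility_yield(yields, r)
  write_validation_report(report, cfg_path(cfg, "validation"))
  invisible(report)
}

#' Run the full pipeline
#'
#' `generate`, `score`, `map`, `validate` in sequence, then writes the run
#' manifest (config hash, package version, per-file MD5 checksums, stage
#' timings) atomically.
#'
#' @param cfg Configuration from [fz_config()].
#' @return Invisible manifest list.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(generate = run_generate, score = run_score,
                 map = run_map, validate = run_validate)
  timings <- list()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    stages[[nm]](cfg)
    timings[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  write_manifest(cfg, timings)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, timings = list()) {
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% cfg$paths$manifest]
  manifest <- list(
    package = "fertzone",
    version = as.character(utils::packageVersion("fertzone")),
    seed = cfg$seed,
    config_md5 = config_hash(cfg),
    timings_s = timings,
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  tmp <- tempfile(tmpdir = cfg$out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, cfg_path(cfg, "manifest"))
  invisible(manifest)
}
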