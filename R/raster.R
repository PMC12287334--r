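#' In-memory single-band raster
#'
#' A minimal gridded-surface container: a numeric matrix in row-major
#' map order (row 1 = northernmost row), square cells, lower-left corner
#' registration of the grid and cell-centre registration of values. Nodata
#' cells carry `NA` in memory and the `nodata` value (-9999 by default) on
#' disk.
#'
#' @param values Numeric matrix; `values[1, 1]` is the north-west cell.
#' @param xll,yll Coordinates (m) of the grid's lower-left corner.
#' @param cellsize Cell edge length (m), > 0.
#' @param nodata Sentinel written to disk for `NA` cells.
#' @return Object of class `fz_raster`.
#' @export
fz_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0,
            is.finite(xll), is.finite(yll))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "fz_raster")
}

#' @export
print.fz_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<fz_raster %d x %d @ %g m, origin (%g, %g)>\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  if (length(v))
    cat(sprintf("  values: [%.3f, %.3f], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.fz_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster
#'
#' @param r An `fz_raster`.
#' @return Data frame `x`, `y`, `row`, `col` in row-major order (north-west
#'   first), matching `as.vector(t(r$values))`.
#' @export
raster_cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), times = nr)
  row <- rep(seq_len(nr), each = nc)
  data.frame(x = r$xll + (col - 0.5) * r$cellsize,
             y = r$yll + (nr - row + 0.5) * r$cellsize,
             row = row, col = col)
}

#' Extract raster values at point locations
#'
#' Each point takes the value of the cell containing it (nearest cell
#' centre at cell boundaries); points outside the grid return `NA`.
#'
#' @param r An `fz_raster`.
#' @param x,y Numeric coordinate vectors (m).
#' @return Numeric vector of cell values.
#' @export
raster_extract <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1L
  row <- nr - floor((y - r$yll) / r$cellsize)
  # points on the top/right edge belong to the edge cell
  col[x == r$xll + nc * r$cellsize] <- nc
  row[y == r$yll + nr * r$cellsize] <- 1L
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by all common GIS tools
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows north to south).
#'
#' @param r An `fz_raster`.
#' @param path Output file (conventionally `.asc`).
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xll, scientific = FALSE)),
    paste("yllcorner", format(r$yll, scientific = FALSE)),
    paste("cellsize", format(r$cellsize, scientific = FALSE)),
    paste("NODATA_value", r$nodata)), con)
  utils::write.table(signif(v, digits), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Input `.asc` file.
#' @return An `fz_raster` (`NODATA_value` cells become `NA`).
#' @export
read_ascii_grid <- function(path) {
  hdr_lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in hdr_lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  fz_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
            nodata = hdr$nodata_value)
}
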