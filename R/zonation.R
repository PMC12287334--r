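#' Classify a fertility raster into zones
#'
#' Either the five published score bands (`scheme = "bands"`; see
#' [classify_score()]) or `n_bins` equal-interval display bins over the
#' observed score range (`scheme = "equal_interval"`, the convention used to
#' subdivide low-fertility zones for display). Nodata cells are preserved.
#'
#' @param r An [fz_raster()] of scores in \[0, 100\].
#' @param scheme `"bands"` or `"equal_interval"`.
#' @param n_bins Number of equal-interval bins (equal-interval scheme only).
#' @return Object of class `zone_map`: list with `codes` (integer matrix,
#'   `NA` = nodata), `legend` (code -> label data frame), and the grid
#'   geometry of `r`.
#' @export
classify_raster <- function(r, scheme = c("bands", "equal_interval"),
                            n_bins = 6L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(r, "fz_raster"))
  v <- r$values
  if (all(is.na(v))) stop("empty raster: all cells are nodata", call. = FALSE)
  if (scheme == "bands") {
    ok <- !is.na(v)
    if (any(v[ok] < 0 | v[ok] > 100))
      stop("scores outside [0, 100]", call. = FALSE)
    codes <- matrix(NA_integer_, nrow(v), ncol(v))
    codes[ok] <- findInterval(v[ok], FERTILITY_BANDS$lo)
    legend <- data.frame(code = seq_len(nrow(FERTILITY_BANDS)),
                         label = FERTILITY_BANDS$label,
                         lo = FERTILITY_BANDS$lo, hi = FERTILITY_BANDS$hi,
                         stringsAsFactors = FALSE)
  } else {
    n_bins <- as.integer(n_bins)
    stopifnot(n_bins >= 1L)
    rng <- range(v, na.rm = TRUE)
    width <- (rng[2] - rng[1]) / n_bins
    brk <- rng[1] + width * seq_len(n_bins - 1L)
    codes <- matrix(NA_integer_, nrow(v), ncol(v))
    ok <- !is.na(v)
    codes[ok] <- findInterval(v[ok], brk) + 1L
    legend <- data.frame(code = seq_len(n_bins),
                         label = sprintf("bin %d", seq_len(n_bins)),
                         lo = rng[1] + width * (seq_len(n_bins) - 1L),
                         hi = rng[1] + width * seq_len(n_bins),
                         stringsAsFactors = FALSE)
  }
  structure(list(codes = codes, legend = legend, xll = r$xll, yll = r$yll,
                 cellsize = r$cellsize),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map %d x %d, %d class(es)>\n", nrow(x$codes),
              ncol(x$codes), length(unique(stats::na.omit(as.vector(x$codes))))))
  invisible(x)
}

#' Per-class area fractions of a zone map
#'
#' Fractions are computed over the non-nodata cells and sum to 100%.
#'
#' @param z A `zone_map`.
#' @return Data frame `code`, `label`, `cells`, `fraction_pct`.
#' @export
area_fractions <- function(z) {
  stopifnot(inherits(z, "zone_map"))
  codes <- as.vector(z$codes)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("all-nodata zone map", call. = FALSE)
  cnt <- table(factor(codes, levels = z$legend$code))
  data.frame(code = z$legend$code, label = z$legend$label,
             cells = as.integer(cnt),
             fraction_pct = 100 * as.integer(cnt) / length(codes),
             stringsAsFactors = FALSE)
}

# box-sum counts of a binary matrix over a (2r+1)x(2r+1) window via
# summed-area table; NA-safe (NA treated as 0).
box_count <- function(mask, r) {
  m <- mask * 1
  m[is.na(m)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  sat <- apply(m, 2L, cumsum)
  if (nr == 1L) sat <- matrix(sat, 1L, nc)
  sat <- t(apply(sat, 1L, cumsum))
  if (nc == 1L) sat <- matrix(sat, nr, 1L)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- sat  # S[i+1, j+1] = sum m[1:i, 1:j]
  i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
  S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
    S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

majority_filter <- function(codes, window) {
  # window = full extent of the square neighbourhood; even extents are
  # widened to the next odd so the window stays centred (documented
  # convention). Ties keep the current cell's class when it participates,
  # else the lowest class code.
  r <- max(1L, floor(window / 2))
  classes <- sort(unique(stats::na.omit(as.vector(codes))))
  if (length(classes) <= 1L) return(codes)
  counts <- lapply(classes, function(k) box_count(codes == k, r))
  best <- matrix(classes[1], nrow(codes), ncol(codes))
  bestn <- counts[[1]]
  for (k in seq_along(classes)[-1]) {
    swap <- counts[[k]] > bestn
    best[swap] <- classes[k]
    bestn[swap] <- counts[[k]][swap]
  }
  # keep the incumbent class on ties
  for (k in seq_along(classes)) {
    tie <- !is.na(codes) & codes == classes[k] & counts[[k]] == bestn
    best[tie] <- classes[k]
  }
  best[is.na(codes)] <- NA_integer_
  best
}

# connected components of equal-valued cells (8-connectivity) via igraph
label_regions <- function(codes) {
  nr <- nrow(codes); nc <- ncol(codes)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  shift_pairs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shift_pairs) {
    di <- s[1]; dj <- s[2]
    i1 <- seq_len(nr - di)
    j1 <- if (dj >= 0) seq_len(nc - dj) else seq(1L - dj, nc)
    i2 <- i1 + di; j2 <- j1 + dj
    a <- idx[i1, j1, drop = FALSE]; b <- idx[i2, j2, drop = FALSE]
    same <- !is.na(codes[i1, j1, drop = FALSE]) &
            !is.na(codes[i2, j2, drop = FALSE]) &
            codes[i1, j1, drop = FALSE] == codes[i2, j2, drop = FALSE]
    edges[[length(edges) + 1L]] <- cbind(a[same], b[same])
  }
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0L) {
    lab <- idx
    lab[is.na(codes)] <- NA_integer_
    return(lab)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nr * nc - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab <- matrix(comp[seq_len(nr * nc)], nr, nc)
  lab[is.na(codes)] <- NA_integer_
  lab
}

#' Spatially contiguous zone smoothing
#'
#' Converts a fragmented grid-based zone map into contiguous management
#' zones: (1) a majority filter over a square window; (2) 8-connected
#' region labelling; (3) regions smaller than `min_region_cells` are merged
#' into the modal class of their boundary neighbours (ties broken by the
#' lower class code), iterating until no undersized region remains (capped
#' at 10 iterations with a warning). The output class inventory is always a
#' subset of the input's.
#'
#' @param z A `zone_map`.
#' @param min_region_cells Minimum surviving region size (cells), >= 1;
#'   default 20.
#' @param majority_window Full extent of the majority-filter window in
#'   cells (default 10; even extents widen to the next odd so the window is
#'   centred).
#' @return A smoothed `zone_map`.
#' @export
contiguity_smooth <- function(z, min_region_cells = 20L, majority_window = 10L) {
  stopifnot(inherits(z, "zone_map"), min_region_cells >= 1L)
  codes <- majority_filter(z$codes, majority_window)
  nr <- nrow(codes); nc <- ncol(codes)
  for (iter in seq_len(10L)) {
    lab <- label_regions(codes)
    sizes <- table(as.vector(lab))
    small <- as.integer(names(sizes)[sizes < min_region_cells])
    if (!length(small)) break
    # merge each undersized region into the modal boundary-neighbour class
    newcodes <- codes
    for (rg in small) {
      cells <- which(lab == rg)
      ci <- ((cells - 1L) %% nr) + 1L
      cj <- ((cells - 1L) %/% nr) + 1L
      nb_class <- integer(0)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- ci + di; jj <- cj + dj
        ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
        v <- codes[cbind(ii[ok], jj[ok])]
        l <- lab[cbind(ii[ok], jj[ok])]
        keep <- !is.na(v) & l != rg
        nb_class <- c(nb_class, v[keep])
      }
      if (!length(nb_class)) next  # isolated island in nodata: leave as is
      tab <- table(nb_class)
      modal <- as.integer(names(tab)[tab == max(tab)])
      newcodes[cells] <- min(modal)
    }
    if (identical(newcodes, codes)) break
    codes <- newcodes
    if (iter == 10L) {
      lab <- label_regions(codes)
      if (any(table(as.vector(lab)) < min_region_cells))
        warning("contiguity smoothing hit the iteration cap with ",
                "undersized regions remaining", call. = FALSE)
    }
  }
  out <- z
  out$codes <- codes
  out
}

#' Write a zone map as an ASCII grid plus legend sidecar
#'
#' @param z A `zone_map`.
#' @param path Output `.asc` path; the legend is written next to it as
#'   `<path>.legend.tsv`.
#' @return `path`, invisibly.
#' @export
write_zone_map <- function(z, path) {
  r <- fz_raster(z$codes + 0, z$xll, z$yll, z$cellsize)
  write_ascii_grid(r, path, digits = 3)
  utils::write.table(z$legend, paste0(path, ".legend.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
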