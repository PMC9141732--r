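#' Lightweight in-memory raster
#'
#' A `land_raster` is a numeric or integer matrix with minimal georeferencing:
#' lower-left corner, square cell size in metres, and a nodata code. Rows are
#' stored north-up (row 1 is the northern edge). Categorical land-use rasters
#' use integer codes 1-6 (farmland, woodland, grassland, water area,
#' construction land, unused land) with nodata 0; continuous driver layers use
#' `NA` for nodata.
#'
#' @param values numeric or integer matrix, row 1 = north.
#' @param cellsize cell edge length in metres.
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata nodata code (0 for categorical layers, NA for continuous).
#' @return an object of class `land_raster`.
#' @export
land_raster <- function(values, cellsize = 100, xll = 0, yll = 0, nodata = NA) {
  stopifnot(is.matrix(values))
  structure(
    list(values = values, cellsize = cellsize, xll = xll, yll = yll,
         nodata = nodata),
    class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  v <- raster_values(x)
  cat(sprintf("land_raster: %d x %d cells, %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  valid cells: %d, range: [%g, %g]\n",
              sum(!is.na(v)), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.matrix.land_raster <- function(x, ...) x$values

#' Raster values with nodata replaced by NA
#' @param r a [land_raster].
#' @return matrix with nodata cells set to `NA`.
#' @export
raster_values <- function(r) {
  v <- r$values
  if (!is.na(r$nodata)) v[v == r$nodata] <- NA
  v
}

#' Cell area in hectares
#' @param r a [land_raster].
#' @export
cell_area_ha <- function(r) r$cellsize^2 / 1e4

#' Check that two rasters share geometry
#' @param a,b [land_raster] objects.
#' @return invisibly TRUE; errors if misaligned.
#' @export
check_aligned <- function(a, b) {
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
  if (!ok) stop("rasters are not aligned (dimensions or georeferencing differ)")
  invisible(TRUE)
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' north row first.
#'
#' @param path file path.
#' @param integer read values as integers (categorical maps).
#' @return a [land_raster].
#' @export
read_asc <- function(path, integer = FALSE) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  nodata <- h[["nodata_value"]]
  if (integer) {
    storage.mode(m) <- "integer"
    nodata <- as.integer(nodata)
  } else {
    m[m == nodata] <- NA
    nodata <- NA
  }
  land_raster(m, cellsize = h[["cellsize"]], xll = h[["xllcorner"]],
              yll = h[["yllcorner"]], nodata = nodata)
}

#' @rdname read_asc
#' @param r a [land_raster] to write.
#' @export
write_asc <- function(r, path) {
  m <- r$values
  nodata <- if (is.na(r$nodata)) -9999 else r$nodata
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", r$xll),
    sprintf("yllcorner %.6f", r$yll),
    sprintf("cellsize %.6f", r$cellsize),
    sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Tabulate class areas of a categorical raster
#'
#' @param lulc a categorical [land_raster] with codes 1-6.
#' @param label optional date/scenario label.
#' @return an area table: data.frame with `class_code`, `class_name`,
#'   `area_ha`.
#' @export
raster_area_table <- function(lulc, label = NULL) {
  v <- raster_values(lulc)
  counts <- tabulate(v[!is.na(v)], nbins = 6)
  area_table(counts * cell_area_ha(lulc), label = label)
}

#' Construct an area table
#'
#' @param area_ha numeric vector of six per-class areas in hectares, ordered
#'   farmland, woodland, grassland, water area, construction land, unused land.
#' @param label optional label.
#' @export
area_table <- function(area_ha, label = NULL) {
  stopifnot(length(area_ha) == 6, all(area_ha >= 0))
  out <- data.frame(class_code = 1:6, class_name = lulc_classes(),
                    area_ha = as.numeric(area_ha))
  attr(out, "label") <- label
  class(out) <- c("area_table", class(out))
  out
}

#' Land-use class names
#' @export
lulc_classes <- function() {
  c("farmland", "woodland", "grassland", "water", "construction", "unused")
}
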