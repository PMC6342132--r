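# Plain-text spatial I/O: ESRI ASCII grids and GeoJSON polygons.
# (No raster/vector GIS package is required; both formats are simple text.)

#' Read and write ESRI ASCII grid (.asc) covariate rasters
#'
#' The ESRI ASCII grid is a 6-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by rows of values from
#' the top of the grid down. `read_asc()` returns an `asc_grid` whose
#' `values` matrix is indexed `[row_from_bottom, col]`, so
#' `values[i, j]` covers x in `xll + (j-1..j) * cellsize` and y in
#' `yll + (i-1..i) * cellsize`.
#'
#' @param path File path.
#' @return `read_asc()`: an `asc_grid` list (`ncols`, `nrows`, `xll`, `yll`,
#'   `cellsize`, `nodata`, `values`). `write_asc()`: `path`, invisibly.
#' @export
read_asc <- function(path) {
  ln <- readLines(path, n = 6)
  kv <- strsplit(trimws(ln), "\\s+")
  hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                  tolower(vapply(kv, `[`, "", 1)))
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- hdr[["nrows"]]; nc <- hdr[["ncols"]]
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # store bottom row first
  nodata <- hdr[["nodata_value"]]
  if (!is.na(nodata)) m[m == nodata] <- NA
  structure(
    list(ncols = nc, nrows = nr,
         xll = hdr[["xllcorner"]], yll = hdr[["yllcorner"]],
         cellsize = hdr[["cellsize"]], nodata = nodata, values = m),
    class = "asc_grid"
  )
}

#' @rdname read_asc
#' @param grid An `asc_grid`, or a `mask_grid`/data frame with `x`, `y` and
#'   one value column named by `column`.
#' @param column Column to rasterize when `grid` is a data frame.
#' @export
write_asc <- function(grid, path, column = NULL) {
  if (!inherits(grid, "asc_grid")) {
    stopifnot(is.data.frame(grid))
    column <- column %||% setdiff(names(grid), c("x", "y"))[1]
    ux <- sort(unique(grid$x)); uy <- sort(unique(grid$y))
    cs <- min(diff(ux))
    m <- matrix(NA_real_, length(uy), length(ux))
    m[cbind(match(grid$y, uy), match(grid$x, ux))] <- as.numeric(grid[[column]])
    grid <- structure(
      list(ncols = length(ux), nrows = length(uy),
           xll = min(ux) - cs / 2, yll = min(uy) - cs / 2,
           cellsize = cs, nodata = -9999, values = m),
      class = "asc_grid"
    )
  }
  m <- grid$values
  m[is.na(m)] <- grid$nodata %||% -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", as.integer(grid$ncols)),
               sprintf("nrows %d", as.integer(grid$nrows)),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("nodata_value %g", grid$nodata %||% -9999)), con)
  writeLines(apply(m[grid$nrows:1, , drop = FALSE], 1, paste, collapse = " "), con)
  invisible(path)
}

#' Write a polygon as GeoJSON
#'
#' @param poly An `mcp` object or a data frame of boundary vertices
#'   (`x`, `y`).
#' @param path Output file.
#' @param properties Named list of feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(poly, path, properties = list()) {
  ring <- if (inherits(poly, "mcp")) poly$boundary else tibble::as_tibble(poly)
  coords <- cbind(ring$x, ring$y)
  coords <- rbind(coords, coords[1, ])  # close the ring
  feat <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(coords)),
                                  function(i) coords[i, ]))
      )
    ))
  )
  jsonlite::write_json(feat, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
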