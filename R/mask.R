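# SECR habitat-mask construction.

#' Root pooled spatial variance of detections
#'
#' A 2-D measure of the dispersion of each individual's detections about its
#' mean detection location, pooled over all individuals with at least two
#' detections:
#' `RPSV = sqrt( sum_i sum_j ((x_ij - xbar_i)^2 + (y_ij - ybar_i)^2) /
#' (2 (sum_i n_i - m)) )`,
#' where the sums run over the `m` individuals with `n_i >= 2` detections.
#' It is the usual plug-in proxy for the spatial scale `sigma` and sets the
#' default mask buffer (`3 * RPSV`). Individuals with a single detection
#' carry no spatial information and are excluded.
#'
#' @param history Detection tibble (`individual`, `occasion`, `detector`).
#' @param detectors Detector tibble giving each detector's `x`, `y`.
#' @return RPSV in km.
#' @export
rpsv <- function(history, detectors) {
  locs <- dplyr::inner_join(history, detectors[c("detector", "x", "y")],
                            by = "detector")
  counts <- table(locs$individual)
  keep <- names(counts)[counts >= 2]
  if (length(keep) == 0) {
    abort("RPSV undefined: no individual has >= 2 detections; supply a buffer manually")
  }
  locs <- locs[locs$individual %in% keep, ]
  ss <- locs |>
    dplyr::group_by(individual) |>
    dplyr::summarise(
      ss = sum((x - mean(x))^2 + (y - mean(y))^2), n = dplyr::n(),
      .groups = "drop"
    )
  sqrt(sum(ss$ss) / (2 * (sum(ss$n) - nrow(ss))))
}

#' Build a habitat mask around a detector array
#'
#' The mask (area of integration) is a square grid of cells at `spacing` km
#' whose centroids lie within `buffer` km of at least one detector; it
#' defines where activity centers may lie. The conventional buffer is three
#' times the RPSV of the detections (see [rpsv()]), applied per sex.
#'
#' @param detectors Detector tibble (`x`, `y` in km).
#' @param buffer Buffer distance in km.
#' @param spacing Grid spacing in km (cell area = `spacing^2`).
#' @return A `mask_grid` tibble of cell centroids.
#' @export
build_mask <- function(detectors, buffer, spacing) {
  if (nrow(detectors) == 0) abort("cannot build a mask around an empty detector set")
  check_scalar_pos(buffer, "buffer")
  check_scalar_pos(spacing, "spacing")
  # Centroid lattice anchored at the detector bounding box minus the buffer
  # (so detectors sit on centroids when the buffer is a multiple of spacing).
  xs <- seq(min(detectors$x) - buffer, max(detectors$x) + buffer, by = spacing)
  ys <- seq(min(detectors$y) - buffer, max(detectors$y) + buffer, by = spacing)
  g <- tidyr::expand_grid(x = xs, y = ys)
  d2 <- dist2_matrix(g, detectors)
  near <- matrixStats_rowMins(d2) <= buffer^2
  cells <- g[near, , drop = FALSE]
  # Always keep the cells that contain a detector, however small the buffer.
  if (nrow(cells) == 0) {
    kx <- xs[pmax(1, findInterval(detectors$x, xs - spacing / 2))]
    ky <- ys[pmax(1, findInterval(detectors$y, ys - spacing / 2))]
    cells <- dplyr::distinct(tibble::tibble(x = kx, y = ky))
  }
  new_mask_grid(cells, spacing)
}

# Row-wise minimum without extra dependencies.
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Clip a mask to the mapped landscape
#'
#' Drops mask cells outside the rectangle where covariates exist (the mask
#' buffer may overshoot the mapped area; activity centers are then assumed
#' confined to mapped habitat).
#'
#' @param mask A `mask_grid`.
#' @param xlim,ylim Length-2 limits in km.
#' @return The clipped `mask_grid`.
#' @export
clip_mask <- function(mask, xlim, ylim) {
  keep <- mask$x >= xlim[1] & mask$x <= xlim[2] &
    mask$y >= ylim[1] & mask$y <= ylim[2]
  new_mask_grid(tibble::as_tibble(mask)[keep, , drop = FALSE], mask_spacing(mask))
}

#' Attach gridded covariates to mask cells by point extraction
#'
#' Each mask cell takes the value of the covariate grid cell containing (or
#' nearest to) its centroid: the standard spatial point extraction on the
#' mask's x-y coordinates. A centroid falling outside a covariate grid's
#' footprint is an error naming the cell, never a silent `NA`.
#'
#' @param mask A `mask_grid`.
#' @param rasters A named list of covariate grids, each either an
#'   `asc_grid` from [read_asc()] or a data frame with columns `x`, `y` and
#'   one value column (regular grid of cell centers).
#' @return The mask with one new column per covariate (categorical grids
#'   stay factors).
#' @export
attach_covariates <- function(mask, rasters) {
  stopifnot(is.list(rasters), !is.null(names(rasters)))
  out <- mask
  for (nm in names(rasters)) {
    out[[nm]] <- extract_at(rasters[[nm]], out$x, out$y, nm)
  }
  out
}

extract_at <- function(r, x, y, nm) {
  if (inherits(r, "asc_grid")) {
    ci <- floor((x - r$xll) / r$cellsize) + 1
    ri <- floor((y - r$yll) / r$cellsize) + 1
    bad <- ci < 1 | ci > r$ncols | ri < 1 | ri > r$nrows
    if (any(bad)) {
      b <- which(bad)[1]
      abort(sprintf("mask cell (%.3f, %.3f) lies outside covariate grid '%s'",
                    x[b], y[b], nm))
    }
    v <- r$values[cbind(ri, ci)]
    if (anyNA(v)) {
      b <- which(is.na(v))[1]
      abort(sprintf("covariate '%s' is missing (NODATA) at mask cell (%.3f, %.3f)",
                    nm, x[b], y[b]))
    }
    return(v)
  }
  stopifnot(is.data.frame(r), all(c("x", "y") %in% names(r)))
  vcol <- setdiff(names(r), c("x", "y"))[1]
  ux <- sort(unique(r$x)); uy <- sort(unique(r$y))
  step_x <- if (length(ux) > 1) min(diff(ux)) else Inf
  step_y <- if (length(uy) > 1) min(diff(uy)) else Inf
  ix <- findInterval(x, ux - step_x / 2)
  iy <- findInterval(y, uy - step_y / 2)
  bad <- ix < 1 | iy < 1 |
    (is.finite(step_x) & (x > max(ux) + step_x / 2)) |
    (is.finite(step_y) & (y > max(uy) + step_y / 2))
  if (any(bad)) {
    b <- which(bad)[1]
    abort(sprintf("mask cell (%.3f, %.3f) lies outside covariate grid '%s'",
                  x[b], y[b], nm))
  }
  key <- paste(ux[pmin(ix, length(ux))], uy[pmin(iy, length(uy))])
  hit <- match(key, paste(r$x, r$y))
  if (anyNA(hit)) {
    b <- which(is.na(hit))[1]
    abort(sprintf("covariate '%s' has no value at mask cell (%.3f, %.3f)",
                  nm, x[b], y[b]))
  }
  r[[vcol]][hit]
}

#' Aggregate point detections onto an opportunistic sampling grid
#'
#' Opportunistic hair samples have no fixed trap locations; each sample is
#' assigned to the centroid of the `cell_size`-km grid cell containing it
#' (half-open cells `[origin + k*c, origin + (k+1)*c)`), and each grid cell
#' becomes a trap. Multiple samples of one individual in one cell on one
#' occasion collapse to a single binary detection.
#'
#' @param samples Tibble of point detections: `individual`, `x`, `y`, and
#'   optionally `occasion` (defaults to 1) and `sex`.
#' @param cell_size Cell side in km (the field default is 7).
#' @param origin Length-2 lower-left corner of the grid (default `c(0, 0)`).
#' @return A list with `detectors` (the nonempty cells, type `"opp"`) and
#'   `history` (deduplicated detections referencing those detectors).
#' @export
grid_opportunistic <- function(samples, cell_size = 7, origin = c(0, 0)) {
  check_scalar_pos(cell_size, "cell_size")
  if (nrow(samples) == 0) {
    return(list(
      detectors = tibble::tibble(detector = character(), x = numeric(),
                                 y = numeric(), type = factor(character(),
                                 levels = c("rub", "fence", "opp"))),
      history = tibble::tibble(individual = character(), occasion = integer(),
                               detector = character())
    ))
  }
  if (!"occasion" %in% names(samples)) samples$occasion <- 1L
  kx <- floor((samples$x - origin[1]) / cell_size)
  ky <- floor((samples$y - origin[2]) / cell_size)
  cx <- origin[1] + (kx + 0.5) * cell_size
  cy <- origin[2] + (ky + 0.5) * cell_size
  cells <- dplyr::distinct(tibble::tibble(x = cx, y = cy)) |>
    dplyr::arrange(y, x) |>
    dplyr::mutate(detector = sprintf("o%03d", dplyr::row_number()),
                  type = factor("opp", levels = c("rub", "fence", "opp"))) |>
    dplyr::select(detector, x, y, type)
  hist <- tibble::tibble(
    individual = samples$individual,
    occasion = samples$occasion,
    detector = cells$detector[match(paste(cx, cy), paste(cells$x, cells$y))]
  )
  if ("sex" %in% names(samples)) {
    hist <- dplyr::mutate(hist, sex = samples$sex, .after = "individual")
  }
  hist <- dplyr::distinct(hist) |> dplyr::arrange(individual, occasion, detector)
  list(detectors = cells, history = hist)
}
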