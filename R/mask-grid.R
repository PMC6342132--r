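# The habitat mask / landscape grid container.
#
# A mask_grid is a tibble of cell centroids (x, y in km) plus per-cell
# covariate columns, with the grid spacing (km) carried as an attribute.
# Cell area is spacing^2; total area is n_cells * spacing^2. It serves both
# as the synthetic landscape and as the SECR area of integration.

new_mask_grid <- function(cells, spacing) {
  stopifnot(all(c("x", "y") %in% names(cells)))
  check_scalar_pos(spacing, "spacing")
  tibble::new_tibble(cells, spacing = spacing, class = "mask_grid")
}

#' Grid spacing and cell area of a habitat mask
#'
#' @param mask A `mask_grid` tibble.
#' @return `mask_spacing()`: spacing in km; `cell_area()`: one cell's area in
#'   km^2; `mask_area()`: total mask area in km^2.
#' @export
mask_spacing <- function(mask) attr(mask, "spacing")

#' @rdname mask_spacing
#' @export
cell_area <- function(mask) mask_spacing(mask)^2

#' @rdname mask_spacing
#' @export
mask_area <- function(mask) nrow(mask) * cell_area(mask)

#' @export
print.mask_grid <- function(x, ...) {
  cat(sprintf("<mask_grid> %d cells, spacing %.3g km, area %.5g km^2\n",
              nrow(x), mask_spacing(x), mask_area(x)))
  NextMethod()
}
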