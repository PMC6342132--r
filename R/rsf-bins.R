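# RSF-score binning and reference-area abundance extrapolation
# (Boyce-McDonald habitat-bin method).

#' Reclassify RSF scores into equal-width habitat bins
#'
#' Scores are scaled by their maximum into `(0, 1]` and cut into `n_bins`
#' equal-width bins on `[0, 1]`; bin `i` has midpoint score
#' `w(x_i) = (i - 0.5) / n_bins` and area `A(x_i)` = number of member cells
#' times the cell area. Max-scaling makes the binning invariant to any
#' constant rescaling of the raw scores.
#'
#' @param scores Finite, non-negative raw RSF scores, one per cell.
#' @param area Cell area in km^2 (scalar, or one value per cell).
#' @param n_bins Number of bins (default 10).
#' @return An object of class `rsf_bins`: `bins` (tibble `bin`, `lo`, `hi`,
#'   `w`, `n_cells`, `area`) and `assignment` (bin index per cell).
#' @export
bin_scores <- function(scores, area, n_bins = 10) {
  if (length(scores) == 0) abort("need at least one cell")
  if (any(!is.finite(scores)) || any(scores < 0)) {
    abort("scores must be finite and non-negative")
  }
  if (max(scores) == 0) abort("all scores are zero; binning undefined")
  if (length(area) == 1) area <- rep(area, length(scores))
  scaled <- scores / max(scores)
  idx <- pmax(1L, as.integer(ceiling(scaled * n_bins)))  # (0,1] -> 1..n_bins
  bins <- tibble::tibble(
    bin = seq_len(n_bins),
    lo = (seq_len(n_bins) - 1) / n_bins,
    hi = seq_len(n_bins) / n_bins,
    w = (seq_len(n_bins) - 0.5) / n_bins,
    n_cells = as.integer(tabulate(idx, n_bins)),
    area = vapply(seq_len(n_bins), function(b) sum(area[idx == b]), numeric(1))
  )
  structure(list(bins = bins, assignment = idx, n_bins = n_bins),
            class = "rsf_bins")
}

#' Relative probability of use per habitat bin
#'
#' `U(x_i) = w(x_i) A(x_i) / sum_j w(x_j) A(x_j)`: bin midpoint score times
#' bin area, normalized so the `U` sum to 1.
#'
#' @param x An `rsf_bins` object (or its `bins` tibble with `w` and `area`).
#' @return The same object with a `U` column added to the bin table.
#' @export
expected_use <- function(x) {
  bins <- if (inherits(x, "rsf_bins")) x$bins else x
  tot <- sum(bins$w * bins$area)
  if (tot == 0) abort("sum of w * area is zero; no usable habitat")
  bins$U <- bins$w * bins$area / tot
  if (inherits(x, "rsf_bins")) {
    x$bins <- bins
    x
  } else {
    bins
  }
}

#' Restrict inference to the better habitat bins
#'
#' Drops the lowest `drop_lowest` score bins (the convention when a natural
#' break separates rarely used habitat from the rest) and returns which
#' cells remain.
#'
#' @param x An `rsf_bins` object from the global placement-bias RSF.
#' @param drop_lowest Number of lowest bins to exclude (default 3).
#' @return Logical vector over cells: `TRUE` where the cell's bin survives.
#' @export
area_of_inference <- function(x, drop_lowest = 3) {
  stopifnot(inherits(x, "rsf_bins"))
  if (drop_lowest >= x$n_bins) abort("`drop_lowest` must be < the number of bins")
  x$assignment > drop_lowest
}

#' Reference abundance estimate anchoring the extrapolation
#'
#' @param density Point density in bears/1,000 km^2 in the reference area.
#' @param lo,hi 95% CI of that density (same units).
#' @param area Reference-area size in km^2.
#' @param sex Optional label.
#' @return A `reference_estimate` object; `N_hat = density * area / 1000`.
#' @export
reference_estimate <- function(density, lo, hi, area, sex = NA_character_) {
  if (!(lo <= density && density <= hi)) abort("need lo <= density <= hi")
  check_scalar_pos(area, "area")
  structure(
    list(density = density, lo = lo, hi = hi, area = area, sex = sex,
         N_hat = density * area / 1000,
         N_lo = lo * area / 1000, N_hi = hi * area / 1000),
    class = "reference_estimate"
  )
}

#' Extrapolate density from a reference area by habitat bin
#'
#' Distributes the reference abundance over the reference-area habitat bins
#' as `N_i = N_hat * U(x_i)` and converts to per-bin density
#' `D_i = N_i / A(x_i)`; every target cell then inherits the density of its
#' bin. Confidence surfaces substitute the reference CI bounds for `N_hat`.
#' A target bin with no area in the reference bins is flagged and mapped to
#' the nearest populated bin, with a warning.
#'
#' @param reference A [reference_estimate()].
#' @param ref_bins `rsf_bins` computed over the reference-area cells (its
#'   `U` is computed here if absent).
#' @param target_bins Bin index per target cell (e.g. the `assignment` of an
#'   `rsf_bins` over the wider area, scored with the same model), or an
#'   `rsf_bins` object.
#' @return List with `bins` (reference bin table with `U`, `N_hat`, `D_hat`,
#'   `lo`, `hi` per 1,000 km^2) and `cells` (tibble `bin`, `density`, `lo`,
#'   `hi` per 1,000 km^2, one row per target cell).
#' @export
extrapolate_density <- function(reference, ref_bins, target_bins) {
  stopifnot(inherits(reference, "reference_estimate"),
            inherits(ref_bins, "rsf_bins"))
  if (!"U" %in% names(ref_bins$bins)) ref_bins <- expected_use(ref_bins)
  b <- ref_bins$bins
  b$N_hat <- reference$N_hat * b$U
  b$D_hat <- ifelse(b$area > 0, 1000 * b$N_hat / b$area, NA_real_)
  b$lo <- ifelse(b$area > 0, 1000 * reference$N_lo * b$U / b$area, NA_real_)
  b$hi <- ifelse(b$area > 0, 1000 * reference$N_hi * b$U / b$area, NA_real_)

  tb <- if (inherits(target_bins, "rsf_bins")) target_bins$assignment else target_bins
  populated <- which(b$area > 0)
  absent <- setdiff(unique(tb), populated)
  mapped <- tb
  if (length(absent)) {
    warn(sprintf("target bins absent from reference area (%s); using nearest populated bin",
                 paste(sort(absent), collapse = ", ")))
    for (bb in absent) {
      mapped[tb == bb] <- populated[which.min(abs(populated - bb))]
    }
  }
  cells <- tibble::tibble(
    bin = tb,
    density = b$D_hat[mapped],
    lo = b$lo[mapped],
    hi = b$hi[mapped]
  )
  list(bins = b, cells = cells)
}
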