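# Synthetic detector arrays.

cover_classes <- c("deciduous", "coniferous", "shrub", "grassland",
                   "agriculture", "mixed", "barren")

# Place n points in the extent, optionally hugging linear features
# (rub-object surveys follow roads, trails and fencelines).
place_points <- function(n, extent, segs = NULL, biased = TRUE, jitter_sd = 1) {
  if (n == 0) return(tibble::tibble(x = numeric(), y = numeric()))
  if (biased && !is.null(segs) && nrow(segs) > 0) {
    i <- sample.int(nrow(segs), n, replace = TRUE)
    t <- runif(n)
    x <- segs[i, 1] + t * (segs[i, 3] - segs[i, 1]) + rnorm(n, 0, jitter_sd)
    y <- segs[i, 2] + t * (segs[i, 4] - segs[i, 2]) + rnorm(n, 0, jitter_sd)
  } else {
    x <- runif(n, 0, extent[1])
    y <- runif(n, 0, extent[2])
  }
  tibble::tibble(
    x = pmin(pmax(x, 0.01), extent[1] - 0.01),
    y = pmin(pmax(y, 0.01), extent[2] - 0.01)
  )
}

#' Place rub, fence and opportunistic detectors on a landscape
#'
#' Rub objects and fenceline detectors (both treated as points) are placed
#' across the landscape, biased toward the synthetic linear features when
#' `config$detector_bias` is set. Opportunistic sampling is represented by
#' one detector at the centroid of every `opp_cell_size`-km square covering
#' the extent. Usage follows the survey design: rub/fence detectors are
#' active on occasions `1..S-1`, opportunistic detectors only on occasion
#' `S`. Each detector carries a 7-level habitat `cover` class and a
#' time-varying grizzly-bear-presence indicator (`gb_1..gb_S`, 1 = a grizzly
#' was detected there on the previous occasion).
#'
#' @param landscape A `mask_grid` from [sim_landscape()].
#' @param config The [sim_config()] used to build the landscape.
#' @return A detector tibble with columns `detector`, `x`, `y`, `type`
#'   (factor rub/fence/opp), `usage` (0/1 string, one char per occasion),
#'   `cover`, and `gb_1..gb_S`.
#' @export
sim_detectors <- function(landscape, config) {
  stopifnot(inherits(config, "sim_config"))
  n_req <- config$n_rub + config$n_fence
  if (n_req > nrow(landscape)) {
    abort(sprintf("requested %d detectors but landscape has only %d cells",
                  n_req, nrow(landscape)))
  }
  ext <- attr(landscape, "extent") %||% config$extent
  S <- config$n_occasions
  with_seed(config$seed + 1L, {
    rub <- place_points(config$n_rub, ext, attr(landscape, "roads"),
                        config$detector_bias)
    fence <- place_points(config$n_fence, ext, attr(landscape, "roads"),
                          config$detector_bias, jitter_sd = 0.3)
    cs <- config$opp_cell_size
    opp_x <- (seq_len(ceiling(ext[1] / cs)) - 0.5) * cs
    opp_y <- (seq_len(ceiling(ext[2] / cs)) - 0.5) * cs
    opp <- tidyr::expand_grid(x = opp_x, y = opp_y)

    sys_usage <- paste0(strrep("1", S - 1), "0")
    opp_usage <- paste0(strrep("0", S - 1), "1")
    det <- dplyr::bind_rows(
      dplyr::mutate(rub, type = "rub", usage = sys_usage),
      dplyr::mutate(fence, type = "fence", usage = sys_usage),
      dplyr::mutate(opp, type = "opp", usage = opp_usage)
    )
    det$detector <- sprintf("%s%03d", substr(det$type, 1, 1),
                            stats::ave(seq_len(nrow(det)), det$type, FUN = seq_along))
    det$type <- factor(det$type, levels = c("rub", "fence", "opp"))
    det$cover <- factor(sample(cover_classes, nrow(det), replace = TRUE),
                        levels = cover_classes)
    gb <- matrix(rbinom(nrow(det) * S, 1, 0.2), nrow(det), S)
    gb[, 1] <- 0L  # no "previous occasion" before the first
    colnames(gb) <- paste0("gb_", seq_len(S))
    dplyr::bind_cols(
      dplyr::select(det, detector, x, y, type, usage, "cover"),
      tibble::as_tibble(gb)
    )
  })
}
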