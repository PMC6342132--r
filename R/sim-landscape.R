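# Synthetic landscape generation.

# Distance from points (x, y) to the nearest of a set of segments
# (matrix with columns x0, y0, x1, y1).
dist_to_segments <- function(x, y, segs) {
  d2 <- rep(Inf, length(x))
  for (i in seq_len(nrow(segs))) {
    dx <- segs[i, 3] - segs[i, 1]
    dy <- segs[i, 4] - segs[i, 2]
    len2 <- dx^2 + dy^2
    if (len2 == 0) {
      di2 <- (x - segs[i, 1])^2 + (y - segs[i, 2])^2
    } else {
      t <- pmin(1, pmax(0, ((x - segs[i, 1]) * dx + (y - segs[i, 2]) * dy) / len2))
      di2 <- (x - (segs[i, 1] + t * dx))^2 + (y - (segs[i, 2] + t * dy))^2
    }
    d2 <- pmin(d2, di2)
  }
  sqrt(d2)
}

# Random segments crossing the extent (used for synthetic roads/streams).
random_segments <- function(n, extent) {
  cbind(runif(n, 0, extent[1]), runif(n, 0, extent[2]),
        runif(n, 0, extent[1]), runif(n, 0, extent[2]))
}

# Smooth [0, 1] field from a few seeded Gaussian bumps (vegetation analog).
smooth_field <- function(x, y, extent, n_bumps = 4) {
  cx <- runif(n_bumps, 0, extent[1])
  cy <- runif(n_bumps, 0, extent[2])
  amp <- runif(n_bumps, 0.5, 1.5)
  sc <- runif(n_bumps, 0.15, 0.35) * max(extent)
  f <- rep(0, length(x))
  for (i in seq_len(n_bumps)) {
    f <- f + amp[i] * exp(-((x - cx[i])^2 + (y - cy[i])^2) / (2 * sc[i]^2))
  }
  (f - min(f)) / max(f - min(f) + 1e-12)
}

#' Generate a synthetic landscape grid with habitat covariates
#'
#' Builds the gridded planar landscape the rest of the simulation lives on:
#' cell centroids at `spacing` km, a contiguous three-band land-tenure mosaic
#' (private / Crown / protected along the x-axis, with the configured area
#' shares), and continuous covariates emulating the remote-sensed layers used
#' as density covariates: a smooth vegetation-productivity index (`ndvi`,
#' 0-1), canopy cover (`canopy`, 0-100), a recent-burn patch (`burn`, 0/1),
#' hunter-harvest density (`harvest`, bears/km^2/yr, piecewise constant over
#' coarse management blocks and zero on protected land), ln-distance to
#' synthetic streams (`water`) and tertiary roads (`tertiary_rd`), and road
#' density (`rddens`, km/km^2 in a 7-km radius). Everything is a
#' deterministic function of the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A `mask_grid` tibble with one row per cell. The synthetic road
#'   and stream segments are attached as attributes `roads` and `streams`
#'   (used to bias detector placement).
#' @export
sim_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ext <- config$extent
  sp <- config$spacing
  with_seed(config$seed, {
    xs <- seq(sp / 2, ext[1], by = sp)
    ys <- seq(sp / 2, ext[2], by = sp)
    g <- tidyr::expand_grid(x = xs, y = ys)

    # Tenure: contiguous vertical bands with the configured proportions.
    brk <- cumsum(config$tenure_props)[1:2] * ext[1]
    tenure <- factor(
      ifelse(g$x < brk[1], "private", ifelse(g$x < brk[2], "crown", "protected")),
      levels = c("protected", "crown", "private")
    )

    roads <- random_segments(3, ext)
    streams <- random_segments(2, ext)

    ndvi <- smooth_field(g$x, g$y, ext)
    canopy <- round(100 * smooth_field(g$x, g$y, ext, n_bumps = 5))

    # Recent burn: one circular patch covering ~burn_fraction of the area.
    burn <- rep(0L, nrow(g))
    if (config$burn_fraction > 0) {
      r_burn <- sqrt(config$burn_fraction * prod(ext) / pi)
      bc <- c(runif(1, r_burn, ext[1] - r_burn), runif(1, r_burn, ext[2] - r_burn))
      burn <- as.integer((g$x - bc[1])^2 + (g$y - bc[2])^2 <= r_burn^2)
    }

    # Harvest density: piecewise constant over ~20-km management blocks,
    # zero where hunting is prohibited (protected tenure).
    bw <- 20
    bi <- floor(g$x / bw) + 100 * floor(g$y / bw)
    lev <- sort(unique(bi))
    hval <- stats::rgamma(length(lev), shape = 2, rate = 40)
    harvest <- hval[match(bi, lev)]
    harvest[tenure == "protected"] <- 0

    d_road <- dist_to_segments(g$x, g$y, roads)
    d_stream <- dist_to_segments(g$x, g$y, streams)

    # Road density: km of road within a 7-km radius, per km^2, from points
    # sampled densely along the road segments.
    step <- 0.25
    rp <- do.call(rbind, lapply(seq_len(nrow(roads)), function(i) {
      len <- sqrt((roads[i, 3] - roads[i, 1])^2 + (roads[i, 4] - roads[i, 2])^2)
      t <- seq(0, 1, length.out = max(2, ceiling(len / step)))
      cbind(roads[i, 1] + t * (roads[i, 3] - roads[i, 1]),
            roads[i, 2] + t * (roads[i, 4] - roads[i, 2]))
    }))
    r_search <- 7
    d2rp <- outer(g$x, rp[, 1], "-")^2 + outer(g$y, rp[, 2], "-")^2
    rddens <- rowSums(d2rp <= r_search^2) * step / (pi * r_search^2)

    cells <- tibble::tibble(
      x = g$x, y = g$y, tenure = tenure,
      ndvi = ndvi, canopy = as.numeric(canopy), burn = burn,
      harvest = harvest,
      water = log(d_stream + 0.03),
      tertiary_rd = log(d_road + 0.03),
      rddens = rddens
    )
    out <- new_mask_grid(cells, sp)
    attr(out, "roads") <- roads
    attr(out, "streams") <- streams
    attr(out, "extent") <- ext
    out
  })
}
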