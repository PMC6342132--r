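# Synthetic bear populations and capture histories.

#' Simulate activity centers from a log-linear inhomogeneous density
#'
#' Activity (home-range) centers are drawn from an inhomogeneous Poisson
#' point process with intensity `D(x) = exp(z(x)' beta_d)` bears/km^2 on the
#' landscape grid: cell counts are Poisson with mean `D(x) * a` (`a` = cell
#' area) and centers are placed uniformly within their cell, so the realized
#' total is Poisson with mean `sum(D(x) * a)`.
#'
#' @param landscape A `mask_grid` carrying every covariate named in
#'   `truth$d_formula`.
#' @param truth A [true_params()] object.
#' @param seed Integer seed for this draw.
#' @return Tibble of centers (`x`, `y`, `sex`) with attribute `N_true` (the
#'   realized count) and `Lambda` (the expected count).
#' @export
sim_population <- function(landscape, truth, seed = 1L) {
  stopifnot(inherits(truth, "true_params"))
  Z <- model.matrix(truth$d_formula, landscape)
  if (!all(colnames(Z) %in% names(truth$beta_d))) {
    abort(sprintf("beta_d is missing coefficients for: %s",
                  paste(setdiff(colnames(Z), names(truth$beta_d)), collapse = ", ")))
  }
  eta <- drop(Z %*% truth$beta_d[colnames(Z)])
  if (any(abs(eta) > 50)) {
    abort("density linear predictor exceeds +/-50 on the log scale (intensity overflow)")
  }
  a <- cell_area(landscape)
  mu <- exp(eta) * a
  sp <- mask_spacing(landscape)
  with_seed(seed, {
    n_cell <- rpois(length(mu), mu)
    idx <- rep.int(seq_along(mu), n_cell)
    n <- length(idx)
    centers <- tibble::tibble(
      x = landscape$x[idx] + runif(n, -sp / 2, sp / 2),
      y = landscape$y[idx] + runif(n, -sp / 2, sp / 2),
      sex = rep(truth$sex, n)
    )
    attr(centers, "N_true") <- n
    attr(centers, "Lambda") <- sum(mu)
    centers
  })
}

# Per-(detector, occasion) baseline hazard and scale implied by true_params,
# before the bk response. Returns K x S matrices.
true_hazard_pars <- function(detectors, truth) {
  S <- n_occasions_of(detectors)
  K <- nrow(detectors)
  gb <- gb_matrix(detectors, S)
  t0 <- matrix(rep(0:(S - 1), each = K), K, S)
  type <- as.character(detectors$type)
  l0_type <- ifelse(type == "rub", 0, truth$beta_l0_type[type])
  s_type <- ifelse(type == "rub", 0, truth$beta_sigma_type[type])
  lambda0 <- truth$lambda0 *
    exp(matrix(l0_type, K, S) + truth$beta_T * t0 + truth$beta_gb * gb)
  sigma <- truth$sigma * exp(matrix(s_type, K, S) + truth$beta_sigma_T * t0)
  list(lambda0 = lambda0, sigma = sigma)
}

#' Simulate binary capture histories under the hazard half-normal model
#'
#' For each animal `i`, detector `k` and occasion `s` where the detector is
#' in use, a detection is a Bernoulli draw with
#' `p = 1 - exp(-lambda0_iks * exp(-d_ik^2 / (2 sigma_ks^2)))`, where
#' `lambda0_iks` carries the trap-type, time-trend and grizzly-presence
#' effects, plus the trap-specific behavioural step (`beta_bk`) once animal
#' `i` has been detected at site `k` on any earlier occasion. Animals never
#' detected are dropped from the returned history (as in real hair-snag
#' data) but counted in the attributes.
#'
#' @param centers Activity centers from [sim_population()].
#' @param detectors Detector tibble from [sim_detectors()].
#' @param truth A [true_params()] object.
#' @param seed Integer seed.
#' @return A detection tibble (`individual`, `sex`, `occasion`, `detector`),
#'   one row per (individual, detector, occasion) detection, with attributes
#'   `n_simulated`, `n_detected` and `n_occasions`.
#' @export
sim_captures <- function(centers, detectors, truth, seed = 1L) {
  if (!"usage" %in% names(detectors)) abort("detectors need a `usage` column")
  S <- n_occasions_of(detectors)
  use <- usage_matrix(detectors)
  hp <- true_hazard_pars(detectors, truth)
  K <- nrow(detectors)
  N <- nrow(centers)
  if (N == 0) {
    out <- tibble::tibble(individual = character(), sex = character(),
                          occasion = integer(), detector = character())
    attr(out, "n_simulated") <- 0L
    attr(out, "n_detected") <- 0L
    attr(out, "n_occasions") <- S
    return(out)
  }
  d2 <- dist2_matrix(centers, detectors)  # N x K
  with_seed(seed, {
    seen_at <- matrix(FALSE, N, K)  # animal i ever detected at trap k so far
    recs <- vector("list", S)
    for (s in seq_len(S)) {
      lam <- matrix(hp$lambda0[, s], N, K, byrow = TRUE) *
        exp(ifelse(seen_at, truth$beta_bk, 0)) *
        exp(-d2 / (2 * matrix(hp$sigma[, s]^2, N, K, byrow = TRUE)))
      p <- (1 - exp(-lam)) * matrix(use[, s], N, K, byrow = TRUE)
      hit <- matrix(runif(N * K) < p, N, K)
      ij <- which(hit, arr.ind = TRUE)
      if (nrow(ij) > 0) {
        recs[[s]] <- tibble::tibble(
          i = ij[, 1], occasion = s, detector = detectors$detector[ij[, 2]]
        )
      }
      seen_at <- seen_at | hit
    }
    dets <- dplyr::bind_rows(recs)
    if (nrow(dets) == 0) {
      out <- tibble::tibble(individual = character(), sex = character(),
                            occasion = integer(), detector = character())
      attr(out, "n_simulated") <- N
      attr(out, "n_detected") <- 0L
      attr(out, "n_occasions") <- S
      return(out)
    }
    detected <- sort(unique(dets$i))
    out <- dets |>
      dplyr::mutate(
        individual = sprintf("%s%04d", truth$sex, match(i, detected)),
        sex = centers$sex[i]
      ) |>
      dplyr::arrange(individual, occasion, detector) |>
      dplyr::select(individual, sex, occasion, detector)
    attr(out, "n_simulated") <- N
    attr(out, "n_detected") <- length(detected)
    attr(out, "n_occasions") <- S
    out
  })
}
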