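#' Configuration for the synthetic landscape and survey design
#'
#' Defines the simulated world: a planar rectangular landscape (km, no CRS)
#' carved into a three-class land-tenure mosaic (private / Crown / protected),
#' continuous habitat covariates, and a non-invasive hair-snag survey with
#' three detector types. Rub and fence detectors are active on the
#' `n_occasions - 1` systematic occasions; a coarse grid of opportunistic
#' "detectors" is active only on the final occasion, mirroring how
#' opportunistic hair samples are pooled into one closing occasion.
#'
#' @param extent Length-2 numeric, landscape width and height in km.
#' @param spacing Landscape grid cell spacing in km (cell area = spacing^2).
#' @param tenure_props Length-3 numeric summing to 1: proportions of the
#'   landscape in private, Crown and protected tenure (defaults 0.52, 0.34,
#'   0.14, the shares of the southwestern Alberta study area).
#' @param n_rub,n_fence Numbers of rub-object and fenceline detectors.
#' @param opp_cell_size Side (km) of the opportunistic sampling cells
#'   (default 7).
#' @param n_occasions Total sampling occasions including the final
#'   opportunistic one (default 8: seven systematic + one opportunistic).
#' @param burn_fraction Approximate fraction of the landscape in a recent
#'   burn patch.
#' @param detector_bias If `TRUE`, rub/fence detectors are biased toward the
#'   synthetic linear features (surveys follow roads and fencelines).
#' @param seed Integer seed; together with the config it fully determines
#'   every simulated object.
#' @return An object of class `sim_config` (a named list).
#' @seealso [true_params()], [sim_landscape()], [sim_detectors()]
#' @export
sim_config <- function(extent = c(60, 60),
                       spacing = 2,
                       tenure_props = c(private = 0.52, crown = 0.34, protected = 0.14),
                       n_rub = 60,
                       n_fence = 20,
                       opp_cell_size = 7,
                       n_occasions = 8,
                       burn_fraction = 0.05,
                       detector_bias = TRUE,
                       seed = 1L) {
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0)) {
    abort("`extent` must be two positive dimensions in km")
  }
  check_scalar_pos(spacing, "spacing")
  if (length(tenure_props) != 3 || abs(sum(tenure_props) - 1) > 1e-9 ||
      any(tenure_props < 0)) {
    abort("`tenure_props` must be 3 non-negative fractions summing to 1")
  }
  if (is.null(names(tenure_props))) {
    names(tenure_props) <- c("private", "crown", "protected")
  }
  if (n_rub < 0 || n_fence < 0) abort("detector counts must be >= 0")
  check_scalar_pos(opp_cell_size, "opp_cell_size")
  if (n_occasions < 2) abort("need at least 2 occasions (1 systematic + 1 opportunistic)")
  structure(
    list(
      extent = as.numeric(extent), spacing = spacing,
      tenure_props = tenure_props,
      n_rub = as.integer(n_rub), n_fence = as.integer(n_fence),
      opp_cell_size = opp_cell_size, n_occasions = as.integer(n_occasions),
      burn_fraction = burn_fraction, detector_bias = isTRUE(detector_bias),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generating parameters of the synthetic bear population
#'
#' The generator uses the same model family the estimator fits: a log-linear
#' inhomogeneous density over landscape covariates, and a hazard half-normal
#' detection model where the cumulative per-occasion detection hazard is
#' `lambda(d) = lambda0 * exp(-d^2 / (2 sigma^2))` and detection probability
#' is `g(d) = 1 - exp(-lambda(d))`. Effects on `lambda0` and `sigma` act
#' multiplicatively (additively on the log scale).
#'
#' @param d_formula Density formula over landscape covariates, e.g.
#'   `~ tenure`; the intercept is on the log scale in bears/km^2.
#' @param beta_d Named numeric of density coefficients matching
#'   `model.matrix(d_formula, landscape)` columns. Must include
#'   `"(Intercept)"`.
#' @param lambda0 Baseline cumulative detection hazard per occasion at
#'   distance zero (rub detectors, first occasion, no prior detection).
#' @param sigma Baseline spatial scale of the detection kernel in km.
#' @param beta_l0_type Named log-scale `lambda0` offsets for detector types
#'   other than `"rub"` (names among `"fence"`, `"opp"`).
#' @param beta_bk Log-scale step change in `lambda0` after an individual's
#'   first detection at a site (trap-specific behavioural response). The
#'   response is permanent within a session.
#' @param beta_T Log-linear time trend in `lambda0` per occasion (occasion
#'   index is 0-based).
#' @param beta_gb Log-scale `lambda0` effect of a grizzly bear having been
#'   detected at the site on the previous occasion.
#' @param beta_sigma_type,beta_sigma_T Analogous log-scale effects on `sigma`.
#' @param sex Cohort label, `"F"` or `"M"` (sexes are simulated and analysed
#'   separately).
#' @return An object of class `true_params`.
#' @export
true_params <- function(d_formula = ~1,
                        beta_d = c("(Intercept)" = log(0.05)),
                        lambda0 = 0.1,
                        sigma = 2,
                        beta_l0_type = c(fence = 0, opp = 0),
                        beta_bk = 0,
                        beta_T = 0,
                        beta_gb = 0,
                        beta_sigma_type = c(fence = 0, opp = 0),
                        beta_sigma_T = 0,
                        sex = "F") {
  check_scalar_pos(lambda0, "lambda0")
  check_scalar_pos(sigma, "sigma")
  if (!"(Intercept)" %in% names(beta_d)) {
    abort('`beta_d` must include an "(Intercept)" term (log bears/km^2)')
  }
  structure(
    list(
      d_formula = d_formula, beta_d = beta_d,
      lambda0 = lambda0, sigma = sigma,
      beta_l0_type = beta_l0_type, beta_bk = beta_bk,
      beta_T = beta_T, beta_gb = beta_gb,
      beta_sigma_type = beta_sigma_type, beta_sigma_T = beta_sigma_T,
      sex = match.arg(sex, c("F", "M"))
    ),
    class = "true_params"
  )
}
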