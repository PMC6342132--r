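# SECR model specification and design-matrix construction.

#' Specify a spatially explicit capture-recapture model
#'
#' A model has three log-linear submodels: the cumulative detection hazard at
#' distance zero (`lambda0`), the spatial scale of the hazard half-normal
#' kernel (`sigma`, km), and density over the habitat mask (`density`,
#' bears/km^2). Detection follows the hazard half-normal form
#' `lambda(d) = lambda0 * exp(-d^2 / (2 sigma^2))` with per-occasion
#' detection probability `g(d) = 1 - exp(-lambda(d))`.
#'
#' Available `lambda0` terms: `traptype` (rub/fence/opp), `bk` (trap-specific
#' behavioural step after the individual's first detection at the site), `T`
#' (0-based occasion index, log-linear trend), `gb` (grizzly detected at the
#' site on the previous occasion) and `cover` (7-level habitat class at the
#' detector). `sigma` accepts `traptype`, `T` and `gb`. `density` accepts any
#' mask covariate; the tenure reference level is `protected`.
#'
#' @param lambda0,sigma,density One-sided formulas.
#' @return An object of class `secr_model`.
#' @examples
#' secr_model(~ traptype + bk + T, ~T, ~tenure)
#' @export
secr_model <- function(lambda0 = ~1, sigma = ~1, density = ~1) {
  structure(
    list(lambda0 = lambda0, sigma = sigma, density = density),
    class = "secr_model"
  )
}

#' @export
print.secr_model <- function(x, ...) {
  cat(sprintf("D ~ %s   lambda0 ~ %s   sigma ~ %s\n",
              deparse1(x$density[[2]]), deparse1(x$lambda0[[2]]),
              deparse1(x$sigma[[2]])))
  invisible(x)
}

model_label <- function(m) {
  sprintf("D~%s l0~%s s~%s", deparse1(m$density[[2]]),
          deparse1(m$lambda0[[2]]), deparse1(m$sigma[[2]]))
}

# Split a detection formula into (formula without bk, has_bk flag).
strip_bk <- function(f) {
  lab <- attr(terms(f), "term.labels")
  has_bk <- "bk" %in% lab
  rest <- setdiff(lab, "bk")
  f2 <- if (length(rest)) stats::reformulate(rest) else ~1
  list(formula = f2, bk = has_bk)
}

# Assemble everything the likelihood needs that does not depend on theta.
build_secr_design <- function(model, history, detectors, mask) {
  stopifnot(inherits(model, "secr_model"))
  S <- n_occasions_of(detectors)
  K <- nrow(detectors)
  use <- usage_matrix(detectors)
  if (any(history$occasion < 1 | history$occasion > S)) {
    abort("capture history has occasions outside the detector usage window")
  }
  ki <- match(history$detector, detectors$detector)
  if (anyNA(ki)) abort("capture history references unknown detectors")
  if (any(use[cbind(ki, history$occasion)] == 0)) {
    abort("detections recorded at (detector, occasion) cells with zero usage")
  }

  # Long (detector x occasion) design frame; row order ks = k + (s-1) * K.
  det_occ <- tibble::tibble(
    traptype = droplevels(rep(detectors$type, S)),
    T = rep(0:(S - 1), each = K),
    gb = as.vector(gb_matrix(detectors, S))
  )
  if ("cover" %in% names(detectors)) {
    det_occ$cover <- droplevels(rep(detectors$cover, S))
  }
  l0 <- strip_bk(model$lambda0)
  sg <- strip_bk(model$sigma)
  if (sg$bk) abort("`bk` is a lambda0 term only")
  X_L <- model.matrix(l0$formula, det_occ)
  X_S <- model.matrix(sg$formula, det_occ)
  X_D <- model.matrix(model$density, mask)

  # Per-individual detection cells and bk states.
  ids <- unique(history$individual)
  ks_of <- ki + (history$occasion - 1L) * K
  by_id <- split(seq_len(nrow(history)), factor(history$individual, ids))
  indiv <- lapply(by_id, function(rows) {
    k <- ki[rows]; s <- history$occasion[rows]
    first_at <- tapply(s, k, min)
    bk_state <- first_at[as.character(k)] < s  # detected there earlier?
    # Cells where the animal was NOT detected but carried the bk response:
    # trap k on occasions > first detection at k, with usage, omega = 0.
    miss <- integer(0)
    for (kk in unique(k)) {
      f <- first_at[as.character(kk)]
      ss <- which(use[kk, ] == 1)
      ss <- ss[ss > f & !(ss %in% s[k == kk])]
      miss <- c(miss, kk + (ss - 1L) * K)
    }
    list(det = ks_of[rows], det_bk = as.logical(bk_state), miss_bk = miss)
  })

  list(
    model = model, n = length(ids), ids = ids, S = S, K = K,
    usage = as.vector(use) == 1,
    d2 = dist2_matrix(detectors, mask),      # K x M
    X_L = X_L, X_S = X_S, X_D = X_D,
    has_bk = l0$bk, indiv = indiv,
    a = cell_area(mask), M = nrow(mask),
    par_names = c(paste0("D.", colnames(X_D)),
                  paste0("lambda0.", c(colnames(X_L), if (l0$bk) "bk")),
                  paste0("sigma.", colnames(X_S))),
    p_D = ncol(X_D), p_L = ncol(X_L) + l0$bk, p_S = ncol(X_S)
  )
}
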