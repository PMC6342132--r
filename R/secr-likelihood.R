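# Full SECR likelihood: hazard half-normal detection, activity centers
# marginalized over the habitat mask.

#' Hazard half-normal detection function
#'
#' `hazard()` gives the cumulative detection hazard at distance `d` from an
#' activity center, `lambda(d) = lambda0 * exp(-d^2 / (2 sigma^2))`;
#' `hazard_to_prob()` converts a hazard to a per-occasion detection
#' probability, `g = 1 - exp(-lambda)`.
#'
#' @param d Distance(s) in km.
#' @param lambda0 Hazard at distance zero (`>= 0`).
#' @param sigma Spatial scale in km (`> 0`).
#' @param lambda Cumulative hazard(s) (`>= 0`).
#' @return Hazards, or probabilities in `[0, 1)`.
#' @export
hazard <- function(d, lambda0, sigma) {
  if (any(lambda0 < 0)) abort("`lambda0` must be >= 0")
  if (any(sigma <= 0)) abort("`sigma` must be > 0")
  lambda0 * exp(-d^2 / (2 * sigma^2))
}

#' @rdname hazard
#' @export
hazard_to_prob <- function(lambda) {
  if (any(lambda < 0)) abort("`lambda` must be >= 0")
  -expm1(-lambda)
}

# theta -> list of per-(detector, occasion) parameter vectors.
split_theta <- function(theta, des) {
  i <- 0
  beta_D <- theta[i + seq_len(des$p_D)]; i <- i + des$p_D
  beta_L <- theta[i + seq_len(des$p_L)]; i <- i + des$p_L
  beta_S <- theta[i + seq_len(des$p_S)]
  bk_coef <- if (des$has_bk) beta_L[des$p_L] else 0
  beta_L0 <- beta_L[seq_len(ncol(des$X_L))]
  list(beta_D = beta_D, beta_L0 = beta_L0, bk = bk_coef, beta_S = beta_S)
}

#' Negative log-likelihood of the full SECR model
#'
#' Implements the full (unconditional) likelihood with the latent activity
#' center marginalized over mask cells. For each detected individual,
#' `Pr(omega_i | x)` multiplies per-(detector, occasion) Bernoulli terms with
#' `p = 1 - exp(-lambda)`; the hazard carries the individual's trap-specific
#' behavioural state where the model includes `bk`. Undetected animals enter
#' through the naive (`bk = 0`) probability of being detected at all,
#' `p.(x) = 1 - prod_ks (1 - p_ks(x))`. With `Lambda = sum_m D(x_m) a` and
#' `pbar = sum_m p.(x_m) D(x_m) a / Lambda`, the Poisson form is
#' `-logL = Lambda pbar - sum_i log( sum_m Pr(omega_i|x_m) D(x_m) a ) +
#' log n!`; the binomial form replaces the Poisson count term by a binomial
#' one with continuous size `N = Lambda` (gamma functions) and histories
#' conditioned on detection.
#'
#' @param theta Coefficient vector on the working (log-link) scale, ordered
#'   density, lambda0 (bk last), sigma — see `design$par_names`.
#' @param design Design object from `build_secr_design()` (internal), or
#'   pass `model`, `history`, `detectors`, `mask` to build one.
#' @param model,history,detectors,mask Inputs used when `design` is `NULL`.
#' @param distribution `"poisson"` (default) or `"binomial"` for the number
#'   of activity centers on the mask.
#' @return The negative log-likelihood (a large barrier value if not finite).
#' @export
secr_negloglik <- function(theta, design = NULL, model = NULL, history = NULL,
                           detectors = NULL, mask = NULL,
                           distribution = c("poisson", "binomial")) {
  distribution <- match.arg(distribution)
  des <- design %||% build_secr_design(model, history, detectors, mask)
  if (length(theta) != des$p_D + des$p_L + des$p_S) {
    abort(sprintf("theta has length %d; model needs %d coefficients",
                  length(theta), des$p_D + des$p_L + des$p_S))
  }
  nll <- secr_nll_impl(theta, des, distribution)
  if (!is.finite(nll)) 1e10 else nll
}

secr_nll_impl <- function(theta, des, distribution) {
  pp <- split_theta(theta, des)
  lam0 <- exp(drop(des$X_L %*% pp$beta_L0))          # length K*S, naive (bk=0)
  sig2 <- exp(2 * drop(des$X_S %*% pp$beta_S))
  if (!all(is.finite(lam0)) || !all(is.finite(sig2))) return(Inf)

  K <- des$K; S <- des$S
  # Hazard matrix h[ks, m]: rows are (detector, occasion), columns mask cells.
  d2ks <- des$d2[rep.int(seq_len(K), S), , drop = FALSE]
  h <- lam0 * exp(d2ks / (-2 * sig2))
  hu <- h[des$usage, , drop = FALSE]
  H <- .colSums(hu, nrow(hu), ncol(hu))               # total hazard per cell
  # log(1 - p_ks) = -h_ks, so log Pr(never detected | x) = -H.

  D <- exp(drop(des$X_D %*% pp$beta_D))
  if (!all(is.finite(D))) return(Inf)
  Da <- D * des$a
  Lambda <- sum(Da)
  pdot <- -expm1(-H)
  Lp <- sum(pdot * Da)                                # Lambda * pbar

  ebk <- exp(pp$bk)
  sum_li <- 0
  for (ind in des$indiv) {
    logPr <- -H
    hd <- h[ind$det, , drop = FALSE]
    if (des$has_bk && any(ind$det_bk)) {
      hd[ind$det_bk, ] <- hd[ind$det_bk, , drop = FALSE] * ebk
    }
    # Detected cells: swap the survivor term -h for log(p).
    logPr <- logPr + .colSums(log(-expm1(-hd)) + h[ind$det, , drop = FALSE],
                              nrow(hd), ncol(hd))
    if (des$has_bk && length(ind$miss_bk)) {
      hm <- h[ind$miss_bk, , drop = FALSE]
      # Non-detections under the bk-elevated hazard: -h*ebk replaces -h.
      logPr <- logPr + (1 - ebk) * .colSums(hm, nrow(hm), ncol(hm))
    }
    li <- sum(exp(logPr) * Da)
    if (li <= 0 || !is.finite(li)) return(Inf)
    sum_li <- sum_li + log(li)
  }

  n <- des$n
  if (distribution == "poisson") {
    Lp - sum_li + lfactorial(n)
  } else {
    if (Lambda <= n) return(Inf)
    pbar <- Lp / Lambda
    -(lgamma(Lambda + 1) - lgamma(Lambda - n + 1) - lfactorial(n) +
        (Lambda - n) * log1p(-pbar) - n * log(Lambda) + sum_li)
  }
}
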