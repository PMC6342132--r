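# Maximum-likelihood SECR fitting.

#' Fit a spatially explicit capture-recapture model
#'
#' Maximizes the full likelihood (see [secr_negloglik()]) by quasi-Newton
#' (BFGS) search on the log-link working scale, from default starting values
#' (`ln sigma` at `ln RPSV`, `ln lambda0` at `ln(-ln(1 - r))` with `r` the
#' naive per-occasion capture rate, `ln D` at `ln(n / mask area)`; other
#' coefficients 0) plus `n_starts - 1` jittered restarts. Standard errors
#' come from the numerical Hessian at the optimum; density intervals are
#' lognormal, coefficient intervals Wald.
#'
#' @param model A [secr_model()].
#' @param history Detection tibble (`individual`, `occasion`, `detector`);
#'   analyze one sex at a time.
#' @param detectors Detector tibble with `usage` (and any detection
#'   covariates the model names).
#' @param mask A `mask_grid` carrying the density covariates.
#' @param distribution `"poisson"` or `"binomial"` number of activity
#'   centers.
#' @param start Optional start vector on the working scale.
#' @param n_starts Number of optimizer starts (first is the default start).
#' @param jitter_sd SD of the start jitter on the working scale.
#' @param max_iter BFGS iteration cap per start.
#' @return An object of class `secr_fit`: coefficients and `vcov` on the
#'   working scale, `logLik`, `K`, `n`, `AICc`, back-transformed baseline
#'   `estimates` with 95% CIs, expected abundance `Lambda` with relative SE
#'   `rse`, and convergence metadata. Supports [tidy()], [glance()],
#'   [predict_density()] and [region_abundance()].
#' @export
fit_secr <- function(model, history, detectors, mask,
                     distribution = c("poisson", "binomial"),
                     start = NULL, n_starts = 3, jitter_sd = 0.25,
                     max_iter = 500) {
  distribution <- match.arg(distribution)
  if (nrow(history) == 0) abort("empty capture history: nothing to fit")
  des <- build_secr_design(model, history, detectors, mask)
  n_par <- des$p_D + des$p_L + des$p_S
  if (n_par >= des$n) {
    warn(sprintf("model has %d parameters but only %d detected individuals", n_par, des$n))
  }
  if (is.null(start)) start <- default_start(des, history, detectors, mask)

  fn <- function(th) secr_nll_impl_safe(th, des, distribution)
  best <- NULL
  with_seed(des$n + 1000L * n_par, {
    for (j in seq_len(max(1, n_starts))) {
      st <- if (j == 1) start else start + rnorm(n_par, 0, jitter_sd)
      opt <- tryCatch(
        optim(st, fn, method = "BFGS",
              control = list(maxit = max_iter, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
  })
  if (is.null(best)) abort("all optimizer starts failed")

  theta <- setNames(best$par, des$par_names)
  grad <- numeric_grad(fn, theta)
  Hs <- tryCatch(optimHess(theta, fn), error = function(e) NULL)
  vc <- NULL
  if (!is.null(Hs)) {
    vc <- tryCatch(solve(Hs), error = function(e) NULL)
    if (!is.null(vc) && any(diag(vc) <= 0)) vc <- NULL
  }
  if (is.null(vc)) {
    warn("Hessian singular or not positive definite; standard errors unavailable")
  } else {
    dimnames(vc) <- list(des$par_names, des$par_names)
  }
  converged <- best$convergence == 0
  if (!converged) warn("optimizer did not converge; fit is flagged")

  ll <- -best$value
  fit <- structure(
    list(
      model = model, distribution = distribution,
      coefficients = theta, vcov = vc,
      logLik = ll, K = n_par, n = des$n,
      AICc = aicc(ll, n_par, des$n),
      converged = converged, grad_norm = sqrt(sum(grad^2)),
      design = des[c("p_D", "p_L", "p_S", "par_names", "has_bk", "n", "a", "M")],
      X_D_names = colnames(des$X_D),
      mask_area = des$M * des$a
    ),
    class = "secr_fit"
  )
  fit$estimates <- baseline_estimates(fit)
  lam <- lambda_hat(fit, mask)
  fit$Lambda <- lam$Lambda
  fit$rse <- lam$rse
  fit
}

secr_nll_impl_safe <- function(th, des, distribution) {
  v <- secr_nll_impl(th, des, distribution)
  if (!is.finite(v)) 1e10 else v
}

numeric_grad <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    (fn(xp) - f0) / eps
  }, numeric(1))
}

default_start <- function(des, history, detectors, mask) {
  sig0 <- tryCatch(rpsv(history, detectors), error = function(e) NA_real_)
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- 2 * mask_spacing(mask)
  use <- usage_matrix(detectors)
  rate <- nrow(history) / (des$n * max(1, sum(colSums(use) > 0)))
  rate <- min(max(rate, 1e-4), 0.9)
  st <- numeric(des$p_D + des$p_L + des$p_S)
  st[1] <- log(des$n / (des$M * des$a))
  st[des$p_D + 1] <- log(-log(1 - rate))
  st[des$p_D + des$p_L + 1] <- log(sig0)
  st
}

# Back-transformed baseline D, lambda0, sigma with 95% CIs (lognormal on
# the intercepts; covariate effects at their reference level / zero).
baseline_estimates <- function(fit) {
  idx <- c(D = 1, lambda0 = fit$design$p_D + 1,
           sigma = fit$design$p_D + fit$design$p_L + 1)
  se_link <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov))[idx] else rep(NA_real_, 3)
  est <- fit$coefficients[idx]
  z <- qnorm(0.975)
  tibble::tibble(
    parameter = names(idx),
    estimate = exp(est),
    se = exp(est) * se_link,        # delta method on the natural scale
    lcl = exp(est - z * se_link),   # lognormal interval
    ucl = exp(est + z * se_link)
  )
}

# Expected abundance on the mask and its delta-method relative SE.
lambda_hat <- function(fit, mask) {
  Z <- model.matrix(fit$model$density, mask)
  bd <- fit$coefficients[seq_len(fit$design$p_D)]
  Da <- exp(drop(Z %*% bd)) * cell_area(mask)
  Lambda <- sum(Da)
  rse <- NA_real_
  if (!is.null(fit$vcov)) {
    g <- drop(crossprod(Z, Da))  # d Lambda / d beta_D
    v <- drop(t(g) %*% fit$vcov[seq_along(g), seq_along(g), drop = FALSE] %*% g)
    if (v >= 0) rse <- sqrt(v) / Lambda
  }
  list(Lambda = Lambda, rse = rse)
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("SECR fit (%s): %s\n", x$distribution, model_label(x$model)))
  cat(sprintf("  n = %d detected, K = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$n, x$K, x$logLik, x$AICc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$estimates)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2K + 2K(K + 1) / (n - K - 1)`, where `n` is the number of
#' detected individuals (the sample size in capture-recapture model
#' selection).
#'
#' @param LL Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Number of detected individuals; must exceed `K + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-1750.67, 8, 126)
#' @export
aicc <- function(LL, K, n) {
  if (n <= K + 1) abort("AICc undefined: need n > K + 1")
  -2 * LL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank fitted models by AICc
#'
#' @param fits List of `secr_fit` objects fitted to the same data.
#' @return Tibble with columns `model`, `K`, `LL`, `AICc`, `dAICc` and the
#'   Akaike weight `w = exp(-dAICc/2) / sum(exp(-dAICc/2))`, sorted by AICc
#'   (ties broken in favour of fewer parameters).
#' @export
model_table <- function(fits) {
  if (length(fits) == 0) abort("no fits supplied")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("fits are not comparable: differing numbers of detected individuals")
  }
  tb <- tibble::tibble(
    model = vapply(fits, function(f) model_label(f$model), character(1)),
    K = vapply(fits, function(f) f$K, numeric(1)),
    LL = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1))
  ) |>
    dplyr::arrange(AICc, K) |>
    dplyr::mutate(dAICc = AICc - min(AICc), w = akaike_weights(dAICc))
  tb
}

#' Akaike weights from AICc differences
#'
#' @param dAICc Vector of AICc differences from the best model.
#' @return Normalized weights `exp(-d/2) / sum(exp(-d/2))`.
#' @export
akaike_weights <- function(dAICc) {
  w <- exp(-dAICc / 2)
  w / sum(w)
}

#' Predict the fitted density surface over a mask
#'
#' `D(x) = exp(z(x)' beta_D)` per cell, with pointwise 95% CIs from the
#' delta method on the linear predictor (lognormal intervals).
#'
#' @param fit A `secr_fit`.
#' @param mask A `mask_grid` carrying the model's density covariates.
#' @param per_1000 Report densities per 1,000 km^2 (the reporting
#'   convention) instead of per km^2.
#' @return Tibble `x`, `y`, `density`, `lo`, `hi`.
#' @export
predict_density <- function(fit, mask, per_1000 = FALSE) {
  miss <- setdiff(all.vars(fit$model$density), names(mask))
  if (length(miss)) {
    abort(sprintf("mask lacks density covariates: %s", paste(miss, collapse = ", ")))
  }
  Z <- model.matrix(fit$model$density, mask)
  bd <- fit$coefficients[seq_len(fit$design$p_D)]
  eta <- drop(Z %*% bd)
  se <- rep(NA_real_, length(eta))
  if (!is.null(fit$vcov)) {
    Vd <- fit$vcov[seq_along(bd), seq_along(bd), drop = FALSE]
    se <- sqrt(pmax(0, rowSums((Z %*% Vd) * Z)))
  }
  z <- qnorm(0.975)
  mult <- if (per_1000) 1000 else 1
  tibble::tibble(
    x = mask$x, y = mask$y,
    density = exp(eta) * mult,
    lo = exp(eta - z * se) * mult,
    hi = exp(eta + z * se) * mult
  )
}

#' Region abundance by discrete summation over the mask
#'
#' Sums the fitted density surface over the mask cells of each region
#' (`N_region = sum D(x) * a`). Confidence limits come from parametric
#' resampling of the density coefficients from their estimated covariance.
#'
#' @param fit A `secr_fit`.
#' @param mask A `mask_grid`.
#' @param region Name of the mask column labelling regions (default
#'   `"tenure"`).
#' @param nsim Number of coefficient draws for the CI.
#' @param seed Seed for the draws.
#' @param level Confidence level.
#' @return Tibble `region`, `area`, `N_hat`, `lo`, `hi`.
#' @export
region_abundance <- function(fit, mask, region = "tenure", nsim = 1000,
                             seed = 1L, level = 0.95) {
  if (!region %in% names(mask)) abort(sprintf("mask has no column '%s'", region))
  Z <- model.matrix(fit$model$density, mask)
  bd <- fit$coefficients[seq_len(fit$design$p_D)]
  a <- cell_area(mask)
  labs <- mask[[region]]
  if (any(is.na(labs))) abort("every mask cell must carry a region label")
  Dcell <- exp(drop(Z %*% bd)) * a
  point <- tapply(Dcell, labs, sum)
  point[is.na(point)] <- 0
  if (any(point == 0)) warn("some regions contain no mask cells; N_hat = 0 there")
  lo <- hi <- rep(NA_real_, length(point))
  if (!is.null(fit$vcov)) {
    Vd <- fit$vcov[seq_along(bd), seq_along(bd), drop = FALSE]
    draws <- with_seed(seed, MASS::mvrnorm(nsim, bd, Vd))
    sims <- exp(Z %*% t(draws)) * a          # M x nsim cell abundances
    gsum <- rowsum(sims, labs)               # regions x nsim
    alpha <- (1 - level) / 2
    qs <- apply(gsum, 1, quantile, probs = c(alpha, 1 - alpha))
    lo <- qs[1, names(point)]; hi <- qs[2, names(point)]
  }
  tibble::tibble(
    region = names(point),
    area = as.numeric(tapply(rep(a, length(labs)), labs, sum)[names(point)]),
    N_hat = as.numeric(point), lo = as.numeric(lo), hi = as.numeric(hi)
  )
}
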