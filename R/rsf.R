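# Used-available resource-selection functions.

#' Draw available (random) points inside a sampling domain
#'
#' Uniform points within the availability domain, conventionally at a 20:1
#' available:used ratio (e.g. 873 used rub objects yield 17,460 random
#' points).
#'
#' @param domain An `mcp` object from [mcp_buffer()].
#' @param n_used Number of used points.
#' @param ratio Available points per used point (`>= 1`).
#' @param seed Integer seed.
#' @return Tibble of `n_used * ratio` points (`x`, `y`).
#' @export
sample_available <- function(domain, n_used, ratio = 20, seed = 1L) {
  stopifnot(inherits(domain, "mcp"))
  if (ratio < 1) abort("`ratio` must be >= 1")
  n <- as.integer(n_used * ratio)
  bb_x <- range(domain$boundary$x)
  bb_y <- range(domain$boundary$y)
  with_seed(seed, {
    out_x <- numeric(0); out_y <- numeric(0)
    guard <- 0
    while (length(out_x) < n) {
      m <- max(1000L, 2L * (n - length(out_x)))
      cx <- runif(m, bb_x[1], bb_x[2])
      cy <- runif(m, bb_y[1], bb_y[2])
      keep <- in_mcp(domain, cx, cy)
      out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
      guard <- guard + 1
      if (guard > 1000) abort("degenerate domain: rejection sampling not terminating")
    }
    tibble::tibble(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
  })
}

# Continuous predictors = numeric columns with > 2 distinct values.
continuous_vars <- function(data, vars) {
  vars[vapply(vars, function(v) {
    is.numeric(data[[v]]) && length(unique(data[[v]])) > 2
  }, logical(1))]
}

#' Fit an exponential RSF by used-available logistic regression
#'
#' Pools used (coded 1) and available (coded 0) covariate rows, standardizes
#' every continuous predictor to mean 0, SD 1 on the pooled design, and fits
#' a logistic regression. The selection score is the exponential RSF
#' `w(x) = exp(beta_1 x_1 + ... + beta_n x_n)` — the intercept is excluded,
#' as it only encodes the sampling ratio. Standardization constants are
#' stored and re-applied at prediction time.
#'
#' @param used,available Data frames of covariate rows (used points and
#'   random/available points).
#' @param formula One-sided formula of predictors, e.g. `~ ndvi + canopy`.
#' @return An object of class `rsf_model`: `coef` (non-intercept
#'   coefficients), `fit` (the glm), `std` (standardization constants),
#'   `AIC`, and the pooled data for refitting during cross-validation.
#' @export
fit_rsf <- function(used, available, formula) {
  if (nrow(used) == 0 || nrow(available) == 0) {
    abort("both used and available sets must be nonempty")
  }
  vars <- all.vars(formula)
  miss <- setdiff(vars, intersect(names(used), names(available)))
  if (length(miss)) {
    abort(sprintf("covariates missing from used/available data: %s",
                  paste(miss, collapse = ", ")))
  }
  dat <- dplyr::bind_rows(
    dplyr::mutate(used[vars], .y = 1L),
    dplyr::mutate(available[vars], .y = 0L)
  )
  cont <- continuous_vars(dat, vars)
  std <- tibble::tibble(
    variable = cont,
    mean = vapply(cont, function(v) mean(dat[[v]]), numeric(1)),
    sd = vapply(cont, function(v) sd(dat[[v]]), numeric(1))
  )
  if (any(std$sd == 0)) {
    abort(sprintf("constant covariate cannot be standardized: %s",
                  paste(std$variable[std$sd == 0], collapse = ", ")))
  }
  for (i in seq_len(nrow(std))) {
    v <- std$variable[i]
    dat[[v]] <- (dat[[v]] - std$mean[i]) / std$sd[i]
  }
  f2 <- update(formula, .y ~ .)
  fit <- withCallingHandlers(
    glm(f2, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("rank-deficient design: no estimate for %s",
                  paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  big <- abs(cf[-1]) > 15
  if (any(big)) {
    abort(sprintf("complete or quasi-complete separation on: %s",
                  paste(names(cf[-1])[big], collapse = ", ")))
  }
  structure(
    list(formula = formula, coef = cf[-1], intercept = cf[1], fit = fit,
         std = std, AIC = AIC(fit), used = used[vars], available = available[vars]),
    class = "rsf_model"
  )
}

#' @export
print.rsf_model <- function(x, ...) {
  cat(sprintf("RSF (used-available logistic): ~ %s\n", deparse1(x$formula[[2]])))
  cat(sprintf("  n_used = %d, n_available = %d, AIC = %.2f\n",
              nrow(x$used), nrow(x$available), x$AIC))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict exponential RSF scores
#'
#' @param model An `rsf_model`.
#' @param newdata Data frame with the model's covariates (raw scale; the
#'   stored standardization is applied).
#' @return Numeric vector of scores `exp(sum beta_i x_i)` (no intercept).
#' @export
predict_rsf <- function(model, newdata) {
  stopifnot(inherits(model, "rsf_model"))
  dat <- newdata[all.vars(model$formula)]
  for (i in seq_len(nrow(model$std))) {
    v <- model$std$variable[i]
    dat[[v]] <- (dat[[v]] - model$std$mean[i]) / model$std$sd[i]
  }
  X <- model.matrix(model$formula, dat)
  exp(drop(X[, names(model$coef), drop = FALSE] %*% model$coef))
}

#' Select an RSF among candidate formulas by AIC
#'
#' Fits every candidate with [fit_rsf()] and returns the minimum-AIC model
#' (ties broken toward fewer parameters) plus the full AIC table. The
#' default candidate list ([rsf_candidates()]) is a documented, configurable
#' set over the synthetic covariates.
#'
#' @param candidates List of one-sided formulas.
#' @param used,available As in [fit_rsf()].
#' @return List with `model` (best `rsf_model`) and `table` (formula, K,
#'   AIC, dAIC, w).
#' @export
select_rsf <- function(candidates, used, available) {
  if (length(candidates) == 0) abort("empty candidate list")
  fits <- lapply(candidates, function(f) {
    tryCatch(fit_rsf(used, available, f), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("every candidate RSF failed to fit")
  fits <- fits[ok]
  tb <- tibble::tibble(
    formula = vapply(fits, function(f) deparse1(f$formula[[2]]), character(1)),
    K = vapply(fits, function(f) length(coef(f$fit)), numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1))
  ) |>
    dplyr::arrange(AIC, K) |>
    dplyr::mutate(dAIC = AIC - min(AIC), w = akaike_weights(dAIC))
  best <- fits[[order(vapply(fits, function(f) f$AIC, numeric(1)),
                      vapply(fits, function(f) length(coef(f$fit)), numeric(1)))[1]]]
  list(model = best, table = tb)
}

#' @rdname select_rsf
#' @export
rsf_candidates <- function() {
  list(
    ~ndvi,
    ~canopy,
    ~harvest,
    ~rddens,
    ~ ndvi + canopy,
    ~ ndvi + water,
    ~ ndvi + harvest,
    ~ water + tertiary_rd,
    ~ ndvi + tertiary_rd + rddens,
    ~ canopy + burn,
    ~ ndvi + canopy + burn + harvest + water + tertiary_rd + rddens
  )
}
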