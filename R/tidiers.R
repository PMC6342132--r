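# broom-style tidiers.

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per coefficient; `glance()` one row per fit.
#'
#' @param x A `secr_fit`, `rsf_model` or `rsf_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.secr_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, x$K)
  z <- qnorm(0.975)
  tibble::tibble(
    term = names(x$coefficients),
    parameter = sub("\\..*$", "", names(x$coefficients)),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    conf.low = unname(x$coefficients - z * se),
    conf.high = unname(x$coefficients + z * se)
  )
}

#' @rdname tidiers
#' @export
glance.secr_fit <- function(x, ...) {
  tibble::tibble(
    model = model_label(x$model), distribution = x$distribution,
    n = x$n, K = x$K, logLik = x$logLik, AICc = x$AICc,
    Lambda = x$Lambda, rse = x$rse, converged = x$converged
  )
}

#' @rdname tidiers
#' @export
tidy.rsf_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )[rownames(sm) != "(Intercept)", ]
}

#' @rdname tidiers
#' @export
glance.rsf_model <- function(x, ...) {
  tibble::tibble(
    formula = deparse1(x$formula[[2]]),
    n_used = nrow(x$used), n_available = nrow(x$available),
    K = length(coef(x$fit)), AIC = x$AIC,
    deviance = x$fit$deviance
  )
}

#' @rdname tidiers
#' @export
tidy.rsf_cv <- function(x, ...) x$results

#' @rdname tidiers
#' @export
glance.rsf_cv <- function(x, ...) {
  tibble::tibble(rs_bar = x$rs_bar, folds = x$folds, repeats = x$repeats,
                 n_fold_results = sum(!is.na(x$results$rs)))
}
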