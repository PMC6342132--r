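# Two-step AICc model selection for SECR.

#' Default candidate model sets for two-step selection
#'
#' `secr_step1_candidates()` returns the 17 observation models (effects on
#' `lambda0` and `sigma`, density held constant) and
#' `secr_step2_candidates()` the 8 single-covariate density formulas used in
#' the two-step screening of the southwestern Alberta analysis.
#'
#' @return Step 1: a list of [secr_model()] objects with `density = ~1`;
#'   step 2: a list of one-sided density formulas.
#' @export
secr_step1_candidates <- function() {
  specs <- list(
    list(~1, ~1),
    list(~bk, ~1),
    list(~traptype, ~1),
    list(~1, ~traptype),
    list(~traptype, ~traptype),
    list(~T, ~1),
    list(~T, ~T),
    list(~1, ~T),
    list(~ traptype + bk, ~traptype),
    list(~ traptype + bk, ~1),
    list(~ traptype + bk, ~T),
    list(~ gb + T, ~1),
    list(~ gb + T + traptype, ~1),
    list(~ T + cover, ~gb),
    list(~ traptype + bk, ~gb),
    list(~ T + cover + bk, ~1),
    list(~ traptype + cover + bk, ~1)
  )
  lapply(specs, function(s) secr_model(lambda0 = s[[1]], sigma = s[[2]]))
}

#' @rdname secr_step1_candidates
#' @export
secr_step2_candidates <- function() {
  list(~burn, ~tenure, ~harvest, ~tertiary_rd, ~canopy, ~water, ~ndvi, ~rddens)
}

#' Two-step SECR model selection by AICc
#'
#' Step 1 fits every candidate observation model with homogeneous density
#' (`D ~ 1`) and keeps the AICc-best (ties go to fewer parameters). Step 2
#' refits that observation model under each candidate density formula
#' (including `D ~ 1` itself, so a structured density must beat the
#' constant). Failed candidate fits are recorded and skipped, not fatal.
#'
#' @param history,detectors,mask Data as in [fit_secr()].
#' @param step1 List of candidate [secr_model()]s (density is forced to
#'   `~1`); default [secr_step1_candidates()].
#' @param step2 List of candidate density formulas; default
#'   [secr_step2_candidates()]. `~1` is prepended if absent.
#' @param distribution Passed to [fit_secr()].
#' @param ... Further arguments to [fit_secr()].
#' @return List with `base_model` (best step-1 model), `best_fit` (best
#'   step-2 `secr_fit`), `step1_table`, `step2_table`, `failures`.
#' @export
run_two_step <- function(history, detectors, mask,
                         step1 = secr_step1_candidates(),
                         step2 = secr_step2_candidates(),
                         distribution = "poisson", ...) {
  if (length(step1) == 0 || length(step2) == 0) {
    abort("candidate lists must be nonempty")
  }
  d_forms <- step2
  if (!any(vapply(d_forms, function(f) identical(deparse1(f[[2]]), "1"), logical(1)))) {
    d_forms <- c(list(~1), d_forms)
  }
  failures <- list()
  fit_one <- function(m, stage) {
    tryCatch(fit_secr(m, history, detectors, mask,
                      distribution = distribution, ...),
             error = function(e) {
               failures[[paste(stage, model_label(m))]] <<- conditionMessage(e)
               NULL
             })
  }
  s1_models <- lapply(step1, function(m) secr_model(m$lambda0, m$sigma, ~1))
  s1_fits <- lapply(s1_models, fit_one, stage = "step1")
  ok1 <- !vapply(s1_fits, is.null, logical(1))
  if (!any(ok1)) abort("every step-1 candidate failed to fit")
  t1 <- model_table(s1_fits[ok1])
  best1 <- s1_fits[ok1][[order(vapply(s1_fits[ok1], function(f) f$AICc, numeric(1)),
                               vapply(s1_fits[ok1], function(f) f$K, numeric(1)))[1]]]
  base <- best1$model

  s2_models <- lapply(d_forms, function(df) secr_model(base$lambda0, base$sigma, df))
  s2_fits <- lapply(s2_models, fit_one, stage = "step2")
  ok2 <- !vapply(s2_fits, is.null, logical(1))
  if (!any(ok2)) abort("every step-2 candidate failed to fit")
  t2 <- model_table(s2_fits[ok2])
  best2 <- s2_fits[ok2][[order(vapply(s2_fits[ok2], function(f) f$AICc, numeric(1)),
                               vapply(s2_fits[ok2], function(f) f$K, numeric(1)))[1]]]
  list(base_model = base, best_fit = best2,
       step1_table = t1, step2_table = t2, failures = failures)
}
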