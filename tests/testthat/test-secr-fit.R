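# SECR fitting, AICc machinery, prediction and region abundance.

world_cache <- new.env()
small_world <- function() {
  if (is.null(world_cache$w)) {
    world_cache$w <- make_test_world(seed = 21, extent = c(24, 24),
                                     n_rub = 20, n_fence = 6, n_occasions = 6)
  }
  world_cache$w
}
small_fit <- function() {
  if (is.null(world_cache$fit)) {
    w <- small_world()
    world_cache$fit <- fit_secr(secr_model(~1, ~1, ~1), w$captures,
                                w$detectors, w$mask)
  }
  world_cache$fit
}

test_that("a homogeneous fit recovers the generating parameters", {
  w <- small_world()
  fit <- small_fit()
  expect_true(fit$converged)
  est <- fit$estimates
  # truth within the 95% intervals on this one realization
  truth <- c(D = 0.08, lambda0 = 0.35, sigma = 2)
  for (p in names(truth)) {
    row <- est[est$parameter == p, ]
    expect_gt(truth[[p]], row$lcl * 0.999)
    expect_lt(truth[[p]], row$ucl * 1.001)
  }
  expect_equal(fit$n, attr(w$captures, "n_detected"))
  expect_equal(fit$AICc, aicc(fit$logLik, fit$K, fit$n))
})

test_that("poisson and binomial likelihoods give similar density estimates", {
  w <- small_world()
  fb <- fit_secr(secr_model(~1, ~1, ~1), w$captures, w$detectors, w$mask,
                 distribution = "binomial")
  fp <- small_fit()
  Dp <- fp$estimates$estimate[1]
  Db <- fb$estimates$estimate[1]
  expect_lt(abs(Dp - Db) / Dp, 0.05)
})

test_that("empty histories and undefined AICc are errors", {
  w <- small_world()
  expect_error(fit_secr(secr_model(), w$captures[0, ], w$detectors, w$mask),
               "empty")
  expect_error(aicc(-10, 5, 6), "n > K")
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-5)
})

test_that("model tables rank by AICc with normalized weights", {
  w <- small_world()
  f1 <- small_fit()
  f2 <- fit_secr(secr_model(~traptype, ~1, ~1), w$captures, w$detectors, w$mask)
  tb <- model_table(list(f2, f1))
  expect_equal(tb$dAICc[1], 0)
  expect_equal(sum(tb$w), 1)
  expect_true(all(diff(tb$AICc) >= 0))
  # mixed data sets refuse to rank
  w2 <- make_test_world(seed = 77, extent = c(24, 24), n_rub = 20,
                        n_fence = 6, n_occasions = 6)
  f3 <- fit_secr(secr_model(), w2$captures, w2$detectors, w2$mask)
  if (f3$n != f1$n) expect_error(model_table(list(f1, f3)), "comparable")
})

test_that("density prediction and region abundance are internally consistent", {
  w <- small_world()
  fit <- small_fit()
  surf <- predict_density(fit, w$mask)
  # D ~ 1: constant surface equal to the baseline estimate
  expect_equal(unname(unique(round(surf$density, 12))),
               unname(round(fit$estimates$estimate[1], 12)))
  # surface total equals Lambda
  expect_equal(sum(surf$density) * cell_area(w$mask), fit$Lambda,
               tolerance = 1e-9)

  ra <- region_abundance(fit, w$mask, region = "tenure", nsim = 200)
  expect_equal(sum(ra$N_hat), fit$Lambda, tolerance = 1e-9)
  expect_true(all(ra$lo <= ra$N_hat & ra$N_hat <= ra$hi))
  expect_equal(sum(ra$area), mask_area(w$mask))

  ft <- fit_secr(secr_model(~1, ~1, ~tenure), w$captures, w$detectors, w$mask)
  surf_t <- predict_density(ft, w$mask)
  expect_equal(length(unique(round(surf_t$density, 10))),
               length(unique(w$mask$tenure)))
  expect_error(predict_density(ft, dplyr::select(tibble::as_tibble(w$mask), -tenure)),
               "tenure")
})

test_that("two-step selection returns ranked tables and a base model", {
  w <- small_world()
  out <- run_two_step(w$captures, w$detectors, w$mask,
                      step1 = list(secr_model(~1, ~1)),
                      step2 = list(~1))
  expect_equal(nrow(out$step1_table), 1)
  expect_equal(out$step2_table$dAICc[1], 0)
  expect_identical(deparse(out$base_model$lambda0), "~1")
  expect_s3_class(out$best_fit, "secr_fit")
})

test_that("sigma and lambda0 compensate with little effect on density", {
  # dense array with near-saturated detection: the classic regime where the
  # sigma-lambda0 trade-off leaves the density estimate almost untouched
  traps <- make_detectors(x = rep(seq(0, 18, by = 2), 10),
                          y = rep(seq(0, 18, by = 2), each = 10),
                          usage = strrep("1", 7))
  gen <- build_mask(traps, buffer = 6, spacing = 2.5)
  tp <- true_params(beta_d = c("(Intercept)" = log(0.1)),
                    lambda0 = 0.8, sigma = 2, sex = "F")
  pop <- sim_population(gen, tp, seed = 4)
  caps <- sim_captures(pop, traps, tp, seed = 5)
  mask <- build_mask(traps, 3 * rpsv(caps, traps), 2.5)
  fit <- fit_secr(secr_model(), caps, traps, mask, n_starts = 1)
  des <- ursadens:::build_secr_design(fit$model, caps, traps, mask)
  prof <- lapply(c(0.9, 1, 1.1), function(mult) {
    lsig <- log(fit$estimates$estimate[3] * mult)
    opt <- optim(unname(fit$coefficients[1:2]),
                 function(p) ursadens:::secr_nll_impl(c(p, lsig), des, "poisson"),
                 method = "BFGS")
    c(D = unname(exp(opt$par[1])), l0 = unname(exp(opt$par[2])))
  })
  prof <- do.call(rbind, prof)
  # lambda0 declines steeply as sigma grows (inverse association)...
  expect_true(all(diff(prof[, "l0"]) < 0))
  expect_gt(diff(range(prof[, "l0"])) / mean(prof[, "l0"]), 0.2)
  # ...while density barely moves across the ridge
  expect_lt(diff(range(prof[, "D"])) / mean(prof[, "D"]), 0.05)
})
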