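# Used-available RSF fitting, binning, expected use and extrapolation.

test_that("logistic coefficients match the 2x2 closed form", {
  used <- tibble::tibble(v = c(rep(1, 6), rep(0, 4)))
  avail <- tibble::tibble(v = c(rep(1, 5), rep(0, 15)))
  m <- fit_rsf(used, avail, ~v)
  expect_equal(unname(m$coef["v"]), log(4.5), tolerance = 1e-6)

  # identical composition in both classes -> no selection
  m0 <- fit_rsf(avail, avail, ~v)
  expect_lt(abs(m0$coef["v"]), 1e-6)

  # duplicating the available set leaves non-intercept coefficients unchanged
  m2 <- fit_rsf(used, dplyr::bind_rows(avail, avail), ~v)
  expect_equal(unname(m2$coef["v"]), unname(m$coef["v"]), tolerance = 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  used <- tibble::tibble(v = rep(1, 10), w = rep(1, 10))
  avail <- tibble::tibble(v = rep(0, 50), w = rep(0, 50))
  expect_error(fit_rsf(used, avail, ~v), "separation")
  u2 <- tibble::tibble(a = rnorm(20))
  u2$b <- u2$a
  a2 <- tibble::tibble(a = rnorm(50))
  a2$b <- a2$a
  expect_error(fit_rsf(u2, a2, ~ a + b), "rank-deficient")
  expect_error(fit_rsf(u2[0, ], a2, ~a), "nonempty")
})

test_that("standardization is stored and reapplied at prediction", {
  set.seed(3)
  used <- tibble::tibble(v = rnorm(200, 2, 3))
  avail <- tibble::tibble(v = rnorm(2000, 0, 3))
  m <- fit_rsf(used, avail, ~v)
  expect_equal(m$std$variable, "v")
  sc <- predict_rsf(m, tibble::tibble(v = c(0, 1)))
  # score ratio equals exp(beta * delta_standardized)
  expect_equal(unname(log(sc[2] / sc[1])), unname(m$coef["v"] / m$std$sd),
               tolerance = 1e-9)
})

test_that("AIC selection prefers the generating model", {
  set.seed(11)
  avail <- tibble::tibble(v = rnorm(3000), z = rnorm(3000))
  keep <- runif(3000) < plogis(-2 + 1.2 * avail$v)
  used <- avail[keep, ]
  sel <- select_rsf(list(~z, ~v, ~ v + z), used, avail)
  expect_identical(deparse1(sel$model$formula[[2]]), "v")
  expect_equal(sel$table$dAIC[1], 0)
  expect_equal(sum(sel$table$w), 1)
  # single candidate trivially selected
  one <- select_rsf(list(~v), used, avail)
  expect_identical(deparse1(one$model$formula[[2]]), "v")
})

test_that("binning scales by the maximum and conserves area", {
  # all equal scores land in the top bin
  b <- bin_scores(rep(3.3, 12), area = 2)
  expect_equal(b$bins$area[10], 24)
  expect_equal(sum(b$bins$area), 24)

  set.seed(5)
  sc <- runif(10000)
  b2 <- bin_scores(sc, area = 1)
  expect_true(all(abs(b2$bins$area / 10000 - 0.1) < 0.012))
  expect_equal(sum(b2$bins$area), 10000)
  expect_equal(b2$bins$w, seq(0.05, 0.95, by = 0.1))

  # scale invariance of the whole bin structure
  b3 <- bin_scores(sc * 37.5, area = 1)
  expect_identical(b3$assignment, b2$assignment)
  expect_equal(b3$bins, b2$bins)

  expect_error(bin_scores(rep(0, 5), 1), "zero")
  expect_error(bin_scores(c(1, NA), 1), "finite")
})

test_that("expected use follows w*A normalization", {
  b <- tibble::tibble(bin = 1:2, w = c(0.25, 0.75), area = c(10, 10))
  u <- expected_use(b)
  expect_equal(u$U, c(0.25, 0.75))
  # doubling areas leaves U unchanged
  b2 <- dplyr::mutate(b, area = area * 2)
  expect_equal(expected_use(b2)$U, u$U)
  # single nonempty bin takes all use
  b3 <- tibble::tibble(bin = 1:3, w = c(0.1, 0.5, 0.9), area = c(0, 0, 5))
  expect_equal(expected_use(b3)$U, c(0, 0, 1))
  expect_error(expected_use(dplyr::mutate(b, area = 0)), "zero")
})

test_that("area of inference drops the lowest bins", {
  sc <- seq(0.05, 1, by = 0.05)  # hits every bin x2
  b <- bin_scores(sc, area = 1)
  keep0 <- area_of_inference(b, 0)
  expect_true(all(keep0))
  keep3 <- area_of_inference(b, 3)
  expect_equal(sum(keep3), sum(b$bins$n_cells[4:10]))
  keep9 <- area_of_inference(b, 9)
  expect_equal(sum(keep9), b$bins$n_cells[10])
  expect_error(area_of_inference(b, 10), "< the number of bins")
})

test_that("extrapolation conserves abundance and scales with U/A", {
  # two bins, equal areas, midpoints 0.25 and 0.75 -> density ratio U2/U1 = 3
  two <- structure(
    list(bins = tibble::tibble(bin = 1:2, lo = c(0, 0.5), hi = c(0.5, 1),
                               w = c(0.25, 0.75), n_cells = c(5L, 5L),
                               area = c(20, 20)),
         assignment = rep(1:2, each = 5), n_bins = 2L),
    class = "rsf_bins")
  ref <- reference_estimate(50, 40, 60, area = 1000)
  ex <- extrapolate_density(ref, two, two$assignment)
  expect_equal(sum(ex$bins$N_hat), ref$N_hat, tolerance = 1e-12)
  expect_equal(ex$bins$D_hat[2] / ex$bins$D_hat[1], 3, tolerance = 1e-9)
  expect_true(all(ex$cells$lo <= ex$cells$density &
                    ex$cells$density <= ex$cells$hi))
  # scores from bin_scores feed through conservation too
  b <- bin_scores(c(rep(0.25, 5), rep(0.75, 5)), area = 4)
  exb <- extrapolate_density(ref, b, b$assignment)
  expect_equal(sum(exb$bins$N_hat), ref$N_hat, tolerance = 1e-12)

  # single bin: every target cell gets N_hat / ref area (per 1,000 km^2)
  b1 <- bin_scores(rep(1, 4), area = 250)
  ex1 <- extrapolate_density(ref, b1, rep(10L, 7))
  expect_equal(unique(ex1$cells$density), 1000 * ref$N_hat / 1000)

  # a target bin missing from the reference maps to the nearest populated one
  expect_warning(
    ex2 <- extrapolate_density(ref, b1, c(10L, 2L)),
    "nearest populated")
  expect_equal(ex2$cells$density[2], ex2$cells$density[1])
})

test_that("reference estimates validate their interval", {
  expect_error(reference_estimate(50, 55, 60, 100), "lo <= density")
  r <- reference_estimate(48.3, 40.2, 57.3, area = 500)
  expect_equal(r$N_hat, 48.3 * 0.5)
})
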