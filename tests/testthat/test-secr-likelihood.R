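# SECR likelihood: detection function, hand-checked values, and equivalence
# with a brute-force enumeration oracle on tiny instances.

test_that("hazard half-normal detection function has its closed forms", {
  expect_equal(hazard(0, 0.3, 2), 0.3)
  expect_equal(hazard(2 * sqrt(2 * log(2)), 0.3, 2), 0.15)  # half-hazard distance
  expect_equal(hazard(3, 0.3, 1e9), 0.3, tolerance = 1e-12) # sigma -> Inf limit
  expect_error(hazard(1, 0.3, -1), "sigma")

  expect_equal(hazard_to_prob(0), 0)
  expect_equal(hazard_to_prob(log(2)), 0.5)
  expect_equal(hazard_to_prob(10), 1 - exp(-10))
  expect_error(hazard_to_prob(-0.1), ">= 0")
})

one_cell_world <- function() {
  mask <- new_mask_grid_for_test(data.frame(x = 0, y = 0), 1)
  det <- make_detectors(0, 0, usage = "1")
  hist <- tibble::tibble(individual = "a", occasion = 1L, detector = "d01")
  list(mask = mask, det = det, hist = hist)
}

test_that("negative log-likelihood matches the hand-computed single-cell value", {
  w <- one_cell_world()
  th <- c(log(1), log(log(2)), log(1))  # D = 1, lambda0 = ln 2 (p = 0.5), sigma = 1
  nll <- secr_negloglik(th, model = secr_model(), history = w$hist,
                        detectors = w$det, mask = w$mask)
  expect_equal(nll, -(log(0.5) - 0.5), tolerance = 1e-9)
})

test_that("with no detected animals the Poisson likelihood reduces to Lambda pbar", {
  w <- one_cell_world()
  th <- c(log(2), log(log(2)), log(1))   # Lambda = 2, pdot = 0.5
  nll <- secr_negloglik(th, model = secr_model(), history = w$hist[0, ],
                        detectors = w$det, mask = w$mask)
  expect_equal(nll, 1.0, tolerance = 1e-9)
})

test_that("likelihood equals the brute-force enumeration oracle", {
  for (seed in 1:6) {
    inst <- tiny_instance(seed)
    for (distr in c("poisson", "binomial")) {
      D <- 0.9; l0 <- 0.4; sg <- 1.7
      th <- c(log(D), log(l0), log(sg))
      nll <- secr_negloglik(th, model = secr_model(), history = inst$hist,
                            detectors = inst$det, mask = inst$mask,
                            distribution = distr)
      K <- nrow(inst$det); S <- 2
      oracle <- brute_negloglik(
        detections = data.frame(
          individual = inst$hist$individual,
          occasion = inst$hist$occasion,
          detector_index = match(inst$hist$detector, inst$det$detector)),
        det_xy = inst$det, mask_xy = inst$mask,
        cell_a = cell_area(inst$mask),
        D_cells = rep(D, nrow(inst$mask)),
        lambda0_ks = matrix(l0, K, S), sigma_ks = matrix(sg, K, S),
        usage = matrix(1, K, S), distribution = distr)
      expect_equal(nll, oracle, tolerance = 1e-8)
    }
  }
})

test_that("likelihood with a bk response equals the oracle", {
  for (seed in 7:10) {
    inst <- tiny_instance(seed)
    bk_coef <- 0.8
    th <- c(log(0.9), log(0.4), bk_coef, log(1.7))
    nll <- secr_negloglik(th, model = secr_model(~bk, ~1, ~1),
                          history = inst$hist, detectors = inst$det,
                          mask = inst$mask)
    K <- nrow(inst$det)
    oracle <- brute_negloglik(
      detections = data.frame(
        individual = inst$hist$individual,
        occasion = inst$hist$occasion,
        detector_index = match(inst$hist$detector, inst$det$detector)),
      det_xy = inst$det, mask_xy = inst$mask,
      cell_a = cell_area(inst$mask),
      D_cells = rep(0.9, nrow(inst$mask)),
      lambda0_ks = matrix(0.4, K, 2), sigma_ks = matrix(1.7, K, 2),
      usage = matrix(1, K, 2), bk_mult = exp(bk_coef))
    expect_equal(nll, oracle, tolerance = 1e-8)
  }
})

test_that("single-animal history probabilities sum to one over all histories", {
  det <- make_detectors(c(0, 2), c(0, 0), S = 2)
  mask <- new_mask_grid_for_test(data.frame(x = c(0, 1), y = c(0, 1)), 1)
  sums <- brute_history_prob_sum(det, mask,
                                 lambda0_ks = matrix(0.5, 2, 2),
                                 sigma_ks = matrix(1.2, 2, 2),
                                 usage = matrix(1, 2, 2), bk_mult = exp(0.7))
  expect_equal(sums, rep(1, 2), tolerance = 1e-10)
})

test_that("likelihood is invariant to relabeling individuals and permuting detectors", {
  inst <- tiny_instance(11)
  th <- c(log(0.7), log(0.3), log(2))
  base <- secr_negloglik(th, model = secr_model(), history = inst$hist,
                         detectors = inst$det, mask = inst$mask)
  # relabel individuals
  h2 <- inst$hist
  h2$individual <- chartr("i", "z", h2$individual)
  expect_equal(secr_negloglik(th, model = secr_model(), history = h2,
                              detectors = inst$det, mask = inst$mask), base)
  # permute detector rows
  perm <- sample(nrow(inst$det))
  expect_equal(secr_negloglik(th, model = secr_model(), history = inst$hist,
                              detectors = inst$det[perm, ], mask = inst$mask),
               base)
})

test_that("invalid detection records are rejected", {
  det <- make_detectors(0, 0, usage = "10")
  h <- tibble::tibble(individual = "a", occasion = 2L, detector = "d01")
  mask <- new_mask_grid_for_test(data.frame(x = 0, y = 0), 1)
  expect_error(
    secr_negloglik(c(0, 0, 0), model = secr_model(), history = h,
                   detectors = det, mask = mask),
    "zero usage")
})
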