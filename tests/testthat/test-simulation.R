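# Synthetic-data generator: landscapes, detectors, populations, captures.

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(spacing = -1), "spacing")
  expect_error(sim_config(tenure_props = c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(sim_config(n_occasions = 1), "occasions")
  expect_error(true_params(sigma = 0), "sigma")
  expect_error(true_params(beta_d = c(a = 1)), "Intercept")
})

test_that("landscape generation is deterministic and honours tenure shares", {
  cfg <- sim_config(extent = c(80, 90), spacing = 2, seed = 42)
  l1 <- sim_landscape(cfg)
  l2 <- sim_landscape(cfg)
  expect_identical(tibble::as_tibble(l1), tibble::as_tibble(l2))
  expect_equal(nrow(l1), 40 * 45)

  shares <- prop.table(table(l1$tenure))
  target <- c(protected = 0.14, crown = 0.34, private = 0.52)
  expect_true(all(abs(shares[names(target)] - target) < 0.02))

  # cells carry every covariate, complete
  covn <- c("ndvi", "canopy", "burn", "harvest", "water", "tertiary_rd", "rddens")
  expect_true(all(covn %in% names(l1)))
  expect_false(anyNA(tibble::as_tibble(l1)))
  expect_true(all(l1$ndvi >= 0 & l1$ndvi <= 1))
  expect_true(all(l1$canopy >= 0 & l1$canopy <= 100))
  expect_true(all(l1$harvest >= 0))
  expect_true(all(l1$harvest[l1$tenure == "protected"] == 0))
})

test_that("burn fraction zero yields no burned cells", {
  cfg <- sim_config(extent = c(20, 20), spacing = 2, burn_fraction = 0, seed = 3)
  expect_true(all(sim_landscape(cfg)$burn == 0))
})

test_that("opportunistic detectors tile the extent at cell centroids", {
  cfg <- sim_config(extent = c(14, 14), spacing = 2, n_rub = 5, n_fence = 0,
                    opp_cell_size = 7, n_occasions = 5, seed = 1)
  det <- sim_detectors(sim_landscape(cfg), cfg)
  opp <- det[det$type == "opp", ]
  expect_equal(nrow(opp), 4)
  expect_setequal(paste(opp$x, opp$y),
                  c("3.5 3.5", "10.5 3.5", "3.5 10.5", "10.5 10.5"))
  # opp usage: only the last occasion
  expect_true(all(opp$usage == "00001"))
  sys <- det[det$type != "opp", ]
  expect_true(all(sys$usage == "11110"))
})

test_that("detector counts are honoured and over-requests fail", {
  cfg <- sim_config(extent = c(14, 14), spacing = 2, n_rub = 0, n_fence = 4,
                    seed = 2)
  ls <- sim_landscape(cfg)
  det <- sim_detectors(ls, cfg)
  expect_setequal(as.character(unique(det$type)), c("fence", "opp"))
  cfg2 <- sim_config(extent = c(6, 6), spacing = 2, n_rub = 100, seed = 2)
  expect_error(sim_detectors(sim_landscape(cfg2), cfg2), "only")
})

test_that("population counts follow the Poisson intensity", {
  # uniform D = 0.05 over ~1000 km^2: mean N over replicates near 50
  cfg <- sim_config(extent = c(32, 32), spacing = 2, seed = 9)
  ls <- sim_landscape(cfg)
  tr <- true_params(beta_d = c("(Intercept)" = log(0.05)))
  area <- mask_area(ls)
  mu <- 0.05 * area
  n_rep <- 400
  ns <- vapply(seq_len(n_rep), function(i) {
    attr(sim_population(ls, tr, seed = i), "N_true")
  }, numeric(1))
  se <- sqrt(mu / n_rep)
  expect_lt(abs(mean(ns) - mu), 3.5 * se)
})

test_that("tenure density effects reproduce intensity ratios", {
  cfg <- sim_config(extent = c(100, 100), spacing = 2, seed = 5)
  ls <- sim_landscape(cfg)
  tr <- true_params(d_formula = ~tenure,
                    beta_d = c("(Intercept)" = log(0.2),
                               tenurecrown = -1, tenureprivate = 0))
  counts <- c(crown = 0, protected = 0)
  for (i in 1:20) {
    pop <- sim_population(ls, tr, seed = 1000 + i)
    band <- cumsum(c(0.52, 0.34)) * 100
    counts["crown"] <- counts["crown"] +
      sum(pop$x >= band[1] & pop$x < band[2])
    counts["protected"] <- counts["protected"] + sum(pop$x >= band[2])
  }
  area_ratio <- 0.34 / 0.14
  dens_ratio <- (counts["crown"] / area_ratio) / counts["protected"]
  expect_lt(abs(dens_ratio - exp(-1)), 0.06)
})

test_that("density linear predictor overflow is caught", {
  cfg <- sim_config(extent = c(10, 10), spacing = 2, seed = 1)
  ls <- sim_landscape(cfg)
  tr <- true_params(beta_d = c("(Intercept)" = 60))
  expect_error(sim_population(ls, tr), "overflow")
})

test_that("capture probability matches the hazard model at distance zero", {
  # one animal on a trap, lambda0 = 0.1, 7 occasions: E[detections] = 7(1-e^-0.1)
  det <- make_detectors(0, 0, usage = "1111111")
  centers <- tibble::tibble(x = 0, y = 0, sex = "F")
  tr <- true_params(lambda0 = 0.1, sigma = 2)
  n_rep <- 4000
  tot <- vapply(seq_len(n_rep), function(i) {
    nrow(sim_captures(centers, det, tr, seed = i))
  }, numeric(1))
  p <- 1 - exp(-0.1)
  mu <- 7 * p
  se <- sqrt(7 * p * (1 - p) / n_rep)
  expect_lt(abs(mean(tot) - mu), 3 * se)
})

test_that("detection is essentially impossible far beyond the kernel", {
  det <- make_detectors(20, 0, usage = strrep("1", 7))  # 10 sigma away
  centers <- tibble::tibble(x = 0, y = 0, sex = "F")
  tr <- true_params(lambda0 = 0.5, sigma = 2)
  hits <- sum(vapply(1:200, function(i) {
    nrow(sim_captures(centers, det, tr, seed = i))
  }, numeric(1)))
  expect_equal(hits, 0)
  # direct probability check
  expect_lt(hazard_to_prob(hazard(20, 0.5, 2)), 1e-10)
})

test_that("a positive bk effect raises post-first-detection capture rates", {
  det <- make_detectors(0, 0, usage = strrep("1", 8))
  centers <- tibble::tibble(x = 1, y = 0, sex = "F")
  tr_bk <- true_params(lambda0 = 0.3, sigma = 2, beta_bk = 1.5)
  post <- naive <- c(hit = 0, n = 0)
  for (i in 1:600) {
    caps <- sim_captures(centers, det, tr_bk, seed = i)
    if (nrow(caps) == 0) next
    f <- min(caps$occasion)
    later <- setdiff((f + 1):8, integer(0))
    if (f < 8) {
      post["hit"] <- post["hit"] + sum(caps$occasion > f)
      post["n"] <- post["n"] + (8 - f)
    }
    naive["hit"] <- naive["hit"] + 1
    naive["n"] <- naive["n"] + f
  }
  p_post <- post["hit"] / post["n"]
  p_naive <- naive["hit"] / naive["n"]
  expect_gt(p_post, p_naive)
})

test_that("expected detections are monotone in lambda0 and sigma", {
  cfg <- sim_config(extent = c(20, 20), spacing = 2, n_rub = 15, n_fence = 0,
                    n_occasions = 5, seed = 4)
  ls <- sim_landscape(cfg)
  det <- sim_detectors(ls, cfg)
  count_at <- function(l0, sg) {
    tr <- true_params(beta_d = c("(Intercept)" = log(0.15)),
                      lambda0 = l0, sigma = sg)
    pop <- sim_population(ls, tr, seed = 77)
    sum(vapply(1:30, function(i) nrow(sim_captures(pop, det, tr, seed = i)),
               numeric(1)))
  }
  by_l0 <- c(count_at(0.05, 2), count_at(0.2, 2), count_at(0.8, 2))
  by_sg <- c(count_at(0.2, 1), count_at(0.2, 2), count_at(0.2, 4))
  expect_true(all(diff(by_l0) > 0))
  expect_true(all(diff(by_sg) > 0))
})

test_that("simulation is fully reproducible from seeds", {
  w1 <- make_test_world(seed = 31)
  w2 <- make_test_world(seed = 31)
  expect_identical(w1$detectors, w2$detectors)
  expect_identical(w1$captures, w2$captures)
  expect_identical(tibble::as_tibble(w1$mask), tibble::as_tibble(w2$mask))
})
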