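# Shared fixture builders (all data generated in code).

tt_levels <- c("rub", "fence", "opp")

# Minimal detector tibble from coordinates.
make_detectors <- function(x, y, type = "rub", usage = NULL, S = 1) {
  n <- length(x)
  if (is.null(usage)) usage <- strrep("1", S)
  tibble::tibble(
    detector = sprintf("d%02d", seq_len(n)), x = x, y = y,
    type = factor(rep_len(type, n), levels = tt_levels),
    usage = rep_len(usage, n)
  )
}

# A small simulated world: landscape, detectors, one sex's population and
# captures, plus a covariate-attached SECR mask.
make_test_world <- function(seed = 1, extent = c(30, 30), spacing = 2,
                            n_rub = 30, n_fence = 10, n_occasions = 6,
                            truth = NULL, mask_spacing = 2,
                            buffer = NULL) {
  cfg <- sim_config(extent = extent, spacing = spacing, n_rub = n_rub,
                    n_fence = n_fence, n_occasions = n_occasions, seed = seed)
  truth <- truth %||% true_params(beta_d = c("(Intercept)" = log(0.08)),
                                  lambda0 = 0.35, sigma = 2, sex = "F")
  landscape <- sim_landscape(cfg)
  detectors <- sim_detectors(landscape, cfg)
  pop <- sim_population(landscape, truth, seed = seed + 100)
  caps <- sim_captures(pop, detectors, truth, seed = seed + 200)
  mask <- NULL
  if (nrow(caps) > 0) {
    b <- buffer %||% (3 * rpsv(caps, detectors))
    mask <- clip_mask(build_mask(detectors, b, mask_spacing),
                      c(0, extent[1]), c(0, extent[2]))
    covn <- setdiff(names(landscape), c("x", "y"))
    mask <- attach_covariates(
      mask, setNames(lapply(covn, function(v) landscape[c("x", "y", v)]), covn))
  }
  list(config = cfg, truth = truth, landscape = landscape,
       detectors = detectors, pop = pop, captures = caps, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_mask_grid_for_test <- function(df, spacing) {
  ursadens:::new_mask_grid(tibble::as_tibble(df), spacing)
}

# Random tiny SECR instance (<= 3 traps / 3 cells / 2 occasions) for
# comparison with the brute-force oracle.
tiny_instance <- function(seed, S = 2, K = 3, M = 3) {
  set.seed(seed)
  det <- make_detectors(runif(K, 0, 4), runif(K, 0, 4), S = S,
                        type = sample(c("rub", "fence"), K, replace = TRUE))
  mask <- new_mask_grid_for_test(
    data.frame(x = runif(M, 0, 4), y = runif(M, 0, 4)), 1.5)
  n_ind <- sample(1:3, 1)
  hist <- purrr::map_dfr(seq_len(n_ind), function(i) {
    nd <- sample(1:3, 1)
    tibble::tibble(
      individual = paste0("i", i),
      occasion = sample(seq_len(S), nd, replace = TRUE),
      detector = sample(det$detector, nd, replace = TRUE)
    ) |> dplyr::distinct()
  })
  list(det = det, mask = mask, hist = hist)
}
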