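# Independent brute-force SECR likelihood for tiny instances.
#
# Everything here is computed by direct looping over individuals, detectors,
# occasions and mask cells from explicit parameter values (no design
# matrices, no shared code with the package's likelihood). Suitable only for
# a handful of cells/traps/occasions.

# detections: data frame (individual, occasion, detector_index)
# lambda0_ks, sigma_ks: K x S matrices of naive detection parameters
# usage: K x S 0/1 matrix; bk_mult: multiplier on lambda0 once an individual
# has been detected at that trap on an earlier occasion.
brute_negloglik <- function(detections, det_xy, mask_xy, cell_a, D_cells,
                            lambda0_ks, sigma_ks, usage, bk_mult = 1,
                            distribution = "poisson") {
  K <- nrow(det_xy); S <- ncol(usage); M <- nrow(mask_xy)
  ids <- unique(detections$individual)
  n <- length(ids)

  p_of <- function(k, s, m, boosted) {
    d2 <- (det_xy$x[k] - mask_xy$x[m])^2 + (det_xy$y[k] - mask_xy$y[m])^2
    lam <- lambda0_ks[k, s] * (if (boosted) bk_mult else 1) *
      exp(-d2 / (2 * sigma_ks[k, s]^2))
    1 - exp(-lam)
  }

  # Pr(at least one detection | center in cell m), naive parameters.
  pdot <- numeric(M)
  for (m in seq_len(M)) {
    surv <- 1
    for (k in seq_len(K)) for (s in seq_len(S)) {
      if (usage[k, s] == 1) surv <- surv * (1 - p_of(k, s, m, FALSE))
    }
    pdot[m] <- 1 - surv
  }
  Lambda <- sum(D_cells * cell_a)
  Lp <- sum(pdot * D_cells * cell_a)

  sum_li <- 0
  for (id in ids) {
    drows <- detections[detections$individual == id, , drop = FALSE]
    li <- 0
    for (m in seq_len(M)) {
      pr <- 1
      first_at <- tapply(drows$occasion, drows$detector_index, min)
      for (k in seq_len(K)) for (s in seq_len(S)) {
        if (usage[k, s] != 1) next
        f <- first_at[as.character(k)]
        boosted <- !is.na(f) && s > f
        p <- p_of(k, s, m, boosted)
        caught <- any(drows$detector_index == k & drows$occasion == s)
        pr <- pr * if (caught) p else (1 - p)
      }
      li <- li + pr * D_cells[m] * cell_a
    }
    sum_li <- sum_li + log(li)
  }
  if (distribution == "poisson") {
    Lp - sum_li + lfactorial(n)
  } else {
    pbar <- Lp / Lambda
    -(lgamma(Lambda + 1) - lgamma(Lambda - n + 1) - lfactorial(n) +
        (Lambda - n) * log(1 - pbar) - n * log(Lambda) + sum_li)
  }
}

# Enumerate all single-animal histories on a tiny instance and return
# sum over histories of Pr(history | center m) for each m (should be 1).
brute_history_prob_sum <- function(det_xy, mask_xy, lambda0_ks, sigma_ks,
                                   usage, bk_mult = 1) {
  K <- nrow(det_xy); S <- ncol(usage)
  cells_on <- which(usage == 1, arr.ind = TRUE)  # rows: (k, s)
  cells_on <- cells_on[order(cells_on[, 2], cells_on[, 1]), , drop = FALSE]
  nc <- nrow(cells_on)
  sums <- numeric(nrow(mask_xy))
  for (m in seq_len(nrow(mask_xy))) {
    tot <- 0
    for (code in 0:(2^nc - 1)) {
      bits <- as.integer(intToBits(code))[seq_len(nc)]
      pr <- 1
      seen <- rep(FALSE, K)
      for (s in seq_len(S)) {
        seen_before <- seen
        for (j in seq_len(nc)) {
          if (cells_on[j, 2] != s) next
          k <- cells_on[j, 1]
          d2 <- (det_xy$x[k] - mask_xy$x[m])^2 + (det_xy$y[k] - mask_xy$y[m])^2
          lam <- lambda0_ks[k, s] * (if (seen_before[k]) bk_mult else 1) *
            exp(-d2 / (2 * sigma_ks[k, s]^2))
          p <- 1 - exp(-lam)
          if (bits[j] == 1) {
            pr <- pr * p
            seen[k] <- TRUE
          } else {
            pr <- pr * (1 - p)
          }
        }
      }
      tot <- tot + pr
    }
    sums[m] <- tot
  }
  sums
}
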