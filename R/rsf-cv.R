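# k-fold Spearman cross-validation of RSF predictive ability
# (Boyce-style evaluation against withheld presences).

#' k-fold Spearman cross-validation of an RSF
#'
#' Repeatedly partitions the used points into `folds` folds; for each fold
#' the model is refitted on the remaining used points (against the full
#' available set), cell scores are re-binned into `n_bins` ranks, and the
#' withheld used points are tallied per bin. The per-fold statistic is
#' Spearman's rank correlation between bin rank and the (by default
#' area-adjusted) frequency of withheld points; `rs_bar` averages over all
#' folds and repeats. A strongly predictive RSF concentrates withheld
#' presences in high-ranked bins (`rs_bar` near 1); a model no better than
#' chance hovers near 0.
#'
#' @param model An `rsf_model` (carries its own used/available data).
#' @param cells Data frame of scoring cells with the model covariates
#'   (typically the mask restricted to the area of inference).
#' @param folds,repeats Cross-validation design (defaults 10 and 10).
#' @param n_bins Number of score bins (default 10).
#' @param area_adjust Divide per-bin frequencies by bin area before ranking
#'   (default `TRUE`; set `FALSE` for raw frequencies).
#' @param cell_area Area per scoring cell (scalar or vector), used when
#'   `area_adjust = TRUE`.
#' @param seed Integer seed; fixes the fold assignments.
#' @return An object of class `rsf_cv`: `rs_bar`, per-fold tibble
#'   `results` (`rep`, `fold`, `rs`, `n_test`), and the design settings.
#' @export
kfold_cv <- function(model, cells, folds = 10, repeats = 10, n_bins = 10,
                     area_adjust = TRUE, cell_area = 1, seed = 1L) {
  stopifnot(inherits(model, "rsf_model"))
  used <- model$used
  if (nrow(used) < folds) abort("need at least `folds` used points")
  if (length(cell_area) == 1) cell_area <- rep(cell_area, nrow(cells))
  res <- with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fold_id <- sample(rep_len(seq_len(folds), nrow(used)))
      purrr::map_dfr(seq_len(folds), function(f) {
        test <- used[fold_id == f, , drop = FALSE]
        train <- used[fold_id != f, , drop = FALSE]
        if (nrow(test) == 0) {
          inform(sprintf("repeat %d fold %d has no test points; skipped", r, f))
          return(tibble::tibble(rep = r, fold = f, rs = NA_real_, n_test = 0L))
        }
        m_f <- fit_rsf(train, model$available, model$formula)
        sc_cells <- predict_rsf(m_f, cells)
        mx <- max(sc_cells)
        if (mx == 0) return(tibble::tibble(rep = r, fold = f, rs = NA_real_,
                                           n_test = nrow(test)))
        bins <- bin_scores(sc_cells, cell_area, n_bins)
        # Withheld points binned on the same max-scaled scale as the cells.
        sc_test <- pmin(predict_rsf(m_f, test) / mx, 1)
        tb <- pmax(1L, as.integer(ceiling(sc_test * n_bins)))
        freq <- tabulate(tb, n_bins)
        keep <- bins$bins$area > 0
        adj <- if (area_adjust) freq[keep] / bins$bins$area[keep] else freq[keep]
        rs <- suppressWarnings(
          cor(bins$bins$bin[keep], adj, method = "spearman")
        )
        tibble::tibble(rep = r, fold = f, rs = rs, n_test = nrow(test))
      })
    })
  })
  structure(
    list(rs_bar = mean(res$rs, na.rm = TRUE), results = res,
         folds = folds, repeats = repeats, n_bins = n_bins,
         area_adjust = area_adjust, seed = seed),
    class = "rsf_cv"
  )
}

#' @export
print.rsf_cv <- function(x, ...) {
  cat(sprintf("RSF %d-fold CV x %d repeats: mean Spearman rs = %.3f\n",
              x$folds, x$repeats, x$rs_bar))
  invisible(x)
}
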