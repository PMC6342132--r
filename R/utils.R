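# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Squared Euclidean distance matrix between two point sets (planar km).
dist2_matrix <- function(a, b) {
  outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
}

#' Expand a detector usage string into a 0/1 matrix
#'
#' Detector tables store per-occasion effort as a compact string of 0/1
#' characters (e.g. `"1111110"`: active on the seven systematic occasions,
#' inactive on the opportunistic one). This expands it to a detectors x
#' occasions matrix.
#'
#' @param detectors A detector tibble with a `usage` character column.
#' @return Integer matrix, detectors in rows, occasions in columns.
#' @export
usage_matrix <- function(detectors) {
  stopifnot(is.data.frame(detectors), "usage" %in% names(detectors))
  nch <- unique(nchar(detectors$usage))
  if (length(nch) != 1) {
    abort("all detectors must have usage strings of equal length (one per occasion)")
  }
  m <- do.call(rbind, lapply(strsplit(detectors$usage, ""), as.integer))
  rownames(m) <- detectors$detector
  m
}

# Time-varying grizzly-bear-presence covariate as a detectors x occasions
# matrix, from gb_1..gb_S columns (all zero if absent).
gb_matrix <- function(detectors, n_occasions) {
  cols <- paste0("gb_", seq_len(n_occasions))
  if (!all(cols %in% names(detectors))) {
    return(matrix(0L, nrow(detectors), n_occasions,
                  dimnames = list(detectors$detector, NULL)))
  }
  m <- as.matrix(detectors[cols])
  dimnames(m) <- list(detectors$detector, NULL)
  m
}

# Pretty number of occasions implied by a detector table.
n_occasions_of <- function(detectors) unique(nchar(detectors$usage))[1]

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}
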