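# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the upper-triangle (off-diagonal) values of a symmetric matrix
#' in a fixed pair order.
#' @noRd
upper_tri_values <- function(m) m[upper.tri(m)]

#' Validate a symmetric labelled distance-like matrix.
#' @noRd
check_dist_matrix <- function(m, zero_diag = TRUE, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop(what, " must carry identical row and column labels", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop(what, " labels must be unique", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop(what, " must be symmetric", call. = FALSE)
  if (zero_diag && any(abs(diag(m)) > 1e-12))
    stop(what, " must have a zero diagonal", call. = FALSE)
  invisible(m)
}

#' Align matrix B onto the labels of matrix A.
#' @noRd
align_labels <- function(a, b, what = "matrices") {
  la <- rownames(a); lb <- rownames(b)
  if (!setequal(la, lb))
    stop(what, " have mismatched labels", call. = FALSE)
  b[la, la, drop = FALSE]
}

#' Numerically stable log(sum(exp(x))) by row.
#' @noRd
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

#' Deterministic per-stage seed derived from a master seed.
#'
#' Keeps every derived seed in the 32-bit signed range. The scheme
#' (master * 1000003 + k) mod (2^31 - 1) is documented so that pipeline
#' stages are individually reproducible.
#' @param master master integer seed
#' @param k stage index (small integer)
#' @return an integer seed
#' @export
stage_seed <- function(master, k) {
  as.integer((abs(as.numeric(master)) * 1000003 + as.numeric(k)) %% 2147483647)
}
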