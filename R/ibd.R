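# Isolation by distance: Rousset linearisation, Mantel permutation tests,
# and a slope-uncertainty equivalence test with relocation counterfactuals.

#' Rousset linearisation of a theta matrix
#'
#' Elementwise `y = theta / (1 - theta)`, the response that is linear in
#' distance under one-dimensional isolation by distance. Negative theta
#' passes through to (slightly) negative y; theta = 1 is a singularity.
#'
#' @param fst a `pairwise_fst` object from [pairwise_fst_matrix()] or a
#'   symmetric labelled theta matrix.
#' @return Symmetric labelled matrix of linearised values, zero diagonal.
#' @export
rousset_linearize <- function(fst) {
  th <- if (inherits(fst, "pairwise_fst")) fst$theta else fst
  check_dist_matrix(th, zero_diag = TRUE, what = "theta matrix")
  sing <- which(th >= 1 & upper.tri(th), arr.ind = TRUE)
  if (nrow(sing))
    stop("singularity: theta = 1 for pair ",
         rownames(th)[sing[1, 1]], " / ", colnames(th)[sing[1, 2]],
         call. = FALSE)
  y <- th / (1 - th)
  diag(y) <- 0
  y
}

#' Ordinary least squares isolation-by-distance regression
#'
#' Regresses the upper-triangle linearised genetic distances on the
#' upper-triangle stream distances (each unordered pair once), with
#' intercept. The OLS slope standard error is reported for use by the
#' equivalence test; significance of the IBD relationship itself is *not*
#' taken from OLS (pairs are not independent) — use [mantel_test()].
#'
#' @param y linearised genetic-distance matrix.
#' @param d stream-distance matrix (km) with matching labels.
#' @return List of class `ibd_fit`: `slope`, `intercept`, `se_slope`,
#'   `n_pairs`, plus the aligned `y` and `d` matrices.
#' @export
ibd_regression <- function(y, d) {
  check_dist_matrix(y, what = "y")
  check_dist_matrix(d, what = "d")
  d <- align_labels(y, d, "y and d")
  if (nrow(y) < 3L) stop("need at least 3 populations", call. = FALSE)
  yy <- upper_tri_values(y); dd <- upper_tri_values(d)
  if (stats::var(dd) == 0) stop("degenerate design: constant distances", call. = FALSE)
  fit <- stats::lm(yy ~ dd)
  # a perfect fit is a legitimate input (exact-recovery checks); lm's
  # summary warns about it, harmlessly
  sm <- suppressWarnings(summary(fit)$coefficients)
  se <- if (nrow(sm) == 2L) sm["dd", "Std. Error"] else NA_real_
  if (!is.finite(se)) se <- 0   # perfect fit: zero residual variance
  structure(list(slope = unname(stats::coef(fit)["dd"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 se_slope = se, n_pairs = length(yy), y = y, d = d),
            class = "ibd_fit")
}

#' Mantel permutation test of association between two distance matrices
#'
#' The statistic is the Pearson correlation of upper-triangle entries; the
#' null distribution is built by jointly permuting rows and columns of `b`.
#' Ties count as at-least-as-extreme and the p-value uses the never-zero
#' convention `(1 + extreme) / (n_perm + 1)`.
#'
#' @param a,b symmetric labelled matrices with matching label sets.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail `"greater"` (positive association, the default for isolation
#'   by distance) or `"less"`.
#' @return List with `rho`, `p_value`, `n_perm`, `tail`.
#' @export
mantel_test <- function(a, b, n_perm = 10000L, seed = 1L,
                        tail = c("greater", "less")) {
  tail <- match.arg(tail)
  check_dist_matrix(a, zero_diag = FALSE, what = "a")
  check_dist_matrix(b, zero_diag = FALSE, what = "b")
  b <- align_labels(a, b, "a and b")
  n <- nrow(a)
  if (n < 4L) stop("need at least 4 labels", call. = FALSE)
  va <- upper_tri_values(a)
  if (stats::var(va) == 0 || stats::var(upper_tri_values(b)) == 0)
    stop("undefined correlation: zero-variance triangle", call. = FALSE)
  rho <- stats::cor(va, upper_tri_values(b))
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(va, upper_tri_values(b[p, p]))
    hit <- if (tail == "greater") rp >= rho else rp <= rho
    if (hit) count <- count + 1L
  }
  list(rho = rho, p_value = (1 + count) / (n_perm + 1),
       n_perm = as.integer(n_perm), tail = tail)
}

#' Slope-uncertainty equivalence test between two isolation-by-distance sets
#'
#' Asks whether a test set of populations follows the same
#' differentiation-with-distance relationship as a reference set. Per
#' replicate r: a slope `b*_r` is drawn from Normal(reference slope,
#' reference slope SE); the residual matrix `R_r = y_test - b*_r * d_test`
#' is formed (the intercept is omitted — Pearson statistics are invariant to
#' additive constants); `T_obs,r` is the Mantel correlation of `R_r` with
#' `d_test`, and `T_rand,r` its correlation with one fresh joint row/column
#' permutation of `d_test`. The p-value is
#' `(1 + #\{T_rand,r < T_obs,r\}) / (n_rep + 1)`: small p means the test
#' set's residuals are unusually *negatively* associated with distance,
#' i.e. its differentiation is depressed relative to the reference line.
#'
#' @param ref_fit an [ibd_regression()] fit providing the reference slope
#'   and its standard error.
#' @param y_test,d_test linearised genetic and stream-distance matrices for
#'   the set under test (matching label sets).
#' @param n_rep number of sampled slopes / randomisations (default 10000).
#' @param seed integer seed.
#' @return List of class `ibd_equivalence` with `p_value`, `b_star`,
#'   `T_obs`, `T_rand`, `n_rep`, `seed`.
#' @export
ibd_equivalence_test <- function(ref_fit, y_test, d_test,
                                 n_rep = 10000L, seed = 1L) {
  stopifnot(inherits(ref_fit, "ibd_fit"))
  if (ref_fit$se_slope < 0) stop("parameter error: negative slope SE", call. = FALSE)
  check_dist_matrix(y_test, what = "y_test")
  check_dist_matrix(d_test, what = "d_test")
  d_test <- align_labels(y_test, d_test, "y_test and d_test")
  n <- nrow(y_test)
  set.seed(seed)
  b_star <- stats::rnorm(n_rep, ref_fit$slope, ref_fit$se_slope)
  dd <- upper_tri_values(d_test)
  yy <- upper_tri_values(y_test)
  T_obs <- numeric(n_rep); T_rand <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    res <- yy - b_star[r] * dd
    T_obs[r] <- stats::cor(res, dd)
    p <- sample.int(n)
    R <- y_test - b_star[r] * d_test
    T_rand[r] <- stats::cor(upper_tri_values(R), upper_tri_values(d_test[p, p]))
  }
  p_val <- (1 + sum(T_rand < T_obs)) / (n_rep + 1)
  structure(list(p_value = p_val, b_star = b_star, T_obs = T_obs,
                 T_rand = T_rand, n_rep = as.integer(n_rep), seed = seed),
            class = "ibd_equivalence")
}
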