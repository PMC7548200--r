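# Baseline construction, likelihood, leave-one-out self-assignment,
# EM mixture estimation, allocate-sum summaries.

three_stock_world <- function(seed, Fdrift = 0.025, L = 150L, n_base = 100L) {
  set.seed(seed)
  anc <- runif(L, .2, .8)
  k <- (1 - Fdrift) / Fdrift
  fs <- t(sapply(1:3, function(i) rbeta(L, anc * k, (1 - anc) * k)))
  rownames(fs) <- c("S1", "S2", "S3")
  colnames(fs) <- sprintf("loc%03d", seq_len(L))
  base <- gm_bind(gm_from_freqs(fs["S1", ], n_base, "S1"),
                  gm_from_freqs(fs["S2", ], n_base, "S2"),
                  gm_from_freqs(fs["S3", ], n_base, "S3"))
  list(freqs = fs, baseline_g = base,
       stock_map = c(S1 = "S1", S2 = "S2", S3 = "S3"))
}

draw_mixture <- function(fs, pi_true, n) {
  origins <- sample(rownames(fs), n, TRUE, pi_true)
  calls <- t(vapply(origins, function(s) rbinom(ncol(fs), 2L, fs[s, ]),
                    integer(ncol(fs))))
  colnames(calls) <- colnames(fs)
  rownames(calls) <- sprintf("m%04d", seq_len(n))
  list(g = gm_from_calls(calls, "mixture", 2020L), origins = origins)
}

test_that("baseline pseudocount arithmetic and invariances", {
  calls <- matrix(2L, 10, 1, dimnames = list(NULL, "l1"))
  g <- gm_from_calls(calls, "A")
  b <- fit_baseline(g, c(A = "A"), pseudocount = 0.5)
  expect_equal(unname(b$freqs[1, 1]), 20.5 / 21)
  # pseudocount 0 gives boundary frequency, flagged downstream
  b0 <- fit_baseline(g, c(A = "A"), pseudocount = 0)
  expect_equal(unname(b0$freqs[1, 1]), 1)
  expect_error(genotype_log_likelihood(0L, b0$freqs[1, ]), "numeric guard")
  # counts invariant to individual order
  g2 <- gm_from_calls(calls[sample(10), , drop = FALSE], "A")
  expect_identical(fit_baseline(g2, c(A = "A"))$counts, b$counts)
  expect_error(fit_baseline(g, c(B = "B")), "without a stock")
})

test_that("genotype log-likelihood closed forms and product oracle", {
  expect_equal(genotype_log_likelihood(1L, 0.5), log(0.5))
  expect_equal(genotype_log_likelihood(rep(NA_integer_, 5), runif(5, .1, .9)), 0)
  set.seed(12)
  for (i in 1:20) {
    p <- runif(5, 0.05, 0.95)
    calls <- sample(c(0:2, NA), 5, TRUE)
    probs <- c(function(q) (1 - q)^2, function(q) 2 * q * (1 - q),
               function(q) q^2)
    manual <- 0
    for (l in 1:5) if (!is.na(calls[l]))
      manual <- manual + log(probs[[calls[l] + 1]](p[l]))
    expect_equal(genotype_log_likelihood(calls, p), manual, tolerance = 1e-12)
  }
})

test_that("self-assignment is perfect with disjoint support", {
  g <- gm_bind(gm_from_calls(matrix(0L, 20, 20), "A"),
               gm_from_calls(matrix(2L, 20, 20), "B"))
  res <- self_assign_loo(g, c(A = "A", B = "B"))
  expect_equal(attr(res, "accuracy"), 1)
})

test_that("self-assignment of a panmictic split is at chance level", {
  set.seed(41)
  p <- runif(100, .2, .8)
  g <- gm_bind(gm_from_freqs(p, 100, "A"), gm_from_freqs(p, 100, "B"))
  res <- self_assign_loo(g, c(A = "A", B = "B"))
  acc <- attr(res, "accuracy")
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("leave-one-out equals a from-scratch baseline rebuild", {
  w <- three_stock_world(7, L = 30L, n_base = 15L)
  g <- w$baseline_g
  g$calls[runif(length(g$calls)) < 0.05] <- NA_integer_
  res <- self_assign_loo(g, w$stock_map)
  set.seed(8)
  for (i in sample(nrow(g$calls), 10)) {
    rest <- gm_subset(g, setdiff(seq_len(nrow(g$calls)), i))
    b <- fit_baseline(rest, w$stock_map)
    ll <- vapply(seq_along(b$stocks), function(s)
      genotype_log_likelihood(g$calls[i, ], b$freqs[s, ]), 0)
    post <- exp(ll - max(ll)); post <- post / sum(post)
    expect_equal(unname(unlist(res[i, b$stocks])), unname(post),
                 tolerance = 1e-10)
  }
})

test_that("EM handles the degenerate and symmetric fixed points", {
  # disjoint support, pure-A mixture
  base <- gm_bind(gm_from_calls(matrix(0L, 10, 25), "A"),
                  gm_from_calls(matrix(2L, 10, 25), "B"))
  bl <- fit_baseline(base, c(A = "A", B = "B"), pseudocount = 0.5)
  mix <- gm_from_calls(matrix(0L, 50, 25, dimnames = list(NULL, colnames(base$calls))), "m")
  est <- em_mixture(mix, bl)
  expect_gte(unname(est$pi["A"]), 0.999)
  expect_true(all(diff(est$loglik_trace) >= -1e-8))
  # two identical stocks: uniform init is a fixed point
  base2 <- gm_bind(gm_from_calls(matrix(1L, 10, 25), "A"),
                   gm_from_calls(matrix(1L, 10, 25), "B"))
  bl2 <- fit_baseline(base2, c(A = "A", B = "B"))
  mix2 <- gm_from_calls(matrix(1L, 30, 25, dimnames = list(NULL, colnames(base2$calls))), "m")
  est2 <- em_mixture(mix2, bl2, init = c(0.5, 0.5))
  expect_equal(unname(est2$pi), c(0.5, 0.5), tolerance = 1e-12)
  expect_true(est2$converged)
})

test_that("EM recovers mixture proportions within sampling error", {
  w <- three_stock_world(19)
  bl <- fit_baseline(w$baseline_g, w$stock_map)
  mx <- draw_mixture(w$freqs, c(0.6, 0.3, 0.1), 500)
  est <- em_mixture(mx$g, bl)
  se <- sqrt(c(.6, .3, .1) * c(.4, .7, .9) / 500)
  expect_true(all(abs(est$pi - c(0.6, 0.3, 0.1)) < 3 * se))
  # allocate-sum self-consistency at the fixed point
  expect_equal(unname(colMeans(est$responsibilities)), unname(est$pi),
               tolerance = 1e-6)
})

test_that("posteriors are invariant to locus order and allele swaps", {
  w <- three_stock_world(23, L = 40L, n_base = 30L)
  bl <- fit_baseline(w$baseline_g, w$stock_map)
  mx <- draw_mixture(w$freqs, c(1 / 3, 1 / 3, 1 / 3), 20)
  est <- em_mixture(mx$g, bl)
  s1 <- assign_and_summarize(mx$g, bl, est, true_stock = mx$origins)
  # locus permutation applied consistently to mixture and baseline
  perm <- sample(ncol(mx$g$calls))
  g2 <- gm_subset(mx$g, loci = perm)
  base2 <- gm_subset(w$baseline_g, loci = perm)
  bl2 <- fit_baseline(base2, w$stock_map)
  est2 <- em_mixture(g2, bl2)
  s2 <- assign_and_summarize(g2, bl2, est2, true_stock = mx$origins)
  expect_equal(s1$assignments$max_posterior, s2$assignments$max_posterior,
               tolerance = 1e-9)
  # allele swap
  g3 <- mx$g; g3$calls <- 2L - g3$calls
  base3 <- w$baseline_g; base3$calls <- 2L - base3$calls
  bl3 <- fit_baseline(base3, w$stock_map)
  est3 <- em_mixture(g3, bl3)
  s3 <- assign_and_summarize(g3, bl3, est3, true_stock = mx$origins)
  expect_equal(s1$assignments$max_posterior, s3$assignments$max_posterior,
               tolerance = 1e-9)
})

test_that("assignment summaries satisfy their axioms", {
  base <- gm_bind(gm_from_calls(matrix(0L, 10, 20), "A"),
                  gm_from_calls(matrix(2L, 10, 20), "B"))
  bl <- fit_baseline(base, c(A = "A", B = "B"))
  loci <- colnames(base$calls)
  mix <- gm_bind(
    gm_from_calls(matrix(0L, 25, 20, dimnames = list(NULL, loci)), "mA"),
    gm_from_calls(matrix(2L, 25, 20, dimnames = list(NULL, loci)), "mB"))
  est <- em_mixture(mix, bl)
  truth <- rep(c("A", "B"), each = 25)
  s <- assign_and_summarize(mix, bl, est, true_stock = truth)
  expect_equal(unname(s$accuracy_matrix), diag(2), tolerance = 1e-9)
  expect_equal(rowSums(s$accuracy_matrix), c(A = 1, B = 1), tolerance = 1e-12)
  # CDF axioms
  expect_true(all(s$cdf[, 1] == 1))
  expect_true(all(apply(s$cdf, 1, function(r) all(diff(r) <= 1e-12))))
  # unknown origin excluded with a note
  s2 <- assign_and_summarize(mix, bl, est,
                             true_stock = c("???", truth[-1]))
  expect_identical(s2$excluded_origins, "???")
})
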