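# Call-rate filter, exact HWE test, locus filter rule, permutation
# differentiation test, homogenisation.

test_that("bonferroni_alpha arithmetic and guards", {
  expect_equal(signif(bonferroni_alpha(0.05, 115), 3), 4.35e-4)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0), "parameter error")
})

test_that("call-rate filter applies the threshold boundary exactly", {
  calls <- matrix(1L, 3, 176)
  calls[2, 1:18] <- NA_integer_   # 158/176 = 0.898 -> removed at 0.9
  calls[3, ] <- NA_integer_
  g <- gm_from_calls(calls, "A")
  out <- filter_call_rate(g, 0.9)
  expect_identical(nrow(out$calls), 1L)
  expect_length(attr(out, "removed"), 2L)
  # idempotent
  out2 <- filter_call_rate(out, 0.9)
  expect_identical(out2$calls, out$calls)
  expect_warning(filter_call_rate(gm_from_calls(
    matrix(NA_integer_, 2, 5), "A"), 0.5), "every individual")
})

test_that("exact HWE test matches the enumeration oracle", {
  # frozen case (3,5,2): brute-force enumeration over het counts {1,3,5,7,9}
  expect_equal(hwe_exact_test(3, 5, 2)$p_value, hwe_oracle(3, 5, 2),
               tolerance = 1e-12)
  # random cases
  set.seed(77)
  for (i in 1:50) {
    cnt <- as.vector(rmultinom(1, sample(5:60, 1), runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3])$p_value,
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("exact HWE test handles perfect equilibrium, fixation, monomorphy", {
  r <- hwe_exact_test(25, 50, 25)
  expect_equal(r$f_hat, 0)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  r2 <- hwe_exact_test(50, 0, 50)
  expect_equal(r2$f_hat, 1)
  expect_lt(r2$p_value, 1e-6)
  r3 <- hwe_exact_test(30, 0, 0)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$f_hat, 0)
})

test_that("HWE locus filter removes deficits in more than half the units", {
  cfg <- qc_config(n_tests = 115)
  mk <- function(locus, year, n_pop, n_fail, f = 1) {
    data.frame(locus = locus, population = paste0("P", 1:n_pop), year = year,
               p_value = c(rep(1e-9, n_fail), rep(0.5, n_pop - n_fail)),
               f_hat = f)
  }
  expect_identical(filter_hwe_loci(mk("lA", 2010, 10, 6), cfg), "lA")
  expect_identical(filter_hwe_loci(mk("lB", 2010, 10, 5), cfg), character())
  # heterozygote excess never removes
  expect_identical(filter_hwe_loci(mk("lC", 2010, 10, 8, f = -1), cfg),
                   character())
  # failing spread over two years, never a majority within one year
  two <- rbind(mk("lD", 2010, 10, 4), mk("lD", 2011, 10, 4))
  expect_identical(filter_hwe_loci(two, cfg), character())
})

test_that("permutation differentiation test detects fixed differences", {
  g1 <- gm_from_calls(matrix(0L, 15, 20), "A")
  g2 <- gm_from_calls(matrix(2L, 15, 20), "B")
  g <- gm_bind(g1, g2)
  res <- permutation_differentiation_test(g, g$labels$population,
                                          n_perm = 499, seed = 1)
  expect_equal(res$theta_obs, 1)
  expect_lte(res$p_value, 5 / 500)
  expect_error(permutation_differentiation_test(g, rep("A", 30)), "grouping")
})

test_that("permutation test is invariant to group-label renaming", {
  # label symmetry: the statistic and p-value depend on the partition, not
  # on the group names
  g <- gm_from_freqs(runif(30, .2, .8), 40, seed = 5)
  grp <- rep(c("x", "y"), 20)
  p1 <- permutation_differentiation_test(g, grp, n_perm = 199, seed = 7)
  grp2 <- ifelse(grp == "x", "y", "x")
  p2 <- permutation_differentiation_test(g, grp2, n_perm = 199, seed = 7)
  expect_identical(p1, p2)
})

test_that("homogenisation keeps homogeneous data identical and drops small pops", {
  set.seed(31)
  p <- runif(40, .2, .8)
  big <- gm_bind(gm_from_freqs(p, 30, "A", 2010L), gm_from_freqs(p, 30, "A", 2011L))
  small <- gm_from_freqs(p, 19, "B", 2010L)
  g <- gm_bind(big, small)
  cfg <- qc_config(n_perm = 199)
  out <- homogenize_collections(g, cfg, seed = 3)
  expect_identical(sort(unique(out$genotypes$labels$population)), "A")
  expect_identical(out$genotypes$calls, gm_subset(g, g$labels$population == "A")$calls)
  expect_false(out$collections$A$differentiated)
  expect_true(any(grepl("minimum collection size", out$dropped$reason)))
})

test_that("homogenisation removes a year cohort drawn from different frequencies", {
  set.seed(32)
  p <- runif(60, .2, .8)
  p_odd <- pmin(pmax(p + sample(c(-1, 1), 60, TRUE) * 0.35, 0.02), 0.98)
  g <- gm_bind(gm_from_freqs(p, 40, "A", 2010L),
               gm_from_freqs(p, 40, "A", 2011L),
               gm_from_freqs(p_odd, 40, "A", 2013L))
  cfg <- qc_config(n_perm = 2499)  # p-value floor 4e-4 < adjusted alpha
  out <- homogenize_collections(g, cfg, seed = 4)
  kept_years <- sort(unique(out$genotypes$labels$year))
  expect_identical(kept_years, c(2010L, 2011L))
  expect_false(out$collections$A$differentiated)
  expect_true(any(out$dropped$reason == "year 2013 differentiated"))
  # log records every test with its alpha
  expect_true(all(out$log$alpha == cfg$adjusted_alpha))
  expect_gte(nrow(out$log), 2L)
})

test_that("two mutually differentiated years are kept as separate classes", {
  set.seed(33)
  p <- runif(60, .3, .7)
  p2 <- pmin(pmax(p + sample(c(-1, 1), 60, TRUE) * 0.3, 0.02), 0.98)
  g <- gm_bind(gm_from_freqs(p, 40, "A", 2010L),
               gm_from_freqs(p2, 40, "A", 2011L))
  out <- homogenize_collections(g, qc_config(n_perm = 2499), seed = 5)
  expect_true(out$collections$A$differentiated)
  expect_identical(sort(unique(out$genotypes$labels$year)), c(2010L, 2011L))
})
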