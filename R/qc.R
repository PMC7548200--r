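# Sample/locus quality control and homogenisation of collections.
#
# Filter order is fixed and logged: call-rate filter on individuals, exact
# Hardy-Weinberg locus filter (heterozygote-deficit direction only), then
# homogenisation of collections across spawn years and detection sites via
# permutation tests of multilocus theta at a Bonferroni-adjusted alpha.

#' QC configuration
#'
#' @param call_rate_min minimum fraction of successfully genotyped loci per
#'   individual (default 0.90).
#' @param min_collection_size minimum collection size; populations below it
#'   are dropped, and only units strictly larger than it are tested
#'   (default 20).
#' @param n_perm permutations per differentiation test (default 10000).
#' @param family_alpha family-wise significance level (default 0.05).
#' @param n_tests planned simultaneous differentiation tests for the
#'   Bonferroni family (default 115). Taken from configuration — the planned,
#'   not the realised, test count.
#' @return List of class `qc_config`; `adjusted_alpha = family_alpha/n_tests`.
#' @export
qc_config <- function(call_rate_min = 0.90, min_collection_size = 20L,
                      n_perm = 10000L, family_alpha = 0.05, n_tests = 115L) {
  structure(list(call_rate_min = call_rate_min,
                 min_collection_size = as.integer(min_collection_size),
                 n_perm = as.integer(n_perm),
                 family_alpha = family_alpha,
                 n_tests = as.integer(n_tests),
                 adjusted_alpha = bonferroni_alpha(family_alpha, n_tests)),
            class = "qc_config")
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0,1).
#' @param n_tests number of planned simultaneous tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("parameter error: n_tests must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("parameter error: alpha must be in (0,1)", call. = FALSE)
  alpha / n_tests
}

#' Filter individuals by genotyping call rate
#'
#' Retains individuals whose non-missing fraction is at least `threshold`.
#'
#' @param g a [genotype_matrix()].
#' @param threshold minimum call rate in (0, 1].
#' @return Filtered `genotype_matrix`; attribute `removed` holds the ids of
#'   removed individuals. Emits a warning (not an error) if nothing remains.
#' @export
filter_call_rate <- function(g, threshold = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0,1]", call. = FALSE)
  cr <- rowMeans(!is.na(g$calls))
  keep <- cr >= threshold
  if (!any(keep)) warning("call-rate filter removed every individual", call. = FALSE)
  out <- gm_subset(g, keep)
  attr(out, "removed") <- rownames(g$calls)[!keep]
  out
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Exact conditional test: given the observed allele counts, all heterozygote
#' counts of matching parity are enumerated and the two-sided p-value is the
#' summed probability of outcomes no more probable than the observed one.
#' The inbreeding-style statistic `f_hat = 1 - H_obs/H_exp` is reported so
#' that the heterozygote-deficit direction (`f_hat > 0`) can be filtered on.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return List with `p_value` and `f_hat`. A monomorphic sample returns
#'   `p_value = 1`, `f_hat = 0`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total count must be >= 1", call. = FALSE)
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(list(p_value = 1, f_hat = 0))
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_het | nA, na) up to a common constant:
  #   P ∝ 2^het / (het! * ((nA-het)/2)! * ((na-het)/2)!)
  lp <- hets * log(2) - lfactorial(hets) -
    lfactorial((nA - hets) / 2) - lfactorial((na - hets) / 2)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  p <- sum(pr[pr <= p_obs * (1 + 1e-12)])
  pA <- nA / (2 * n)
  h_exp <- 2 * pA * (1 - pA)
  f_hat <- 1 - (n_Aa / n) / h_exp
  list(p_value = min(p, 1), f_hat = f_hat)
}

#' Hardy-Weinberg scan over testable population x year units
#'
#' Runs [hwe_exact_test()] at every locus for each population x spawn-year
#' unit holding strictly more than `min_collection_size` individuals.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return Data frame with columns `locus`, `population`, `year`,
#'   `p_value`, `f_hat`.
#' @export
hwe_scan <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  lab <- g$labels
  units <- unique(lab[c("population", "year")])
  res <- list()
  for (u in seq_len(nrow(units))) {
    idx <- lab$population == units$population[u] & lab$year == units$year[u]
    if (sum(idx) <= cfg$min_collection_size) next
    sub <- g$calls[idx, , drop = FALSE]
    for (l in seq_len(ncol(sub))) {
      x <- sub[, l]
      t2 <- sum(x == 2L, na.rm = TRUE)
      t1 <- sum(x == 1L, na.rm = TRUE)
      t0 <- sum(x == 0L, na.rm = TRUE)
      if (t0 + t1 + t2 == 0L) next
      hw <- hwe_exact_test(t2, t1, t0)
      res[[length(res) + 1L]] <- data.frame(
        locus = colnames(sub)[l], population = units$population[u],
        year = units$year[u], p_value = hw$p_value, f_hat = hw$f_hat,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(locus = character(), population = character(),
                      year = integer(), p_value = numeric(), f_hat = numeric()))
  do.call(rbind, res)
}

#' Loci to remove for Hardy-Weinberg heterozygote deficit
#'
#' A locus is removed when, within any single spawn year, it is out of
#' equilibrium in the deficit direction (`p_value < adjusted_alpha` and
#' `f_hat > 0`) in strictly more than half of the population units tested
#' that year. Heterozygote excess never removes a locus.
#'
#' @param results data frame from [hwe_scan()].
#' @param cfg a [qc_config()].
#' @return Character vector of locus ids to drop.
#' @export
filter_hwe_loci <- function(results, cfg = qc_config()) {
  if (!nrow(results)) return(character())
  drop <- character()
  for (l in unique(results$locus)) {
    rl <- results[results$locus == l, , drop = FALSE]
    for (y in unique(rl$year)) {
      ry <- rl[rl$year == y, , drop = FALSE]
      n_units <- nrow(ry)
      n_fail <- sum(ry$p_value < cfg$adjusted_alpha & ry$f_hat > 0)
      if (n_fail > n_units / 2) { drop <- c(drop, l); break }
    }
  }
  drop
}

#' Permutation test of genetic differentiation between labelled groups
#'
#' The statistic is the overall multilocus Weir-Cockerham theta across the
#' groups; the null is built by permuting individuals' group labels. Ties
#' are counted as at-least-as-extreme and the p-value uses the
#' never-zero convention `(1 + #\{theta_perm >= theta_obs\})/(n_perm + 1)`.
#'
#' @param g a [genotype_matrix()].
#' @param grouping vector of group labels, one per individual (>= 2 groups,
#'   none empty).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `p_value`, `theta_obs`, `n_perm`.
#' @export
permutation_differentiation_test <- function(g, grouping, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  grouping <- as.factor(grouping)
  if (length(grouping) != nrow(g$calls))
    stop("grouping error: one label per individual required", call. = FALSE)
  if (nlevels(grouping) < 2L || any(table(grouping) == 0L))
    stop("grouping error: need >= 2 non-empty groups", call. = FALSE)
  calls <- g$calls
  th_obs <- theta_multilocus(calls, grouping)
  if (is.na(th_obs)) stop("undefined result: no informative loci", call. = FALSE)
  set.seed(seed)
  n <- length(grouping)
  count <- 0L
  for (b in seq_len(n_perm)) {
    th_p <- theta_multilocus(calls, grouping[sample.int(n)])
    if (!is.na(th_p) && th_p >= th_obs) count <- count + 1L
  }
  list(p_value = (1 + count) / (n_perm + 1), theta_obs = th_obs,
       n_perm = as.integer(n_perm))
}

#' Homogenise collections across spawn years and detection sites
#'
#' For every population holding strictly more than `min_collection_size`
#' individuals: test differentiation across spawn years at the Bonferroni
#' adjusted alpha. If significant, first test across detection sites within
#' each year large enough to test (site subsets must also exceed the minimum
#' size) and iteratively remove sites significantly differentiated from the
#' rest of their year; then, if the years remain differentiated, iteratively
#' remove the most differentiated year (largest theta against the remaining
#' years, provided its one-vs-rest test is significant). A population whose
#' remaining years still differ but cannot be resolved by removal (e.g. two
#' mutually differentiated years) is kept with its years flagged as separate
#' classes for downstream per-year-class averaging of pairwise theta.
#' Populations that end below `min_collection_size` are dropped.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @param seed integer seed; every permutation test draws a deterministic
#'   per-test seed from it.
#' @return List with `genotypes` (retained [genotype_matrix()]), `log`
#'   (data frame recording every test, its p-value and the alpha used),
#'   `collections` (per-population retained years and a `differentiated`
#'   flag), and `dropped` (populations removed, with reasons).
#' @export
homogenize_collections <- function(g, cfg = qc_config(), seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  lab <- g$labels
  alpha <- cfg$adjusted_alpha
  log_rows <- list()
  dropped <- list()
  keep <- rep(TRUE, nrow(lab))
  collections <- list()
  test_counter <- 0L
  run_test <- function(idx, grouping, scope, population, unit) {
    test_counter <<- test_counter + 1L
    res <- permutation_differentiation_test(
      gm_subset(g, idx), grouping, n_perm = cfg$n_perm,
      seed = stage_seed(seed, test_counter))
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      population = population, scope = scope, unit = unit,
      theta = res$theta_obs, p_value = res$p_value, alpha = alpha,
      n_perm = res$n_perm, significant = res$p_value < alpha,
      stringsAsFactors = FALSE)
    res
  }

  for (p in unique(lab$population)) {
    pidx <- which(lab$population == p & keep)
    if (length(pidx) < cfg$min_collection_size) {
      keep[pidx] <- FALSE
      dropped[[length(dropped) + 1L]] <- data.frame(
        population = p, reason = "below minimum collection size",
        stringsAsFactors = FALSE)
      next
    }
    differentiated <- FALSE
    if (length(pidx) > cfg$min_collection_size &&
        length(unique(lab$year[pidx])) >= 2L) {
      res <- run_test(pidx, lab$year[pidx], "years", p, "all years")
      if (res$p_value < alpha) {
        # localise at site level within testable years
        for (y in sort(unique(lab$year[pidx]))) {
          yidx <- which(lab$population == p & lab$year == y & keep)
          if (length(yidx) <= cfg$min_collection_size) next
          sites <- table(lab$site[yidx])
          big <- names(sites)[sites > cfg$min_collection_size]
          if (length(big) < 2L) next
          sidx <- yidx[lab$site[yidx] %in% big]
          res_s <- run_test(sidx, lab$site[sidx], "sites",
                            p, paste0("year ", y))
          while (res_s$p_value < alpha) {
            # remove the site most differentiated from the rest of its year
            cand <- unique(lab$site[sidx])
            if (length(cand) < 2L) break
            th_site <- vapply(cand, function(sx) {
              f <- ifelse(lab$site[sidx] == sx, "this", "rest")
              theta_multilocus(g$calls[sidx, , drop = FALSE], f)
            }, 0)
            worst <- cand[which.max(th_site)]
            res_lo <- run_test(sidx, ifelse(lab$site[sidx] == worst, "this", "rest"),
                               "site-vs-rest", p, paste0(worst, " in ", y))
            if (res_lo$p_value >= alpha) break
            rm_idx <- sidx[lab$site[sidx] == worst]
            keep[rm_idx] <- FALSE
            dropped[[length(dropped) + 1L]] <- data.frame(
              population = p,
              reason = paste0("site ", worst, " in year ", y, " differentiated"),
              stringsAsFactors = FALSE)
            sidx <- setdiff(sidx, rm_idx)
            if (length(unique(lab$site[sidx])) < 2L) break
            res_s <- run_test(sidx, lab$site[sidx], "sites",
                              p, paste0("year ", y, " (after removal)"))
          }
        }
        # re-test across years after any site removals; localise at year level
        repeat {
          pidx <- which(lab$population == p & keep)
          yrs <- sort(unique(lab$year[pidx]))
          if (length(yrs) < 2L) break
          res_y <- run_test(pidx, lab$year[pidx], "years", p, "retest")
          if (res_y$p_value >= alpha) break
          th_year <- vapply(yrs, function(yy) {
            f <- ifelse(lab$year[pidx] == yy, "this", "rest")
            theta_multilocus(g$calls[pidx, , drop = FALSE], f)
          }, 0)
          worst <- yrs[which.max(th_year)]
          res_lo <- run_test(pidx, ifelse(lab$year[pidx] == worst, "this", "rest"),
                             "year-vs-rest", p, as.character(worst))
          if (res_lo$p_value >= alpha || length(yrs) == 2L) {
            # cannot (or should not) resolve by removal: keep separate classes
            differentiated <- TRUE
            break
          }
          rm_idx <- pidx[lab$year[pidx] == worst]
          keep[rm_idx] <- FALSE
          dropped[[length(dropped) + 1L]] <- data.frame(
            population = p,
            reason = paste0("year ", worst, " differentiated"),
            stringsAsFactors = FALSE)
        }
      }
    }
    pidx <- which(lab$population == p & keep)
    if (length(pidx) < cfg$min_collection_size) {
      keep[pidx] <- FALSE
      dropped[[length(dropped) + 1L]] <- data.frame(
        population = p, reason = "below minimum collection size after removals",
        stringsAsFactors = FALSE)
      next
    }
    collections[[p]] <- list(years = sort(unique(lab$year[pidx])),
                             differentiated = differentiated)
  }

  list(genotypes = gm_subset(g, keep),
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(population = character(), scope = character(),
                    unit = character(), theta = numeric(), p_value = numeric(),
                    alpha = numeric(), n_perm = integer(), significant = logical()),
       collections = collections,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(population = character(), reason = character()))
}

#' Run the full QC chain
#'
#' Fixed order: call-rate filter, Hardy-Weinberg locus filter, collection
#' homogenisation.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @param seed integer seed for permutation tests.
#' @return List with `genotypes`, `collections`, `removed_individuals`,
#'   `removed_loci`, `hwe` (scan results), `homogenize_log`, `dropped`.
#' @export
run_qc <- function(g, cfg = qc_config(), seed = 1L) {
  g1 <- filter_call_rate(g, cfg$call_rate_min)
  removed_ind <- attr(g1, "removed")
  hw <- hwe_scan(g1, cfg)
  bad_loci <- filter_hwe_loci(hw, cfg)
  g2 <- if (length(bad_loci)) gm_subset(g1, loci = setdiff(colnames(g1$calls), bad_loci)) else g1
  hom <- homogenize_collections(g2, cfg, seed = seed)
  list(genotypes = hom$genotypes,
       collections = hom$collections,
       removed_individuals = removed_ind,
       removed_loci = bad_loci,
       hwe = hw,
       homogenize_log = hom$log,
       dropped = hom$dropped)
}
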