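# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# -- tiny river networks ----------------------------------------------------

mainstem_net <- function() {
  build_river_network(
    data.frame(parent = c("root", "A"), child = c("A", "B"),
               rkm_child = c(100, 250)),
    c(popA = "A", popB = "B"))
}

fork_net <- function() {
  build_river_network(
    data.frame(parent = c("root", "J", "J"), child = c("J", "A", "B"),
               rkm_child = c(80, 100, 250)),
    c(popA = "A", popB = "B", popJ = "J"))
}

# -- quick genotype constructors --------------------------------------------

# genotype matrix with explicit calls and minimal labels
gm_from_calls <- function(calls, population, year = 2010L, site = "s1") {
  n <- nrow(calls)
  genotype_matrix(calls,
                  population = rep_len(population, n),
                  year = rep_len(year, n),
                  site = rep_len(site, n))
}

# n individuals drawn from frequency vector p (HWE), one population label
gm_from_freqs <- function(p, n, population = "A", year = 2010L, site = "s1",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- matrix(rbinom(n * length(p), 2L, rep(p, each = n)), n, length(p))
  colnames(calls) <- sprintf("loc%03d", seq_along(p))
  gm_from_calls(calls, population, year, site)
}

# stack several genotype matrices (same loci)
gm_bind <- function(...) {
  gs <- list(...)
  calls <- do.call(rbind, lapply(gs, function(g) g$calls))
  lab <- do.call(rbind, lapply(gs, function(g) g$labels))
  rownames(calls) <- make.unique(unlist(lapply(gs, function(g) rownames(g$calls))))
  genotype_matrix(calls, lab$population, lab$year, lab$site)
}

# -- independent Weir-Cockerham oracle (two populations, scalar loop) -------
# Textbook variance-components formulas coded independently of the package's
# vectorised implementation: explicit per-locus loop, r fixed at 2.
theta_oracle_2pop <- function(calls1, calls2) {
  stopifnot(ncol(calls1) == ncol(calls2))
  A <- 0; TOT <- 0
  for (l in seq_len(ncol(calls1))) {
    x1 <- calls1[, l]; x1 <- x1[!is.na(x1)]
    x2 <- calls2[, l]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 == 0 || n2 == 0) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))        # / (r - 1) with r = 2
    if (nc <= 0) next
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar   # / (r - 1)
    if (pbar * (1 - pbar) == 0 && s2 == 0 && hbar == 0) next
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; TOT <- TOT + a + b + cc
  }
  A / TOT
}

# -- independent HWE enumeration oracle (full multinomial normalisation) ----
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa; na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), 2)
  pr <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, 0)
  pobs <- pr[hs == nAa]
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

# -- simulation shortcut ----------------------------------------------------

sim_scenario <- function(seed, translocated = FALSE, n_loci = 176L,
                         n_per_collection = 50L, years = 2010L,
                         missing_rate = 0.03) {
  net <- example_river_network()
  p <- sim_params(n_loci = n_loci, n_per_collection = n_per_collection,
                  years = years, missing_rate = missing_rate, seed = seed)
  fr <- simulate_allele_frequencies(net, p, seed = stage_seed(seed, 1))
  ev <- NULL
  if (translocated) {
    ev <- translocation_event("P07", c("P16", "P17", "P18", "P19"))
    fr <- apply_translocation(fr, ev, seed = stage_seed(seed, 2))
  }
  g <- sample_genotypes(fr, p, seed = stage_seed(seed, 3))
  list(net = net, params = p, freqs = fr, genotypes = g, event = ev)
}
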