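# Multilocus Weir-Cockerham theta and Cavalli-Sforza-Edwards chord distance.

# Per-locus variance components a (among populations), b (among individuals
# within populations), c (within individuals) from the Weir & Cockerham
# (1984) moment estimator, computed from per-group sample sizes n, allele
# frequencies p and observed heterozygote frequencies h. At each locus only
# groups with at least one call enter; loci with fewer than two informed
# groups, mean sample size <= 1, or no variation are dropped.
#
# Returns a list of per-locus vectors a, b, c and the logical keep mask.
wc_components <- function(calls, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  obs <- !is.na(calls)
  calls0 <- calls; calls0[!obs] <- 0L
  n <- rowsum(obs + 0, groups)                    # groups x loci called counts
  s <- rowsum(calls0, groups)                     # reference-allele counts
  het <- rowsum((calls == 1L & obs) + 0, groups)  # heterozygote counts
  p <- s / (2 * n); p[n == 0] <- 0
  h <- het / n;     h[n == 0] <- 0
  valid <- n > 0
  r <- colSums(valid)
  sum_n <- colSums(n)
  nbar <- sum_n / r
  nc <- (sum_n - colSums(n^2) / sum_n) / pmax(r - 1, 1)
  pbar <- colSums(n * p) / sum_n
  hbar <- colSums(n * h) / sum_n
  s2 <- colSums(n * sweep(p, 2, pbar)^2 * valid) / (pmax(r - 1, 1) * nbar)
  keep <- r >= 2 & nbar > 1 & nc > 0 &
    !(pbar * (1 - pbar) == 0 & s2 == 0 & hbar == 0)
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, keep = keep)
}

# Multilocus theta as ratio of sums over retained loci; NA if none retained.
theta_multilocus <- function(calls, groups) {
  comp <- wc_components(calls, groups)
  k <- comp$keep
  if (!any(k)) return(NA_real_)
  sum(comp$a[k]) / sum(comp$a[k] + comp$b[k] + comp$c[k])
}

#' Multilocus Weir-Cockerham theta between two collections
#'
#' Per-locus variance components are combined as a ratio of sums
#' (sum of among-population components over sum of total components), the
#' standard multilocus aggregation. Negative per-locus components are
#' retained, so a multilocus estimate slightly below zero is possible and is
#' reported as computed. Loci monomorphic across both groups, or with calls
#' in fewer than two groups, are skipped.
#'
#' @param g a [genotype_matrix()].
#' @param groupA,groupB logical/integer/character selections of individuals.
#' @return Multilocus theta (scalar). Errors if no locus is informative.
#' @export
wc_theta <- function(g, groupA, groupB) {
  stopifnot(inherits(g, "genotype_matrix"))
  sel <- function(idx) {
    if (is.character(idx)) idx <- match(idx, rownames(g$calls))
    if (is.logical(idx)) idx <- which(idx)
    idx
  }
  ia <- sel(groupA); ib <- sel(groupB)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty", call. = FALSE)
  calls <- g$calls[c(ia, ib), , drop = FALSE]
  f <- rep(c("A", "B"), c(length(ia), length(ib)))
  th <- theta_multilocus(calls, f)
  if (is.na(th)) stop("undefined result: no informative loci", call. = FALSE)
  th
}

#' Pairwise multilocus theta matrix over homogenised collections
#'
#' For a population pair in which one or both members retained multiple,
#' mutually differentiated spawn-year classes (see
#' [homogenize_collections()]), theta is computed for every year-class
#' combination and arithmetically averaged into the single cell; otherwise
#' the populations' individuals are pooled.
#'
#' @param g a [genotype_matrix()] (typically QC output).
#' @param collections optional collection map as returned in
#'   `homogenize_collections()$collections`; when `NULL` every population is
#'   treated as homogeneous (pooled).
#' @return A list of class `pairwise_fst` with `theta` (symmetric labelled
#'   matrix, zero diagonal) and `per_year_components` (data frame logging
#'   every year-class theta averaged into a cell).
#' @export
pairwise_fst_matrix <- function(g, collections = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  lab <- g$labels
  pops <- unique(lab$population)
  if (is.null(collections))
    collections <- lapply(stats::setNames(pops, pops), function(p)
      list(years = unique(lab$year[lab$population == p]), differentiated = FALSE))
  pops <- intersect(pops, names(collections))
  units_of <- function(p) {
    info <- collections[[p]]
    if (isTRUE(info$differentiated) && length(info$years) > 1L)
      lapply(info$years, function(y) which(lab$population == p & lab$year == y))
    else
      list(which(lab$population == p))
  }
  unit_years <- function(p) {
    info <- collections[[p]]
    if (isTRUE(info$differentiated) && length(info$years) > 1L)
      as.character(info$years) else "pooled"
  }
  n <- length(pops)
  th <- matrix(0, n, n, dimnames = list(pops, pops))
  comp_log <- list()
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ua <- units_of(pops[i]); ub <- units_of(pops[j])
    ya <- unit_years(pops[i]); yb <- unit_years(pops[j])
    vals <- c()
    for (k in seq_along(ua)) for (l in seq_along(ub)) {
      v <- wc_theta(g, ua[[k]], ub[[l]])
      vals <- c(vals, v)
      comp_log[[length(comp_log) + 1L]] <- data.frame(
        pop_a = pops[i], pop_b = pops[j],
        year_a = ya[k], year_b = yb[l], theta = v,
        stringsAsFactors = FALSE)
    }
    th[i, j] <- th[j, i] <- mean(vals)
  }
  structure(list(theta = th,
                 per_year_components = do.call(rbind, comp_log)),
            class = "pairwise_fst")
}

#' Cavalli-Sforza-Edwards chord distance between two frequency vectors
#'
#' For biallelic loci with reference frequencies `fa`, `fb`, the per-locus
#' squared chord is `2 * (1 - (sqrt(fa*fb) + sqrt((1-fa)*(1-fb))))` and the
#' distance is the square root of its mean over loci. The classical `2/pi`
#' angular scaling is deliberately omitted: neighbor-joining topology and
#' bootstrap supports are invariant to monotone rescaling.
#'
#' @param fa,fb numeric vectors of per-locus reference-allele frequencies.
#' @return Chord distance D >= 0 (maximum `sqrt(2)` at opposite fixation).
#' @export
cse_chord_distance <- function(fa, fb) {
  if (!length(fa) || length(fa) != length(fb))
    stop("frequency vectors must be non-empty and of equal length", call. = FALSE)
  if (any(fa < 0 | fa > 1 | fb < 0 | fb > 1, na.rm = TRUE))
    stop("frequencies must lie in [0,1]", call. = FALSE)
  d2 <- 2 * (1 - (sqrt(fa * fb) + sqrt((1 - fa) * (1 - fb))))
  sqrt(mean(d2, na.rm = TRUE))
}

#' Pairwise chord-distance matrix from a frequency table
#'
#' @param freqs populations x loci frequency matrix.
#' @return Symmetric labelled matrix, zero diagonal.
#' @export
chord_distance_matrix <- function(freqs) {
  pops <- rownames(freqs)
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- cse_chord_distance(freqs[i, ], freqs[j, ])
  d
}

#' Observed allele frequencies per population from genotypes
#'
#' Plain observed proportions (zero pseudocount), the convention used for
#' chord distances; loci with no calls in a population yield `NA`.
#'
#' @param g a [genotype_matrix()].
#' @return Populations x loci matrix of reference-allele frequencies.
#' @export
freq_from_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- as.factor(g$labels$population)
  obs <- !is.na(g$calls)
  calls0 <- g$calls; calls0[!obs] <- 0L
  n2 <- 2 * rowsum(obs + 0, f)
  s <- rowsum(calls0, f)
  out <- s / n2
  out[n2 == 0] <- NA_real_
  out
}
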