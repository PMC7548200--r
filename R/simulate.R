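# Synthetic genotypes on a river network under distance-dependent drift.
#
# Allele frequencies evolve down the tree by hierarchical Balding-Nichols
# draws: along an edge of length L km the child frequency is Beta-distributed
# around the parent frequency with differentiation F_edge = 1 - exp(-L/tau).
# Compounding along a path of total length D gives expected pairwise
# differentiation ~ 1 - exp(-D/tau), approximately linear in D for small F —
# the regime in which the Rousset isolation-by-distance linearisation holds.
# Genotypes are then binomial draws (Hardy-Weinberg within populations).

#' Simulation parameters
#'
#' Defaults emulate a basin-scale SNP survey: 176 biallelic loci, ~20
#' populations on a dendritic network, 50 sampled adults per population and
#' spawn year over 8 return years, 3% missing genotypes, and a drift scale
#' giving pairwise theta of roughly 0.005-0.06 over the basin (expected pairwise theta ~ (1 - exp(-D/tau))/2, approximately D/(2 tau)).
#'
#' @param n_loci number of biallelic loci.
#' @param ancestral_freq_range interval within (0,1) for ancestral (root)
#'   reference-allele frequencies, drawn uniformly per locus.
#' @param tau_km drift scale in km: per-edge differentiation is
#'   `F_edge = 1 - exp(-edge_length/tau_km)`.
#' @param n_per_collection individuals sampled per population x spawn year.
#' @param missing_rate independent per-call missingness fraction in \[0, 1).
#' @param years vector of spawn years.
#' @param n_sites detection sites per population (labels `s1`, `s2`, ...).
#' @param seed integer master seed for the simulator.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_loci = 176L,
                       ancestral_freq_range = c(0.1, 0.9),
                       tau_km = 7500,
                       n_per_collection = 50L,
                       missing_rate = 0.03,
                       years = 2010:2017,
                       n_sites = 2L,
                       seed = 1L) {
  if (tau_km <= 0) stop("parameter error: tau_km must be > 0", call. = FALSE)
  if (length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] > ancestral_freq_range[2])
    stop("parameter error: ancestral_freq_range must lie within (0,1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("parameter error: missing_rate must be in [0,1)", call. = FALSE)
  if (n_per_collection < 1) stop("parameter error: n_per_collection < 1", call. = FALSE)
  structure(list(n_loci = as.integer(n_loci),
                 ancestral_freq_range = ancestral_freq_range,
                 tau_km = tau_km,
                 n_per_collection = as.integer(n_per_collection),
                 missing_rate = missing_rate,
                 years = as.integer(years),
                 n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Translocation event
#'
#' Emulates a historical stocking programme: each target population's
#' frequencies are replaced by a Balding-Nichols draw (parameter `F_t`,
#' the drift accrued since the event) around the admixed mean
#' `alpha_mix * p_source + (1 - alpha_mix) * p_target`.
#'
#' @param source source population name.
#' @param targets character vector of target population names.
#' @param alpha_mix fraction of target ancestry replaced by the source in
#'   \[0, 1\]. Default 1 (complete replacement), a modelling choice for a
#'   stated stocking history with no published admixture fraction.
#' @param F_t post-event drift in \[0, 1).
#' @return A list of class `translocation_event`.
#' @export
translocation_event <- function(source, targets, alpha_mix = 1, F_t = 0.01) {
  if (alpha_mix < 0 || alpha_mix > 1) stop("alpha_mix must be in [0,1]", call. = FALSE)
  if (F_t < 0 || F_t >= 1) stop("F_t must be in [0,1)", call. = FALSE)
  structure(list(source = source, targets = targets,
                 alpha_mix = alpha_mix, F_t = F_t),
            class = "translocation_event")
}

# Balding-Nichols draw: Beta with mean p, variance F*p*(1-p).
# p in {0,1} is absorbing; F -> 0 degenerates to the parent frequency.
rbalding_nichols <- function(p, F) {
  out <- p
  if (F <= 0) return(out)
  idx <- which(p > 0 & p < 1)
  if (length(idx)) {
    k <- (1 - F) / F
    out[idx] <- stats::rbeta(length(idx), p[idx] * k, (1 - p[idx]) * k)
  }
  out
}

#' Simulate per-population allele frequencies on a river network
#'
#' Ancestral frequencies are drawn at the root; each child node's frequency
#' is a Balding-Nichols draw around its parent's with per-edge
#' differentiation `1 - exp(-edge_length/tau_km)`. Populations inherit the
#' frequency at their placement node.
#'
#' @param net a [build_river_network()] object.
#' @param params a [sim_params()] object.
#' @param seed seed (default `params$seed`).
#' @return Matrix of reference-allele frequencies, populations x loci.
#' @export
simulate_allele_frequencies <- function(net, params, seed = params$seed) {
  stopifnot(inherits(net, "river_network"), inherits(params, "sim_params"))
  set.seed(seed)
  nodes <- net$nodes[order(net$nodes$rkm), , drop = FALSE]  # parents precede children
  L <- params$n_loci
  p0 <- stats::runif(L, params$ancestral_freq_range[1], params$ancestral_freq_range[2])
  freq <- matrix(NA_real_, nrow(nodes), L, dimnames = list(nodes$node, NULL))
  rk <- stats::setNames(nodes$rkm, nodes$node)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes$node[i]
    par <- nodes$parent[i]
    if (is.na(par)) {
      freq[nd, ] <- p0
    } else {
      len <- rk[[nd]] - rk[[par]]
      Fe <- 1 - exp(-len / params$tau_km)
      freq[nd, ] <- rbalding_nichols(freq[par, ], Fe)
    }
  }
  out <- freq[net$placements, , drop = FALSE]
  rownames(out) <- names(net$placements)
  colnames(out) <- sprintf("loc%04d", seq_len(L))
  out
}

#' Apply a translocation event to an allele-frequency table
#'
#' @param freqs populations x loci frequency matrix.
#' @param event a [translocation_event()].
#' @param seed integer seed for the post-event drift draws.
#' @return The modified frequency matrix; non-target rows untouched.
#' @export
apply_translocation <- function(freqs, event, seed = 1L) {
  stopifnot(inherits(event, "translocation_event"))
  pops <- rownames(freqs)
  miss <- setdiff(c(event$source, event$targets), pops)
  if (length(miss))
    stop("lookup error: unknown population(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  ps <- freqs[event$source, ]
  for (tg in event$targets) {
    mean_p <- event$alpha_mix * ps + (1 - event$alpha_mix) * freqs[tg, ]
    freqs[tg, ] <- rbalding_nichols(mean_p, event$F_t)
  }
  freqs
}

#' Sample diploid genotypes from population allele frequencies
#'
#' Each individual's dosage at each locus is Binomial(2, p) — Hardy-Weinberg
#' within populations by construction. Calls are masked missing
#' independently at `missing_rate`; individuals are labelled with their
#' population, a spawn year cycled through `params$years`, and a detection
#' site drawn uniformly from the population's sites.
#'
#' @param freqs populations x loci frequency matrix.
#' @param params a [sim_params()] object.
#' @param seed seed (default `params$seed + 1`, so frequency simulation and
#'   genotype sampling use distinct streams).
#' @param years spawn years to sample (default `params$years`).
#' @return A [genotype_matrix()] with
#'   `n_per_collection * length(years)` individuals per population.
#' @export
sample_genotypes <- function(freqs, params, seed = params$seed + 1L,
                             years = params$years) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_per_collection < 1) stop("parameter error: n_per_collection < 1", call. = FALSE)
  set.seed(seed)
  pops <- rownames(freqs)
  L <- ncol(freqs)
  npc <- params$n_per_collection
  n_total <- length(pops) * length(years) * npc
  calls <- matrix(NA_integer_, n_total, L)
  colnames(calls) <- colnames(freqs)
  pop_lab <- character(n_total); yr_lab <- integer(n_total); site_lab <- character(n_total)
  ids <- character(n_total)
  row <- 0L
  for (p in pops) {
    for (y in years) {
      idx <- row + seq_len(npc)
      calls[idx, ] <- matrix(stats::rbinom(npc * L, 2L, rep(freqs[p, ], each = npc)), npc, L)
      pop_lab[idx] <- p
      yr_lab[idx] <- y
      site_lab[idx] <- paste0("s", sample.int(params$n_sites, npc, replace = TRUE))
      ids[idx] <- sprintf("%s_%d_%03d", p, y, seq_len(npc))
      row <- row + npc
    }
  }
  if (params$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < params$missing_rate
    calls[mask] <- NA_integer_
  }
  rownames(calls) <- ids
  genotype_matrix(calls, pop_lab, yr_lab, site_lab)
}
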