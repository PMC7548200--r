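# Genetic stock identification: baseline construction, leave-one-out
# self-assignment, EM mixture estimation, and allocate-sum assignment
# summaries.
#
# The genotype likelihood is the product over non-missing loci of
# Hardy-Weinberg genotype probabilities p^2, 2pq, q^2 evaluated at the
# stock's pseudocount-adjusted baseline frequency.

#' Build a GSI baseline from reference genotypes
#'
#' Reference-allele counts are accumulated per stock over non-missing calls;
#' frequencies use a per-allele pseudocount:
#' `(count + pseudocount) / (total + 2 * pseudocount)`. The default 0.5
#' (Jeffreys-style) keeps every frequency strictly inside (0, 1) so mixture
#' individuals carrying alleles unseen in a stock keep a finite likelihood.
#'
#' @param g a [genotype_matrix()] of reference individuals.
#' @param stock_map named character vector population -> stock (reporting
#'   unit). Every baseline population must map to a stock.
#' @param pseudocount per-allele pseudocount weight (>= 0). Zero is allowed
#'   but frequencies of 0/1 will trip the likelihood guard downstream.
#' @return Object of class `gsi_baseline`: list with `stocks`, `loci`,
#'   `counts` (stocks x loci reference-allele counts), `totals` (called
#'   allele totals), `freqs`, `pseudocount`.
#' @export
fit_baseline <- function(g, stock_map, pseudocount = 0.5) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$labels$population)
  unmapped <- setdiff(pops, names(stock_map))
  if (length(unmapped))
    stop("population(s) without a stock: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  stock <- as.factor(unname(stock_map[g$labels$population]))
  if (any(table(stock) == 0L)) stop("stock with zero individuals", call. = FALSE)
  obs <- !is.na(g$calls)
  calls0 <- g$calls; calls0[!obs] <- 0L
  counts <- rowsum(calls0, stock)              # reference-allele counts
  totals <- 2 * rowsum(obs + 0, stock)         # called alleles
  freqs <- (counts + pseudocount) / (totals + 2 * pseudocount)
  structure(list(stocks = levels(stock), loci = colnames(g$calls),
                 counts = counts, totals = totals, freqs = freqs,
                 pseudocount = pseudocount),
            class = "gsi_baseline")
}

#' Log-likelihood of one individual's genotype under stock frequencies
#'
#' Sum over non-missing loci of `log P(call | p)` with
#' `P(2) = p^2`, `P(1) = 2 p (1-p)`, `P(0) = (1-p)^2`. Missing loci
#' contribute nothing; with every locus missing the log-likelihood is 0.
#'
#' @param calls integer vector of dosages (0/1/2/NA) aligned with `p`.
#' @param p vector of baseline reference-allele frequencies.
#' @return Scalar log-likelihood.
#' @export
genotype_log_likelihood <- function(calls, p) {
  if (length(calls) != length(p))
    stop("calls and frequencies must align", call. = FALSE)
  use <- !is.na(calls)
  if (!any(use)) return(0)
  pu <- p[use]
  if (any(pu <= 0 | pu >= 1))
    stop("numeric guard: baseline frequency outside (0,1) at a used locus",
         call. = FALSE)
  cu <- calls[use]
  sum(cu * log(pu) + (2 - cu) * log(1 - pu) + (cu == 1L) * log(2))
}

# Matrix of log-likelihoods, individuals x stocks, vectorised over loci.
loglik_matrix <- function(calls, baseline) {
  if (!identical(colnames(calls), baseline$loci))
    stop("loci of mixture and baseline must align", call. = FALSE)
  fr <- baseline$freqs
  if (any(fr <= 0 | fr >= 1))
    stop("numeric guard: baseline frequency outside (0,1)", call. = FALSE)
  obs <- !is.na(calls)
  c0 <- calls; c0[!obs] <- 0L
  het <- (calls == 1L & obs) + 0
  # per stock k: sum_l [ c*log p_k + (2-c)*log q_k + het*log 2 ] over observed
  lp <- t(log(fr)); lq <- t(log(1 - fr))      # loci x stocks
  ll <- c0 %*% lp + ((2 * obs) - c0) %*% lq + rowSums(het) * log(2)
  colnames(ll) <- baseline$stocks
  ll
}

posterior_from_loglik <- function(ll, log_prior = NULL) {
  if (!is.null(log_prior)) ll <- sweep(ll, 2L, log_prior, `+`)
  post <- exp(ll - row_logsumexp(ll))
  post / rowSums(post)
}

#' Leave-one-out self-assignment of baseline individuals
#'
#' For each baseline individual, its own allele copies at non-missing loci
#' are subtracted from its stock's counts, frequencies are recomputed with
#' the pseudocount, and the individual is assigned by maximum posterior
#' under equal stock priors. Equivalent to rebuilding the baseline without
#' the individual.
#'
#' @param g the baseline [genotype_matrix()].
#' @param stock_map named character vector population -> stock.
#' @param pseudocount per-allele pseudocount (default 0.5).
#' @return Data frame with `individual`, `true_stock`, `assigned`,
#'   `max_posterior`, plus one posterior column per stock; attribute
#'   `accuracy` holds the overall correct-assignment fraction.
#' @export
self_assign_loo <- function(g, stock_map, pseudocount = 0.5) {
  base <- fit_baseline(g, stock_map, pseudocount)
  true_stock <- unname(stock_map[g$labels$population])
  n <- nrow(g$calls); K <- length(base$stocks)
  post <- matrix(NA_real_, n, K, dimnames = list(rownames(g$calls), base$stocks))
  for (i in seq_len(n)) {
    calls <- g$calls[i, ]
    use <- !is.na(calls)
    counts <- base$counts; totals <- base$totals
    k <- true_stock[i]
    counts[k, use] <- counts[k, use] - calls[use]
    totals[k, use] <- totals[k, use] - 2
    if (any(counts[k, ] < 0) || any(totals[k, ] < 0))
      stop("accounting bug: negative count after leave-one-out subtraction",
           call. = FALSE)
    fr <- (counts + base$pseudocount) / (totals + 2 * base$pseudocount)
    ll <- vapply(seq_len(K), function(s) genotype_log_likelihood(calls, fr[s, ]), 0)
    post[i, ] <- exp(ll - max(ll)) / sum(exp(ll - max(ll)))
  }
  assigned <- base$stocks[max.col(post, ties.method = "first")]
  out <- data.frame(individual = rownames(g$calls), true_stock = true_stock,
                    assigned = assigned, max_posterior = apply(post, 1, max),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(post))
  rownames(out) <- NULL
  attr(out, "accuracy") <- mean(assigned == true_stock)
  out
}

#' EM estimation of stock mixture proportions
#'
#' Classic full-EM for a finite mixture with fixed component (stock)
#' likelihoods: E-step responsibilities `r_ik` proportional to
#' `pi_k * exp(loglik_ik)`; M-step `pi_k <- mean_i r_ik`. Iterates until the
#' largest change in any mixing proportion falls below `tol`. The observed
#' log-likelihood is recorded each iteration and asserted non-decreasing.
#'
#' @param mix a [genotype_matrix()] of mixture individuals.
#' @param baseline a [fit_baseline()] object.
#' @param tol convergence tolerance on `max |delta pi|` (default 1e-8).
#' @param max_iter iteration cap (default 5000).
#' @param init optional initial mixing proportions (default uniform).
#' @return Object of class `mixture_estimate`: list with `pi`,
#'   `responsibilities`, `loglik_trace`, `iterations`, `converged`.
#' @export
em_mixture <- function(mix, baseline, tol = 1e-8, max_iter = 5000L, init = NULL) {
  stopifnot(inherits(mix, "genotype_matrix"), inherits(baseline, "gsi_baseline"))
  ll <- loglik_matrix(mix$calls, baseline)
  if (any(!is.finite(row_logsumexp(ll)))) {
    bad <- rownames(mix$calls)[!is.finite(row_logsumexp(ll))][1L]
    stop("data error: individual ", bad,
         " has -Inf likelihood under every stock", call. = FALSE)
  }
  K <- ncol(ll)
  pi_k <- if (is.null(init)) rep(1 / K, K) else {
    if (length(init) != K || any(init < 0) || abs(sum(init) - 1) > 1e-8)
      stop("init must be a probability vector over the stocks", call. = FALSE)
    as.numeric(init)
  }
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    lw <- sweep(ll, 2L, log(pi_k), `+`)
    lse <- row_logsumexp(lw)
    obj <- sum(lse)
    if (length(trace) && obj < trace[length(trace)] - 1e-8)
      stop("EM log-likelihood decreased — internal error", call. = FALSE)
    trace <- c(trace, obj)
    r <- exp(lw - lse)
    pi_new <- colMeans(r)
    delta <- max(abs(pi_new - pi_k))
    pi_k <- pi_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  structure(list(pi = stats::setNames(pi_k, colnames(ll)),
                 responsibilities = r, loglik_trace = trace,
                 iterations = it, converged = converged),
            class = "mixture_estimate")
}

#' Allocate-sum assignment and accuracy/confidence summaries
#'
#' Posteriors use the estimated mixing proportions as priors (allocate-sum);
#' each individual is assigned wholly to its maximum-posterior stock. When
#' true origins are known, an accuracy matrix is produced (rows = true
#' origin stock, columns = assigned stock, rows summing to 1), along with a
#' per-assigned-stock cumulative confidence curve: the fraction of a stock's
#' assignees whose maximum posterior is at least x, on a grid of x.
#'
#' @param mix a [genotype_matrix()] of mixture individuals.
#' @param baseline a [fit_baseline()] object.
#' @param mixture_fit a [em_mixture()] result.
#' @param true_stock optional character vector of true origin stocks per
#'   mixture individual; unknown labels are excluded from the accuracy
#'   matrix (with a log attribute).
#' @param grid grid of posterior thresholds for the confidence curves.
#' @return List of class `assignment_summary` with `assignments` (data
#'   frame), `accuracy_matrix` (or `NULL`), `cdf` (stocks x grid matrix),
#'   `grid`.
#' @export
assign_and_summarize <- function(mix, baseline, mixture_fit,
                                 true_stock = NULL, grid = seq(0, 1, 0.01)) {
  stopifnot(inherits(mixture_fit, "mixture_estimate"))
  ll <- loglik_matrix(mix$calls, baseline)
  post <- posterior_from_loglik(ll, log_prior = log(pmax(mixture_fit$pi, 1e-300)))
  assigned <- baseline$stocks[max.col(post, ties.method = "first")]
  maxp <- apply(post, 1, max)
  assignments <- data.frame(individual = rownames(mix$calls),
                            assigned = assigned, max_posterior = maxp,
                            stringsAsFactors = FALSE)
  assignments <- cbind(assignments, as.data.frame(post))
  rownames(assignments) <- NULL

  acc <- NULL; excluded <- character()
  if (!is.null(true_stock)) {
    known <- true_stock %in% baseline$stocks
    excluded <- unique(true_stock[!known])
    tt <- true_stock[known]; aa <- assigned[known]
    acc <- matrix(0, length(baseline$stocks), length(baseline$stocks),
                  dimnames = list(baseline$stocks, baseline$stocks))
    tab <- table(factor(tt, baseline$stocks), factor(aa, baseline$stocks))
    rs <- rowSums(tab)
    acc[rs > 0, ] <- sweep(tab[rs > 0, , drop = FALSE], 1L, rs[rs > 0], `/`)
  }
  cdf <- t(vapply(baseline$stocks, function(s) {
    m <- maxp[assigned == s]
    if (!length(m)) return(rep(NA_real_, length(grid)))
    vapply(grid, function(x) mean(m >= x), 0)
  }, numeric(length(grid))))
  colnames(cdf) <- signif(grid, 3)
  structure(list(assignments = assignments, accuracy_matrix = acc,
                 cdf = cdf, grid = grid, excluded_origins = excluded),
            class = "assignment_summary")
}
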