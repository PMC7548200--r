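# End-to-end scenario pipeline: simulate -> qc -> fst -> gsi -> ibd -> tree.
#
# The pipeline exists because the scientific conclusions are contrasts
# between population sets (all vs excluding translocated vs relocated), not
# single fits; a scenario bundles everything needed to run that contrast
# reproducibly. Stage seeds derive from the master seed via stage_seed().

#' Default population -> stock map for the example basin
#'
#' Aggregates the 20 example populations pairwise into 10 reporting units
#' `RU01`..`RU10`, mirroring the usual population -> stock aggregation of
#' basin-scale GSI baselines.
#' @param populations population names (default the example basin's).
#' @return Named character vector population -> stock.
#' @export
default_stock_map <- function(populations = names(example_river_network()$placements)) {
  k <- ceiling(seq_along(populations) / 2)
  stats::setNames(sprintf("RU%02d", k), populations)
}

#' Assemble a scenario configuration
#'
#' @param sim a [sim_params()].
#' @param network a [build_river_network()] object (default
#'   [example_river_network()]).
#' @param translocation optional [translocation_event()].
#' @param qc a [qc_config()].
#' @param stock_map population -> stock map (default [default_stock_map()]).
#' @param pseudocount baseline pseudocount.
#' @param n_baseline_per_collection reference individuals per population
#'   used to build the GSI baseline (drawn as a separate, earlier-era
#'   sample from the same frequencies).
#' @param ibd_exclude populations excluded to form the reference
#'   isolation-by-distance set (default: the translocation targets).
#' @param ibd_relocate_to node to which excluded populations are
#'   analytically moved for the relocation counterfactual (default: the
#'   translocation source's placement node).
#' @param ibd_n_perm Mantel permutations.
#' @param ibd_n_rep equivalence-test replicates.
#' @param tree_n_boot locus-bootstrap replicates.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(sim = sim_params(),
                            network = example_river_network(),
                            translocation = NULL,
                            qc = qc_config(),
                            stock_map = default_stock_map(names(network$placements)),
                            pseudocount = 0.5,
                            n_baseline_per_collection = 50L,
                            ibd_exclude = NULL,
                            ibd_relocate_to = NULL,
                            ibd_n_perm = 10000L,
                            ibd_n_rep = 10000L,
                            tree_n_boot = 1000L) {
  if (is.null(ibd_exclude) && !is.null(translocation))
    ibd_exclude <- translocation$targets
  if (is.null(ibd_relocate_to) && !is.null(translocation))
    ibd_relocate_to <- unname(network$placements[translocation$source])
  if (!is.null(ibd_exclude)) {
    bad <- setdiff(ibd_exclude, names(network$placements))
    if (length(bad))
      stop("ibd_exclude contains unknown population(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(sim = sim, network = network, translocation = translocation,
                 qc = qc, stock_map = stock_map, pseudocount = pseudocount,
                 n_baseline_per_collection = as.integer(n_baseline_per_collection),
                 ibd_exclude = ibd_exclude, ibd_relocate_to = ibd_relocate_to,
                 ibd_n_perm = as.integer(ibd_n_perm),
                 ibd_n_rep = as.integer(ibd_n_rep),
                 tree_n_boot = as.integer(tree_n_boot)),
            class = "scenario_config")
}

#' Run the full scenario pipeline
#'
#' Executes simulate -> qc -> fst -> gsi -> ibd -> tree and returns a
#' structured report. Every stage draws its seed deterministically from the
#' master seed, so identical config + seed reproduce the report exactly.
#' A stage failure aborts with the stage name; partial results built so far
#' are attached to the error condition.
#'
#' @param cfg a [scenario_config()].
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, writes `report.json`, the
#'   theta and distance matrices as CSV, and the tree as Newick.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(cfg, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  report <- list(master_seed = seed,
                 stage_seeds = stats::setNames(
                   vapply(1:7, function(k) stage_seed(seed, k), 0L),
                   c("frequencies", "translocation", "genotypes", "qc",
                     "baseline", "ibd", "tree")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  net <- cfg$network
  freqs <- stage("simulate", {
    f <- simulate_allele_frequencies(net, cfg$sim, seed = stage_seed(seed, 1))
    if (!is.null(cfg$translocation))
      f <- apply_translocation(f, cfg$translocation, seed = stage_seed(seed, 2))
    f
  })
  g <- stage("genotypes",
             sample_genotypes(freqs, cfg$sim, seed = stage_seed(seed, 3)))
  qc <- stage("qc", run_qc(g, cfg$qc, seed = stage_seed(seed, 4)))
  report$qc <- list(removed_individuals = qc$removed_individuals,
                    removed_loci = qc$removed_loci,
                    homogenize_log = qc$homogenize_log,
                    dropped = qc$dropped)

  fst <- stage("fst", pairwise_fst_matrix(qc$genotypes, qc$collections))
  report$theta <- fst$theta

  report$gsi <- stage("gsi", {
    base_params <- cfg$sim
    base_params$n_per_collection <- cfg$n_baseline_per_collection
    base_g <- sample_genotypes(freqs, base_params,
                               seed = stage_seed(seed, 5), years = 2016L)
    base_g <- gm_subset(base_g, loci = colnames(qc$genotypes$calls))
    baseline <- fit_baseline(base_g, cfg$stock_map, cfg$pseudocount)
    fit <- em_mixture(qc$genotypes, baseline)
    summ <- assign_and_summarize(
      qc$genotypes, baseline, fit,
      true_stock = unname(cfg$stock_map[qc$genotypes$labels$population]))
    list(pi = fit$pi, iterations = fit$iterations, converged = fit$converged,
         accuracy_matrix = summ$accuracy_matrix, cdf = summ$cdf,
         assignments = summ$assignments)
  })

  report$ibd <- stage("ibd", {
    pops <- rownames(fst$theta)
    y <- rousset_linearize(fst)
    excl <- intersect(cfg$ibd_exclude %||% character(), pops)
    ref_pops <- setdiff(pops, excl)
    sseed <- stage_seed(seed, 6)
    d_all <- stream_distances(net, pops)
    one <- function(p_set, d, k) {
      yy <- y[p_set, p_set, drop = FALSE]
      dd <- d[p_set, p_set, drop = FALSE]
      fit <- ibd_regression(yy, dd)
      mt <- mantel_test(yy, dd, n_perm = cfg$ibd_n_perm,
                        seed = stage_seed(sseed, k))
      list(fit = fit, slope = fit$slope, se_slope = fit$se_slope,
           rho = mt$rho, mantel_p = mt$p_value)
    }
    all_fit <- one(pops, d_all, 1)
    ref_fit <- one(ref_pops, d_all, 2)
    net_rel <- if (length(excl) && !is.null(cfg$ibd_relocate_to))
      relocate_populations(net, stats::setNames(
        rep(cfg$ibd_relocate_to, length(excl)), excl)) else net
    d_rel <- stream_distances(net_rel, pops)
    rel_fit <- one(pops, d_rel, 3)
    eq_full <- ibd_equivalence_test(ref_fit$fit, y, d_all,
                                    n_rep = cfg$ibd_n_rep,
                                    seed = stage_seed(sseed, 4))
    eq_rel <- ibd_equivalence_test(ref_fit$fit, y, d_rel,
                                   n_rep = cfg$ibd_n_rep,
                                   seed = stage_seed(sseed, 5))
    list(all = all_fit[c("slope", "se_slope", "rho", "mantel_p")],
         reference = ref_fit[c("slope", "se_slope", "rho", "mantel_p")],
         relocated = rel_fit[c("slope", "se_slope", "rho", "mantel_p")],
         excluded = excl,
         equivalence_full_vs_reference = eq_full$p_value,
         equivalence_relocated_vs_reference = eq_rel$p_value)
  })

  report$tree <- stage("tree", {
    fr <- freq_from_genotypes(qc$genotypes)
    tr <- bootstrap_support(fr, n_boot = cfg$tree_n_boot,
                            seed = stage_seed(seed, 7))
    tmp <- tempfile(fileext = ".nwk")
    write_newick(tr, tmp)
    nwk <- readLines(tmp)
    unlink(tmp)
    list(newick = nwk, support = attr(tr, "support"),
         high_support = attr(tr, "high_support"))
  })

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$theta, file.path(out_dir, "theta.csv"))
  writeLines(report$tree$newick, file.path(out_dir, "tree.nwk"))
  ser <- unclass(report)
  ser$gsi$assignments <- NULL   # bulky per-individual table stays in R
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       matrix = "rowmajor", dataframe = "columns")
  invisible(out_dir)
}
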