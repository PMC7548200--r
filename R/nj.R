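# Neighbor-joining population tree on chord distances, locus-bootstrap
# support, and Newick export.
#
# The agglomeration is implemented here (rather than delegated) so that the
# tie-break is deterministic: labels are sorted canonically on entry, and
# among equal Q-criterion values the lexicographically first pair is joined.
# ape supplies the phylo container and the Newick parser used in testing.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q_ij = (n-2) d_ij - r_i - r_j`. Input labels are sorted canonically and
#' ties in Q are broken by that order, so the output is deterministic.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero; the number clamped is recorded in attribute `n_clamped`.
#'
#' @param D symmetric labelled distance matrix, zero diagonal, n >= 3.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  check_dist_matrix(D, what = "D")
  n <- nrow(D)
  if (n < 3L) stop("size error: need at least 3 taxa", call. = FALSE)
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  labs <- rownames(D)
  # working representation: Newick fragment per active node
  frag <- quote_newick_label(labs)
  fmt <- function(x) sprintf("%.12g", x)
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nm <- c(rownames(D)[keep], paste0("__u", m))
    dimnames(D2) <- list(nm, nm)
    D <- D2
    frag <- c(frag[keep], new_frag)
  }
  # final trifurcation: branch lengths solve the three pairwise equations
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(l1), frag[2], fmt(l2), frag[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  # ape keeps surrounding quotes on parsed labels; restore the raw names
  tree$tip.label <- unquote_newick_label(tree$tip.label)
  n_clamped <- sum(tree$edge.length < 0)
  if (n_clamped > 0) tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_clamped") <- n_clamped
  tree
}

# Tip-label descendant sets per node, built over a postorder edge walk.
node_descendants <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1L]; ch <- edge[k, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  desc
}

# Map each non-root internal node of `tree` to its canonical bipartition:
# the tip set on the side *not* containing the alphabetically first tip,
# sorted and "|"-joined. Trivial splits yield NA.
node_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips)[1L]
  desc <- node_descendants(tree)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  internal <- setdiff(unique(tree$edge[, 1L]), root)
  out <- stats::setNames(rep(NA_character_, length(internal)), internal)
  for (nd in internal) {
    side <- sort(desc[[nd]])
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      out[as.character(nd)] <- paste(side, collapse = "|")
  }
  out
}

# Canonical non-trivial bipartitions of an unrooted phylo.
tree_bipartitions <- function(tree) {
  bp <- node_bipartitions(tree)
  unique(bp[!is.na(bp)])
}

#' Locus-bootstrap support for a chord-distance neighbor-joining tree
#'
#' Loci (columns of the frequency table, taken in canonical sorted order)
#' are resampled with replacement `n_boot` times; each replicate's
#' chord-distance matrix and NJ tree are rebuilt, and the support of each
#' internal edge of the point-estimate tree is the percentage of replicates
#' containing the same bipartition. Supports are written as integer internal
#' node labels on the returned tree; edges at or above `report_threshold`
#' are listed in the `high_support` attribute (the conventional display
#' cut-off).
#'
#' @param freqs populations x loci reference-allele frequency matrix.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param report_threshold highlight threshold in percent (default 80).
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   supports; attributes `support` (data frame bipartition/support) and
#'   `high_support`.
#' @export
bootstrap_support <- function(freqs, n_boot = 1000L, seed = 1L,
                              report_threshold = 80) {
  if (n_boot < 1) stop("parameter error: n_boot must be >= 1", call. = FALSE)
  if (ncol(freqs) < 2L) stop("need at least 2 loci", call. = FALSE)
  freqs <- freqs[, order(colnames(freqs) %||% seq_len(ncol(freqs))), drop = FALSE]
  point <- neighbor_joining(chord_distance_matrix(freqs))
  bp_point <- node_bipartitions(point)
  hits <- stats::setNames(numeric(length(bp_point)), bp_point)
  set.seed(seed)
  L <- ncol(freqs)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    tb <- neighbor_joining(chord_distance_matrix(freqs[, idx, drop = FALSE]))
    bp <- tree_bipartitions(tb)
    present <- names(hits) %in% bp
    hits[present] <- hits[present] + 1
  }
  support <- round(100 * hits / n_boot)
  nl <- rep("", point$Nnode)
  ntip <- length(point$tip.label)
  for (nd in names(bp_point)) {
    key <- bp_point[[nd]]
    if (!is.na(key)) nl[as.integer(nd) - ntip] <- as.character(support[[key]])
  }
  point$node.label <- nl
  attr(point, "support") <- data.frame(bipartition = names(support),
                                       support = unname(support),
                                       stringsAsFactors = FALSE)
  attr(point, "high_support") <- names(support)[support >= report_threshold]
  point
}

quote_newick_label <- function(x) {
  # ']' first so the bracket class parses; POSIX classes take '\' literally
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Write a tree to a Newick file
#'
#' Standard Newick with branch lengths and any integer bootstrap supports as
#' internal node labels. Labels containing spaces or Newick metacharacters
#' are single-quoted per convention (ape's writer would mangle them to
#' underscores, so serialisation is done here).
#'
#' @param tree an `ape::phylo` tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  blen <- tree$edge.length
  fmt <- function(x) sprintf("%.10g", x)
  ser <- function(node) {
    if (node <= ntip) return(quote_newick_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      s <- ser(tree$edge[r, 2L])
      if (!is.null(blen)) s <- paste0(s, ":", fmt(blen[r]))
      s
    }, "")
    lab <- if (!is.null(tree$node.label)) {
      nl <- tree$node.label[node - ntip]
      if (is.na(nl)) "" else quote_newick_label(nl)
    } else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  ok <- try(writeLines(paste0(ser(root), ";"), path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("file error writing ", path, call. = FALSE)
  invisible(path)
}
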