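# Neighbor joining, locus-bootstrap support, Newick export.

# additive distances from a known 4-taxon tree ((A,B),(C,D)) with internal
# edge length m and pendant lengths la..ld
additive_4taxa <- function(la, lb, lc, ld, m) {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- la + lb
  d["A", "C"] <- la + m + lc; d["A", "D"] <- la + m + ld
  d["B", "C"] <- lb + m + lc; d["B", "D"] <- lb + m + ld
  d["C", "D"] <- lc + ld
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

edge_length_of <- function(tree, tipset) {
  # branch length of the internal edge defining bipartition tipset
  bp <- rivergsi:::node_bipartitions(tree)
  key <- paste(sort(tipset), collapse = "|")
  nd <- as.integer(names(bp)[which(bp == key)])
  if (!length(nd)) return(NA_real_)
  tree$edge.length[tree$edge[, 2] == nd]
}

test_that("NJ recovers additive 4-taxon trees exactly", {
  set.seed(14)
  for (i in 1:20) {
    lens <- runif(5, 0.5, 5)
    d <- additive_4taxa(lens[1], lens[2], lens[3], lens[4], lens[5])
    tr <- neighbor_joining(d)
    expect_true(setequal(tr$tip.label, c("A", "B", "C", "D")))
    bp <- rivergsi:::tree_bipartitions(tr)
    expect_identical(bp, "C|D")  # the (A,B)|(C,D) split, anchored at A
    # branch lengths: tip-to-tip path distances reproduce d exactly
    pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(pd, d, tolerance = 1e-9)
    # internal edge length equals m
    expect_equal(edge_length_of(tr, c("C", "D")), lens[5], tolerance = 1e-9)
  }
})

test_that("NJ three-taxon star solves the pairwise equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_identical(tr$Nnode, 1L)
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  expect_error(neighbor_joining(d[1:2, 1:2]), "size error")
})

test_that("NJ agrees with the ape reference implementation on random matrices", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    pts <- matrix(rnorm(2 * n), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    t1 <- neighbor_joining(d)
    t2 <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ output is invariant to input label order", {
  set.seed(18)
  d <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  t1 <- neighbor_joining(d)
  perm <- sample(6)
  t2 <- neighbor_joining(d[perm, perm])
  expect_identical(sort(rivergsi:::tree_bipartitions(t1)),
                   sort(rivergsi:::tree_bipartitions(t2)))
})

test_that("bootstrap support is 100 for disjoint-fixation splits", {
  fr <- rbind(A = rep(c(0, 0, 1, 1), 10), B = rep(c(0, 0, 1, 1), 10),
              C = rep(c(1, 1, 0, 0), 10), D = rep(c(1, 1, 0, 0), 10))
  fr["B", 1] <- 0.1; fr["D", 2] <- 0.9   # break exact ties
  colnames(fr) <- sprintf("l%02d", 1:40)
  tr <- bootstrap_support(fr, n_boot = 100, seed = 1)
  sup <- attr(tr, "support")
  expect_true(all(sup$support == 100))
  expect_identical(attr(tr, "high_support"), sup$bipartition)
  expect_error(bootstrap_support(fr, n_boot = 0), "parameter error")
})

test_that("a duplicated population pair forms a maximally supported cherry", {
  set.seed(19)
  base <- runif(60, .1, .9)
  fr <- rbind(P1 = base, P2 = pmin(base + 0.001, 1),   # near-identical pair
              Q1 = runif(60, .1, .9), Q2 = runif(60, .1, .9),
              Q3 = runif(60, .1, .9))
  colnames(fr) <- sprintf("l%02d", 1:60)
  tr <- bootstrap_support(fr, n_boot = 200, seed = 2)
  sup <- attr(tr, "support")
  cherry <- sup$support[sup$bipartition == "P1|P2"]
  if (!length(cherry)) {
    # anchored representation may phrase the split as the complement
    cherry <- sup$support[sup$bipartition == "Q1|Q2|Q3"]
  }
  expect_gte(cherry, 95)
})

test_that("support values are invariant to input locus order", {
  set.seed(20)
  fr <- matrix(runif(5 * 50, .1, .9), 5,
               dimnames = list(paste0("P", 1:5), sprintf("l%02d", 1:50)))
  t1 <- bootstrap_support(fr, n_boot = 50, seed = 3)
  perm <- sample(50)
  t2 <- bootstrap_support(fr[, perm], n_boot = 50, seed = 3)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
})

test_that("Newick round trip preserves topology, lengths and supports", {
  set.seed(21)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:12, 1), rooted = FALSE)
    tr$node.label <- as.character(sample(50:100, tr$Nnode, TRUE))
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    tr2 <- ape::read.tree(path)
    expect_identical(sort(tr2$tip.label), sort(tr$tip.label))
    expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
    o1 <- order(tr$edge[, 2]); o2 <- order(tr2$edge[, 2])
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("labels with spaces are quoted in Newick output", {
  d <- additive_4taxa(1, 1, 1, 1, 2)
  dimnames(d) <- list(c("A 1", "B", "C", "D"), c("A 1", "B", "C", "D"))
  tr <- neighbor_joining(d)
  expect_true("A 1" %in% tr$tip.label)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_match(readLines(path), "'A 1'", fixed = TRUE)
})
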