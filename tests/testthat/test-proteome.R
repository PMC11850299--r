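# Proteome similarity, UPGMA, leaf ordering, flat clusters, group classes
# and the TSV/Newick exports. stats::hclust + stats::cophenetic and
# ape::read.tree serve as independent oracles.

test_that("similarity follows the symmetric mean of directional fractions", {
  gs <- list(A = c("a", "b", "c", "d"), B = c("a", "b"))
  pm <- proteome_similarity(gs)
  expect_equal(pm$S["A", "B"], 0.5 * (2 / 4 + 2 / 2))   # 0.75
  expect_equal(pm$S["B", "A"], 0.75)
  expect_equal(diag(pm$S), c(A = 1, B = 1))
  expect_equal(pm$D, 1 - pm$S)
  # identical and disjoint proteomes
  pm2 <- proteome_similarity(list(X = c("a", "b"), Y = c("a", "b"),
                                  Z = c("q", "r")))
  expect_equal(pm2$S["X", "Y"], 1)
  expect_equal(pm2$D["X", "Y"], 0)
  expect_equal(pm2$S["X", "Z"], 0)
  # jaccard option
  pmj <- proteome_similarity(gs, method = "jaccard")
  expect_equal(pmj$S["A", "B"], 2 / 4)
})

test_that("empty proteomes give zero similarity and do not disturb others", {
  pm <- proteome_similarity(list(A = c("a"), B = character(0), C = c("a")))
  expect_equal(pm$S["A", "B"], 0)
  expect_equal(pm$S["B", "B"], 1)
  expect_equal(pm$S["A", "C"], 1)
  pm0 <- proteome_similarity(list(A = c("a"), C = c("a")))
  expect_equal(pm$S[c("A", "C"), c("A", "C")], pm0$S)
})

test_that("matrix properties hold on random group-set inputs", {
  set.seed(42)
  for (trial in 1:25) {
    n <- sample(1:8, 1)
    pool <- paste0("g", 1:15)
    gs <- lapply(seq_len(n), function(i)
      sample(pool, sample(0:10, 1)))
    names(gs) <- paste0("L", seq_len(n))
    pm <- proteome_similarity(gs)
    expect_equal(pm$S, t(pm$S))
    expect_true(all(diag(pm$S) == 1))
    expect_true(all(pm$S >= 0 & pm$S <= 1))
    expect_equal(pm$D, 1 - pm$S)
  }
})

test_that("UPGMA reproduces the hand-worked three-leaf example", {
  D <- matrix(c(0, .2, .6,
                .2, 0, .4,
                .6, .4, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                  c("A", "B", "C")))
  tree <- upgma(D)
  expect_equal(tree$height, c(0.1, 0.25))   # ((0.6+0.4)/2)/2 = 0.25
  expect_equal(leaf_order(tree), c("A", "B", "C"))
  expect_equal(as_newick(tree), "((A:0.1,B:0.1):0.15,C:0.25);")
  # cophenetic distances: d(A,B)=0.2, d(A,C)=d(B,C)=0.5
  cm <- cophenetic_matrix(tree)
  expect_equal(cm["A", "B"], 0.2)
  expect_equal(cm["A", "C"], 0.5)
  expect_equal(cm["B", "C"], 0.5)
  # cluster cut at 0.3 separates {A,B} from {C}
  cl <- cut_tree_clusters(tree, max_distance = 0.3)
  expect_equal(unname(cl["A"]), unname(cl["B"]))
  expect_false(cl[["C"]] == cl[["A"]])
})

test_that("two-leaf and single-leaf trees are handled", {
  D <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- upgma(D)
  expect_equal(tree$height, 0.2)
  t1 <- upgma(matrix(0, 1, 1, dimnames = list("A", "A")))
  expect_equal(leaf_order(t1), "A")
  expect_equal(as_newick(t1), "A;")
})

test_that("UPGMA rejects malformed distance matrices", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(neg), "non-negative")
})

test_that("cophenetic distances equal stats::hclust average-linkage oracle", {
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(3:6, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2)
    D <- D + t(D)
    dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
    tree <- upgma(D)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(cophenetic_matrix(tree)[hc$labels, hc$labels],
                 as.matrix(stats::cophenetic(hc)), tolerance = 1e-12)
    # merge heights are non-decreasing (UPGMA on a proper dissimilarity)
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("cophenetic distances also match the from-scratch averaging oracle", {
  set.seed(11)
  for (trial in 1:10) {
    n <- sample(2:6, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2)
    D <- D + t(D)
    dimnames(D) <- list(paste0("x", 1:n), paste0("x", 1:n))
    expect_equal(cophenetic_matrix(upgma(D)), brute_upgma_cophenetic(D),
                 tolerance = 1e-12)
  }
})

test_that("tree structure is equivariant under leaf relabelling", {
  set.seed(3)
  n <- 5
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2)
  D <- D + t(D)
  dimnames(D) <- list(paste0("a", 1:n), paste0("a", 1:n))
  perm <- sample(n)
  D2 <- D[perm, perm]
  cm1 <- cophenetic_matrix(upgma(D))
  cm2 <- cophenetic_matrix(upgma(D2))
  expect_equal(cm2[rownames(cm1), colnames(cm1)], cm1, tolerance = 1e-12)
})

test_that("flat cluster cut behaves at the extremes", {
  n <- 4
  ids <- paste0("L", 1:n)
  D0 <- matrix(0, n, n, dimnames = list(ids, ids))
  expect_equal(length(unique(cut_tree_clusters(upgma(D0), 0.75))), 1L)
  D1 <- matrix(1, n, n, dimnames = list(ids, ids)); diag(D1) <- 0
  expect_equal(length(unique(cut_tree_clusters(upgma(D1), 0.75))), n)
  # cluster labels follow first appearance in leaf order
  cl <- cut_tree_clusters(upgma(D1), 0.75)
  lo <- leaf_order(upgma(D1))
  expect_equal(unname(cl[lo]), paste0("C", 1:n))
})

test_that("group classes split by presence fraction with the stated cutoffs", {
  clusters <- c(L1 = "C1", L2 = "C1", L3 = "C1", L4 = "C1")
  gs <- list(L1 = c("core", "half", "rare"), L2 = c("core", "half"),
             L3 = c("core"), L4 = c("core"))
  cls <- classify_protein_groups(clusters, gs)
  expect_equal(cls$class[cls$group_id == "core"], "conserved")     # f = 1
  expect_equal(cls$class[cls$group_id == "half"], "intermediate")  # f = 0.5
  expect_equal(cls$class[cls$group_id == "rare"], "variable")      # f = 0.25
  expect_equal(cls$presence_fraction[cls$group_id == "rare"], 0.25)
  # partition: every group in a cluster gets exactly one class
  expect_equal(nrow(cls), 3L)
  expect_false(anyNA(cls$class))
})

test_that("singleton clusters classify every group conserved", {
  cls <- classify_protein_groups(c(L1 = "C1"), list(L1 = c("a", "b")))
  expect_equal(unique(cls$class), "conserved")
})

test_that("paralogues count loci once in presence fractions", {
  # the group-set representation already de-duplicates per locus, so two
  # copies in one locus contribute a single presence
  clusters <- c(L1 = "C1", L2 = "C1")
  gs <- list(L1 = c("dup"), L2 = character(0))
  cls <- classify_protein_groups(clusters, gs)
  expect_equal(cls$presence_fraction, 0.5)
})

test_that("Newick export matches ape's reading of the same tree", {
  set.seed(9)
  n <- 5
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  D <- D + t(D)
  ids <- paste0("v", 1:n)
  dimnames(D) <- list(ids, ids)
  tree <- upgma(D)
  phy <- ape::read.tree(text = as_newick(tree))
  expect_setequal(phy$tip.label, ids)
  # ape's patristic distances equal our cophenetic distances
  pd <- ape::cophenetic.phylo(phy)
  expect_equal(pd[ids, ids], cophenetic_matrix(tree), tolerance = 1e-6)
})

test_that("similarity TSV round-trips through read.delim", {
  pm <- proteome_analysis(list(A = c("a", "b"), B = c("a"), C = c("z")))
  tsv <- tempfile(fileext = ".tsv")
  nwk <- tempfile(fileext = ".nwk")
  write_similarity_tsv(pm, tsv, nwk)
  back <- utils::read.delim(tsv)
  expect_equal(back$locus_id, c("A", "B", "C"))
  expect_equal(as.matrix(back[, -1]), pm$S, ignore_attr = TRUE)
  expect_match(readLines(nwk), ";$")
})
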