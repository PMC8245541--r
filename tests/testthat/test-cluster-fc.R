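test_that("fold-change matrix equals hand-computed centered log2 values", {
  young <- data.frame(protein_id = c("P1", "P2", "P3"),
                      mean_ratio = c(2.0, 1.0, 0.5),
                      class = c("up", "unchanged", "down"))
  aged <- data.frame(protein_id = c("P1", "P2", "P3"),
                     mean_ratio = c(0.5, 1.0, 2.0),
                     class = c("down", "unchanged", "up"))
  mat <- build_fc_matrix(list(young = young, aged = aged))
  # reciprocal pair centers to +/-1 in log2; flat protein to zeros
  expect_equal(unname(mat["P1", ]), c(1, -1))
  expect_equal(unname(mat["P2", ]), c(0, 0))
  expect_equal(unname(mat["P3", ]), c(-1, 1))
  expect_equal(unname(rowMeans(mat)), rep(0, 3))

  # hand-computed: log2 minus row mean
  y <- c(1.3, 0.9, 1.6); a <- c(0.7, 1.1, 1.2)
  cy <- data.frame(protein_id = c("A", "B", "C"), mean_ratio = y,
                   class = "unchanged")
  ca <- data.frame(protein_id = c("A", "B", "C"), mean_ratio = a,
                   class = "unchanged")
  m2 <- build_fc_matrix(list(cy, ca))
  hand <- cbind(log2(y), log2(a))
  hand <- hand - rowMeans(hand)
  expect_equal(unname(m2), hand, ignore_attr = TRUE)
})

test_that("ratios of 1 everywhere give a zero matrix", {
  c1 <- data.frame(protein_id = c("A", "B"), mean_ratio = 1,
                   class = "unchanged")
  mat <- build_fc_matrix(list(c1, c1))
  expect_true(all(mat == 0))
})

test_that("matrix construction drops non-majority proteins and flags the window", {
  young <- data.frame(protein_id = c("P1", "P2", "P3"),
                      mean_ratio = c(1.05, 1.4, NA),
                      class = c("unchanged", "up", "insufficient"))
  aged <- data.frame(protein_id = c("P1", "P2", "P3"),
                     mean_ratio = c(0.95, 1.3, 1.0),
                     class = c("unchanged", "up", "unchanged"))
  mat <- build_fc_matrix(list(young = young, aged = aged),
                         window = c(0.85, 1.15))
  expect_identical(rownames(mat), c("P1", "P2"))  # P3 not in both
  expect_identical(unname(attr(mat, "in_window")), c(TRUE, FALSE))

  only_a <- data.frame(protein_id = "X", mean_ratio = 1,
                       class = "unchanged")
  only_b <- data.frame(protein_id = "Y", mean_ratio = 1,
                       class = "unchanged")
  expect_error(build_fc_matrix(list(only_a, only_b)), "overlap is empty")
})

test_that("replicate-level matrix imputes missing cells with the cohort mean", {
  m1 <- matrix(c(2, 2, NA, 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("P1", "P2"), c("r1", "r2", "r3")))
  m2 <- matrix(c(4, 4, 4, 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("P1", "P2"), c("r1", "r2", "r3")))
  tabs <- list(young = ratio_table(m1, oriented = TRUE),
               aged = ratio_table(m2, oriented = TRUE))
  mat <- build_fc_matrix(tabs, values = "replicates", center = "none")
  expect_identical(dim(mat), c(2L, 6L))
  expect_false(anyNA(mat))
  expect_equal(mat["P1", "young.r3"], log2(2))  # imputed cohort mean
})

test_that("the 4-leaf worked example merges at heights 1, 1.5, 5.25", {
  m <- matrix(c(0, 1, 5, 6.5), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "x"))
  tree <- average_linkage_tree(m)
  expect_equal(tree$height, c(1, 1.5, 5.25))
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  expect_identical(tree$merge[2, ], c(-3L, -4L))
  expect_identical(tree$merge[3, ], c(1L, 2L))

  k2 <- cut_tree(tree, 2)
  expect_identical(unname(k2), c(1L, 1L, 2L, 2L))
})

test_that("identical rows merge first at height zero", {
  m <- matrix(c(1, 1, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  tree <- average_linkage_tree(m)
  expect_identical(tree$height[1], 0)
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  two <- average_linkage_tree(matrix(c(1, 1), 2, 1))
  expect_identical(two$height, 0)
})

test_that("merge sequence matches the brute-force recomputation oracle", {
  set.seed(404)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    if (rep %% 5 == 0) m[2, ] <- m[1, ]  # force exact ties sometimes
    tree <- average_linkage_tree(m)
    oracle <- upgma_oracle(m)
    expect_identical(tree$merge, oracle$merge)
    expect_equal(tree$height, oracle$height, tolerance = 1e-12)
  }
})

test_that("heights agree with stats::hclust average linkage", {
  set.seed(77)
  m <- matrix(rnorm(40 * 4), 40, 4)
  tree <- average_linkage_tree(m)
  ref <- stats::hclust(stats::dist(m), method = "average")
  expect_equal(tree$height, ref$height, tolerance = 1e-10)
  # same partitions at several cuts (continuous data: no ties)
  for (k in c(2, 5, 10)) {
    a <- cut_tree(tree, k)
    b <- stats::cutree(ref, k)
    expect_identical(unname(table(a, b) > 0) %*% rep(1, k),
                     matrix(1, k, 1))  # one-to-one group matching
  }
})

test_that("scaling the matrix scales heights and preserves topology", {
  set.seed(88)
  m <- matrix(rnorm(18), 6, 3)
  t1 <- average_linkage_tree(m)
  t3 <- average_linkage_tree(3 * m)
  expect_identical(t1$merge, t3$merge)
  expect_equal(t3$height, 3 * t1$height, tolerance = 1e-12)
})

test_that("average-linkage heights are monotone non-decreasing", {
  set.seed(99)
  for (rep in 1:20) {
    m <- matrix(rnorm(10 * sample(2:4, 1)), 10)
    tree <- average_linkage_tree(m)
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("degenerate clustering inputs are rejected", {
  expect_error(average_linkage_tree(matrix(1, 1, 2)), ">= 2 rows")
  expect_error(average_linkage_tree(matrix(c(1, NA, 2, 3), 2, 2)),
               "non-finite")
  tree <- average_linkage_tree(matrix(rnorm(8), 4, 2))
  expect_error(cut_tree(tree, 0), "integer >= 1")
  expect_error(cut_tree(tree, 5), "between 1")
  expect_identical(unname(cut_tree(tree, 1)), rep(1L, 4))
  expect_identical(unname(cut_tree(tree, 4)), 1:4)
})

test_that("newick export round-trips through ape with the same topology", {
  set.seed(111)
  m <- matrix(rnorm(7 * 3), 7, 3,
              dimnames = list(sprintf("P%d", 1:7), NULL))
  tree <- average_linkage_tree(m)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, sprintf("P%d", 1:7))
  expect_identical(
    ape::dist.topo(ape::unroot(phy),
                   ape::unroot(ape::as.phylo(tree)))[1], 0)
})
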