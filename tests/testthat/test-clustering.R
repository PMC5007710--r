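test_that("standardize_matrix matches the hand z-score and is idempotent", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("v1", NULL))
  expect_equal(unname(standardize_matrix(m)[1, ]), c(-1, 0, 1))
  set.seed(8)
  x <- matrix(rnorm(50, mean = 4, sd = 3), nrow = 5,
              dimnames = list(sprintf("v%d", 1:5), NULL))
  x[2, 3] <- NA
  z <- standardize_matrix(x)
  for (i in 1:5) {
    v <- z[i, !is.na(z[i, ])]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(stats::var(v) - 1), 1e-10)
  }
  expect_equal(standardize_matrix(z), z, tolerance = 1e-10)
  expect_identical(is.na(z), is.na(x))
  bad <- rbind(x, const = rep(2, 10))
  expect_error(standardize_matrix(bad), "constant variable: const")
  # column orientation mirrors row orientation
  expect_equal(standardize_matrix(t(x), margin = 2L), t(z))
})

test_that("profile distances follow the pairwise-available rescaling rule", {
  expect_equal(as.numeric(profile_dist(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(as.numeric(profile_dist(rbind(c(1, 2, 3), c(1, 2, 3)))), 0)
  # missing coordinate omitted, magnitude rescaled by sqrt(m / m_shared)
  d <- as.numeric(profile_dist(rbind(c(0, 0, NA), c(3, 4, 7))))
  expect_equal(d, 5 * sqrt(3 / 2))
  expect_warning(profile_dist(rbind(c(NA, 1), c(2, NA))), "no non-missing")
})

test_that("complete linkage reproduces the hand-agglomerated 1-D example", {
  x <- matrix(c(0, 1, 5, 7), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  tree <- complete_linkage(x)
  expect_equal(tree$height, c(1, 2, 7))
  expect_equal(tree$merge[1, ], c(-1L, -2L))  # {0,1} at height 1
  expect_equal(tree$merge[2, ], c(-3L, -4L))  # {5,7} at height 2
  expect_equal(tree$merge[3, ], c(1L, 2L))    # union at max distance 7
  cl <- cut_tree(tree, 2)
  expect_equal(unname(cl$labels), c(1L, 1L, 2L, 2L))
  # base case: 2 objects merge at their distance
  t2 <- complete_linkage(matrix(c(0, 3), ncol = 1,
                                dimnames = list(c("u", "v"), NULL)))
  expect_equal(t2$height, 3)
})

test_that("linkage agrees with the brute-force agglomeration oracle", {
  set.seed(303)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    d <- random_dist(n, tied = rep %% 2 == 0)
    tree <- complete_linkage(d)
    oracle <- brute_linkage(d)
    expect_identical(tree$merge, oracle$merge)
    expect_equal(tree$height, oracle$height, tolerance = 1e-12)
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone heights
  }
})

test_that("merge heights match stats::hclust on tie-free instances", {
  set.seed(99)
  for (rep in 1:10) {
    x <- matrix(rnorm(8 * 4), nrow = 8,
                dimnames = list(sprintf("O%d", 1:8), NULL))
    tree <- complete_linkage(x)
    ref <- stats::hclust(stats::dist(x), method = "complete")
    expect_equal(tree$height, ref$height, tolerance = 1e-12)
    # same flat partitions at every k
    for (k in 2:7) {
      ours <- cut_tree(tree, k)$labels
      theirs <- stats::cutree(ref, k)
      expect_equal(length(unique(paste(ours, theirs))), k)
    }
  }
})

test_that("object order does not change the partition, given the tie rule", {
  set.seed(17)
  x <- matrix(rnorm(9 * 3), nrow = 9,
              dimnames = list(sprintf("O%d", 1:9), NULL))
  tree <- complete_linkage(x)
  perm <- sample(9)
  tree_p <- complete_linkage(x[perm, , drop = FALSE])
  for (k in c(2, 3, 5)) {
    a <- cut_tree(tree, k)$labels
    b <- cut_tree(tree_p, k)$labels[names(a)]
    expect_equal(length(unique(paste(a, b))), k)
  }
})

test_that("cut_tree covers root and leaf cuts and validates k", {
  set.seed(2)
  x <- matrix(rnorm(12), nrow = 6, dimnames = list(letters[1:6], NULL))
  tree <- complete_linkage(x)
  expect_equal(unname(cut_tree(tree, 1)$labels), rep(1L, 6))
  expect_equal(sort(unname(cut_tree(tree, 6)$labels)), 1:6)
  expect_error(cut_tree(tree, 0), "k must lie")
  expect_error(cut_tree(tree, 7), "k must lie")
  # numbering by first appearance: labels of the k=6 cut are 1..6 in order
  expect_equal(unname(cut_tree(tree, 6)$labels), 1:6)
})

test_that("missing pairwise distances abort clustering with advice", {
  x <- rbind(a = c(NA, 1, NA), b = c(2, NA, 1), c = c(1, 2, 3))
  d <- suppressWarnings(profile_dist(x))
  expect_error(complete_linkage(d), "impute|remove")
})

test_that("newick export round-trips through ape with matching topology", {
  set.seed(12)
  x <- matrix(rnorm(10), nrow = 5, dimnames = list(letters[1:5], NULL))
  tree <- complete_linkage(x)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, letters[1:5])
  ref <- ape::as.phylo(as.hclust(tree))
  expect_true(ape::all.equal.phylo(phy, ref, use.edge.length = FALSE))
  # branch lengths survive to write/read precision
  expect_equal(sum(phy$edge.length), sum(ref$edge.length), tolerance = 1e-6)
})

test_that("the clustering recipe works end to end: standardize, distance, linkage", {
  cfg <- sim_config(n_background = 30, seed = 77)
  resp <- suppressWarnings(simulate_response(cfg))
  ex <- simulate_expression(cfg, resp, "withanolide_1")$expression
  z <- standardize_matrix(ex$values, margin = 1L)
  tree <- complete_linkage(t(z))
  expect_equal(length(tree$labels), 60L)
  expect_equal(length(tree$height), 59L)
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_setequal(tree$labels, line_ids(resp))
})
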