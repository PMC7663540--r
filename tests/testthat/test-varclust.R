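test_that("cluster homogeneity equals the leading correlation eigenvalue", {
  set.seed(11)
  n <- 50
  a <- rnorm(n)
  # single variable
  single <- std_mat(cbind(V1 = a))
  h <- cluster_homogeneity(single)
  expect_equal(h$lambda1, 1, tolerance = 1e-10)

  # two correlated variables: eigenvalues of a 2x2 correlation matrix are 1 +- r
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  x2 <- std_mat(cbind(V1 = a, V2 = b))
  r <- cor(x2[, 1], x2[, 2])
  h2 <- cluster_homogeneity(x2)
  expect_equal(h2$lambda1, 1 + abs(r), tolerance = 1e-10)

  # three exact copies
  x3 <- std_mat(cbind(V1 = a, V2 = a, V3 = a))
  expect_equal(cluster_homogeneity(x3)$lambda1, 3, tolerance = 1e-10)

  expect_error(cluster_homogeneity(cbind(V1 = a + 5)), "standardized")
})

test_that("homogeneity satisfies the summed squared-correlation identity", {
  for (s in 1:5) {
    x <- random_std_matrix(40, 6, seed = s)
    h <- cluster_homogeneity(x)
    expect_equal(sum(cor(x, h$scores)^2), h$lambda1, tolerance = 1e-8)
    # sign convention: top-correlated variable correlates positively
    r <- as.vector(cor(x, h$scores))
    expect_gt(r[which.max(abs(r))], 0)
  }
})

test_that("dissimilarity is the homogeneity loss of a merge", {
  set.seed(21)
  n <- 60
  a <- rnorm(n); b <- rnorm(n)
  x <- std_mat(cbind(V1 = a, V2 = a, V3 = b,
                     V4 = 0.6 * a + sqrt(0.64) * rnorm(n)))
  # exact copy: d = 1 + 1 - 2 = 0
  expect_equal(dissimilarity(x, 1, 2), 0, tolerance = 1e-10)
  # independent variables: d = 2 - (1 + |r|) = 1 - |r|
  r13 <- abs(cor(x[, 1], x[, 3]))
  expect_equal(dissimilarity(x, 1, 3), 1 - r13, tolerance = 1e-10)
  r14 <- abs(cor(x[, 1], x[, 4]))
  expect_equal(dissimilarity(x, 1, 4), 1 - r14, tolerance = 1e-10)
  expect_error(dissimilarity(x, c(1, 2), c(2, 3)), "disjoint")
})

test_that("agglomeration joins duplicate pairs first at height zero", {
  x <- duplicate_pairs_matrix()
  m <- omics_matrix(x, "D", standardized = TRUE)
  tree <- agglomerate(m)
  expect_equal(nrow(tree$merge), 3)
  expect_equal(tree$height[1:2], c(0, 0), tolerance = 1e-10)
  expect_true(all(tree$height >= -1e-10))
  first_two <- lapply(tree$merged_members[1:2], sort)
  expect_setequal(lapply(first_two, paste, collapse = ","), c("1,2", "3,4"))

  single <- omics_matrix(x[, 1, drop = FALSE], "D", standardized = TRUE)
  expect_error(agglomerate(single), "at least 2")
})

test_that("greedy merge order matches the brute-force oracle on small p", {
  for (s in 1:12) {
    set.seed(100 + s)
    p <- sample(3:6, 1)
    x <- random_std_matrix(30, p, seed = 100 + s)
    m <- omics_matrix(x, "D", standardized = TRUE)
    tree <- agglomerate(m)
    oracle <- oracle_agglomerate(x)
    got <- lapply(tree$merged_members, sort)
    expect_equal(got, oracle$merges, info = paste("seed", 100 + s))
    expect_equal(tree$height, oracle$heights, tolerance = 1e-8)
  }
})

test_that("merge heights are nonnegative and total homogeneity decreases by them", {
  x <- random_std_matrix(40, 8, seed = 7)
  m <- omics_matrix(x, "D", standardized = TRUE)
  tree <- agglomerate(m)
  expect_length(tree$height, 7)
  expect_true(all(tree$height >= -1e-10))
  p <- ncol(x)
  # H at K clusters = p - sum of the first p-K merge heights
  for (K in c(1, 3, 5, 8)) {
    part <- cut_tree(tree, K, m)
    expect_equal(part$homogeneity,
                 p - sum(tree$height[seq_len(p - K)]), tolerance = 1e-8)
  }
})

test_that("cut_tree reproduces the trivial partitions", {
  x <- random_std_matrix(40, 5, seed = 9)
  m <- omics_matrix(x, "D", standardized = TRUE)
  tree <- agglomerate(m)
  # K = p: all singletons, every lambda1 exactly 1, total H = p
  all_single <- cut_tree(tree, 5, m)
  expect_equal(all_single$lambda1, rep(1, 5), tolerance = 1e-10)
  expect_equal(all_single$homogeneity, 5, tolerance = 1e-10)
  # K = 1: H = lambda1 of the full correlation matrix
  one <- cut_tree(tree, 1, m)
  expect_equal(one$homogeneity, lam1_cols(x, 1:5), tolerance = 1e-10)
  expect_error(cut_tree(tree, 0, m), "between")
  expect_error(cut_tree(tree, 6, m), "between")

  # duplicate pairs at K = 2 recover the pairs
  xd <- duplicate_pairs_matrix()
  md <- omics_matrix(xd, "D", standardized = TRUE)
  pd <- cut_tree(agglomerate(md), 2, md)
  expect_equal(unname(pd$assignment), c(1, 1, 2, 2))
  expect_equal(pd$lambda1, c(2, 2), tolerance = 1e-10)
})

test_that("block partitions have lambda1 >= 1 and score identity per block", {
  x <- random_std_matrix(50, 7, seed = 13)
  m <- omics_matrix(x, "D", standardized = TRUE)
  part <- cut_tree(agglomerate(m), 3, m)
  expect_true(all(part$lambda1 >= 1 - 1e-10))
  for (k in 1:3) {
    idx <- which(part$assignment == k)
    expect_equal(sum(cor(x[, idx, drop = FALSE], part$scores[, k])^2),
                 part$lambda1[k], tolerance = 1e-8)
  }
})

test_that("scree-based block count recovers planted structure", {
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n = 200, block_sizes = list(c(10, 10, 10)),
                            a = 0.9, censoring = 0, seed = 300 + s)
    st <- generate_multiomics(cfg)
    m <- standardize(st$layers[[1]])
    sug <- suggest_block_count(agglomerate(m), 10)
    if (sug$K == 3) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # duplicate pairs: K = 2
  xd <- duplicate_pairs_matrix()
  md <- omics_matrix(xd, "D", standardized = TRUE)
  expect_equal(suggest_block_count(agglomerate(md), 3)$K, 2)

  # independent variables: the flat scree is usually flagged low-confidence
  # (the flag is a heuristic on noisy gap ratios, so test its rate)
  flags <- vapply(1:20, function(s) {
    set.seed(7000 + s)
    xi <- std_mat(matrix(rnorm(200 * 12), 200, 12,
                         dimnames = list(paste0("S", 1:200), paste0("V", 1:12))))
    mi <- omics_matrix(xi, "I", standardized = TRUE)
    sug <- suggest_block_count(agglomerate(mi), 8)
    expect_true(is.numeric(sug$K) && sug$K >= 2)
    sug$low_confidence
  }, logical(1))
  expect_gte(sum(flags), 15)

  # ... while planted structure is never flagged
  cfg <- synthetic_config(n = 200, block_sizes = list(c(10, 10, 10)),
                          a = 0.9, censoring = 0, seed = 301)
  mp <- standardize(generate_multiomics(cfg)$layers[[1]])
  sugp <- suggest_block_count(agglomerate(mp), 10)
  expect_false(sugp$low_confidence)
  expect_s3_class(sugp$scree, "data.frame")
})

test_that("power iteration agrees with dense eigendecomposition", {
  x <- random_std_matrix(80, 20, seed = 17)
  R <- crossprod(x) / (nrow(x) - 1)
  dense <- bspcox:::leading_eigen(R, dense_limit = 512L)
  power <- bspcox:::leading_eigen(R, dense_limit = 1L)
  expect_equal(power$value, dense$value, tolerance = 1e-8)
  expect_equal(abs(sum(power$vector * dense$vector)), 1, tolerance = 1e-6)
})

test_that("clustering recovers planted blocks exactly (ARI = 1)", {
  skip_if_not_installed("mclust")
  hits <- 0
  for (s in 1:10) {
    cfg <- synthetic_config(n = 200, block_sizes = list(c(12, 12, 12)),
                            a = 0.9, censoring = 0, seed = 400 + s)
    st <- generate_multiomics(cfg)
    m <- standardize(st$layers[[1]])
    part <- cut_tree(agglomerate(m), 3, m)
    if (mclust::adjustedRandIndex(part$assignment, st$partitions[[1]]) == 1)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})
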