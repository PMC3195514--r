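# Preorder alignment, tolerance matching, node-count distances,
# correspondence.

test_that("preorder traversal visits root, left subtree, right subtree", {
  a <- featNode(feat(lw = 1),
                left = featNode(feat(lw = 2), level = 1L),
                right = featNode(feat(lw = 3), level = 1L))
  tree <- featTree(a)
  seq1 <- preorderNodes(tree)
  expect_length(seq1, 3)
  expect_equal(vapply(seq1, function(n) n@features[["lw_ratio"]], 1),
               c(1, 2, 3))
})

test_that("absent positions appear as explicit gaps at the depth limit", {
  a <- featNode(feat(lw = 1),
                left = featNode(feat(lw = 2),
                                left = featNode(feat(lw = 4), level = 2L),
                                right = featNode(feat(lw = 5), level = 2L),
                                level = 1L),
                right = featNode(feat(lw = 3), level = 1L))
  s <- preorderNodes(featTree(a), depthLimit = 2)
  expect_length(s, 7)
  vals <- vapply(s, function(n)
    if (is.null(n)) NA_real_ else n@features[["lw_ratio"]], numeric(1))
  expect_equal(vals, c(1, 2, 4, 5, 3, NA, NA))
  expect_length(preorderNodes(featTree(a), depthLimit = 0), 1)
})

test_that("nodeMatch applies discrete equality and continuous tolerance", {
  cfg <- matchConfig()
  f <- feat(lw = 100, bibr = 1, cross = 1, pos = 0.5, ang = 0.7)
  expect_true(nodeMatch(f, f, cfg))
  expect_true(nodeMatch(f, feat(104, 1, 1, 0.5, 0.7), cfg))
  expect_false(nodeMatch(f, feat(106, 1, 1, 0.5, 0.7), cfg))
  expect_false(nodeMatch(f, feat(100, 0, 1, 0.5, 0.7), cfg))
  expect_false(nodeMatch(f, feat(100, 1, 0, 0.5, 0.7), cfg))
  expect_false(nodeMatch(f, feat(100, 1, 1, 0.58, 0.7), cfg))
  expect_false(nodeMatch(f, feat(100, 1, 1, 0.5, 0.9), cfg))
  expect_true(nodeMatch(NULL, NULL, cfg))
  expect_false(nodeMatch(f, NULL, cfg))
  expect_false(nodeMatch(NULL, f, cfg))
})

completeTree <- function(bibr) {
  lv <- function(lw, level, left = NULL, right = NULL)
    featNode(feat(lw = lw, bibr = bibr), left = left, right = right,
             level = level)
  featTree(lv(10, 0L,
              lv(11, 1L, lv(13, 2L), lv(14, 2L)),
              lv(12, 1L, lv(15, 2L), lv(16, 2L))))
}

test_that("tree distance is 0 for identity and 7 for all-differing trees", {
  t0 <- completeTree(0)
  t1 <- completeTree(1)
  expect_identical(treeDistance(t0, t0), 0L + 0L)
  expect_equal(treeDistance(t0, t1), 7)
  expect_equal(treeDistance(t0, t1, matchConfig(candidateDepth = 0)), 1)
})

test_that("a missing child costs exactly one gap mismatch", {
  full <- featTree(featNode(feat(lw = 5),
                            left = featNode(feat(lw = 6), level = 1L),
                            right = featNode(feat(lw = 7), level = 1L)))
  lop <- featTree(featNode(feat(lw = 5),
                           left = featNode(feat(lw = 6), level = 1L)))
  expect_equal(treeDistance(full, lop, matchConfig(candidateDepth = 1)), 1)
})

test_that("tree distance equals the brute-force array oracle", {
  withr::local_seed(421)
  cfgs <- list(matchConfig(relTolerance = 0, angleTolerance = 0),
               matchConfig())
  for (k in 1:300) {
    t1 <- randomFeatureTree()
    t2 <- if (k %% 3 == 0) t1 else randomFeatureTree()
    for (cfg in cfgs)
      expect_identical(as.integer(treeDistance(t1, t2, cfg)),
                       as.integer(treeDistanceOracle(t1, t2, cfg)))
  }
})

test_that("distance is bounded by the complete-tree position count", {
  withr::local_seed(7)
  for (k in 1:100) {
    d <- treeDistance(randomFeatureTree(), randomFeatureTree())
    expect_gte(d, 0)
    expect_lte(d, 7)
  }
})

test_that("distance never increases when tolerances widen", {
  withr::local_seed(99)
  cfgs <- list(matchConfig(relTolerance = 0, angleTolerance = 0),
               matchConfig(relTolerance = 0.05),
               matchConfig(relTolerance = 0.25, angleTolerance = 0.3))
  for (k in 1:100) {
    t1 <- randomFeatureTree()
    t2 <- randomFeatureTree()
    d <- vapply(cfgs, function(cfg) treeDistance(t1, t2, cfg), numeric(1))
    expect_true(all(diff(d) <= 0))
  }
})

test_that("correspondence of a model with a reshuffled copy is exact", {
  withr::local_seed(11)
  trees <- lapply(1:5, function(i) {
    t <- randomFeatureTree(keep = 1)
    t@vesselId <- sprintf("V%d", i)
    t
  })
  mk <- function(tl) new("TreeModel", od = list(center = c(1, 1), radius = 1),
                         trees = tl, normalization = NULL, finalized = TRUE)
  a <- mk(trees)
  b <- mk(rev(trees))
  corr <- findCorrespondence(a, b)
  expect_identical(nrow(corr@pairs), 5L)
  expect_true(all(corr@pairs$distance == 0))
  expect_identical(corr@pairs$vesselA, corr@pairs$vesselB)
  self <- findCorrespondence(a, a)
  expect_true(all(self@pairs$treeA == self@pairs$treeB))
})

test_that("unequal tree counts leave the excess unmatched", {
  withr::local_seed(12)
  trees <- lapply(1:4, function(i) randomFeatureTree())
  mk <- function(tl) new("TreeModel", od = list(center = c(1, 1), radius = 1),
                         trees = tl, normalization = NULL, finalized = TRUE)
  corr <- findCorrespondence(mk(trees), mk(trees[1:2]))
  expect_identical(nrow(corr@pairs), 2L)
  expect_length(corr@unmatchedA, 2L)
  expect_length(corr@unmatchedB, 0L)
})

test_that("model distance matrices are symmetric with zero diagonal", {
  withr::local_seed(13)
  models <- lapply(1:3, function(i)
    new("TreeModel", od = list(center = c(1, 1), radius = 1),
        trees = lapply(1:4, function(j) randomFeatureTree()),
        normalization = NULL, finalized = TRUE))
  m <- modelDistanceMatrix(models)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0L))
  expect_identical(modelDistanceMatrix(models[1]),
                   matrix(0L, 1, 1, dimnames = list("model1", "model1")))
})

test_that("structurally disjoint five-tree models are 35 apart", {
  mk <- function(bibr)
    new("TreeModel", od = list(center = c(1, 1), radius = 1),
        trees = lapply(1:5, function(i) completeTree(bibr)),
        normalization = NULL, finalized = TRUE)
  m <- modelDistanceMatrix(list(mk(0), mk(1)))
  expect_identical(m[1, 2], 35L)
})

test_that("matching results are identical for raw and normalized models", {
  withr::local_seed(14)
  mk <- function() new("TreeModel", od = list(center = c(1, 1), radius = 1),
                       trees = lapply(1:4, function(j) randomFeatureTree()),
                       normalization = NULL, finalized = TRUE)
  a <- mk(); b <- mk()
  rawM <- vesselDistanceMatrix(a, b)
  an <- normalizeModel(a)$model
  bn <- normalizeModel(b)$model
  expect_equal(unname(vesselDistanceMatrix(an, bn)), unname(rawM))
  expect_identical(modelDistance(an, bn), modelDistance(a, b))
})

test_that("vessel distance matrix of a model against itself has zero diagonal", {
  sc <- generateScene(smallSpec(seed = 7))
  model <- buildTreeModel(sc$scene)
  m <- vesselDistanceMatrix(model, model)
  expect_true(all(diag(m) == 0L))
})
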