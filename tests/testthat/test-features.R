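# The five invariant features and model normalization.

bandScene <- function(theta, w, len = 60, size = 161) {
  ctr <- c(81, 81)
  d <- c(-cos(theta), sin(theta))
  p0 <- ctr - len / 2 * d
  p1 <- ctr + len / 2 * d
  pts <- vasctree:::.bezierPoints(p0, (p0 + p1) / 2, p1)
  mask <- vasctree:::.bandMask(matrix(0L, size, size), pts, w / 2)
  list(mask = mask, path = vasctree:::.curveChain(pts))
}

test_that("profile width of a rendered bar is close to its nominal width", {
  b <- bandScene(0.3, 5)
  expect_gt(segmentAvgWidth(b$path, b$mask), 4)
  expect_lt(segmentAvgWidth(b$path, b$mask), 6)
})

test_that("a 1-px line measures a width between 1 and 2", {
  mask <- matrix(0L, 64, 64)
  mask[cbind(30, 10:50)] <- 1L
  w <- segmentAvgWidth(hline(30, 14:46), mask)
  expect_gte(w, 1)
  expect_lte(w, 2)
})

test_that("width is invariant under a 90-degree change of bar direction", {
  h <- bandScene(pi / 2, 5)
  v <- bandScene(0, 5)
  expect_lt(abs(segmentAvgWidth(h$path, h$mask) -
                segmentAvgWidth(v$path, v$mask)), 0.1)
})

test_that("a path pixel outside the mask is reported by position", {
  sc <- rasterScene(list(hline(30, 10:50)), size = 64)
  bad <- rbind(hline(30, 20:40), c(5, 5))
  expect_error(segmentAvgWidth(bad, sc@mask), "\\(5, 5\\)")
})

test_that("lwRatio divides arc length by width", {
  seg <- dummySegment(n = 100, width = 4)
  expect_equal(lwRatio(seg), 25)
  seg2 <- dummySegment(n = 4, width = 4)
  expect_equal(lwRatio(seg2), 1)
  seg3 <- dummySegment(n = 10, width = 0)
  expect_error(lwRatio(seg3), "width")
})

test_that("landmark classes encode as 1 for bifurcation and 0 for branch", {
  expect_identical(encodeLandmark(list(class = "bifurcation")), 1)
  expect_identical(encodeLandmark(list(class = "branch")), 0)
  expect_error(encodeLandmark(list(class = "crossover")), "crossover")
})

test_that("crossover features give the relative position of the crossing", {
  seg <- dummySegment(n = 100, crossIdx = 70)
  expect_equal(crossoverFeatures(seg),
               c(crossover_flag = 1, crossover_pos = 0.7))
  expect_equal(crossoverFeatures(dummySegment(n = 100)),
               c(crossover_flag = 0, crossover_pos = 0))
  first <- crossoverFeatures(dummySegment(n = 100, crossIdx = 1))
  expect_equal(first[["crossover_flag"]], 1)
  expect_equal(first[["crossover_pos"]], 0.01)
})

straightSeg <- function(dr, dc, n = 40, width = 4, from = c(100, 100),
                        atEnd = FALSE) {
  steps <- t(vapply(seq_len(n) - 1, function(k)
    from + k * c(dr, dc), numeric(2)))
  path <- round(steps)
  if (atEnd) path <- path[rev(seq_len(n)), ]
  new("VesselSegment", id = "s", path = path, terminatingLandmark = NULL,
      lengthPx = n, arcLength = vasctree:::.pathArcLength(path),
      avgWidth = width,
      crossovers = data.frame(index = numeric(0), row = numeric(0),
                              col = numeric(0)))
}

test_that("acute angle is pi/2 for orthogonal and 0 for parallel arms", {
  parent <- straightSeg(0, 1, width = 6, atEnd = TRUE)
  dOrth <- straightSeg(1, 0, width = 3)
  dPar <- straightSeg(0, 1, width = 3)
  expect_equal(acuteAngle(parent, list(dOrth)), pi / 2, tolerance = 1e-6)
  expect_equal(acuteAngle(parent, list(dPar)), 0, tolerance = 1e-6)
})

test_that("the angle pairs the widest with the narrowest arm", {
  parent <- straightSeg(0, 1, width = 5, atEnd = TRUE)
  d45 <- straightSeg(1, 1, width = 3)     # 45 degrees off the parent
  d90 <- straightSeg(1, 0, width = 2)     # 90 degrees off the parent
  # widths 5 > 3 > 2: angle is between the width-5 parent and the width-2
  # daughter, ignoring the width-3 one
  expect_equal(acuteAngle(parent, list(d45, d90)), pi / 2, tolerance = 1e-6)
})

test_that("feature vectors assemble in canonical order", {
  term <- list(row = 1, col = 1, class = "bifurcation", index = 1L)
  seg <- dummySegment(n = 60, width = 5, terminating = term)
  node <- new("SegmentNode", segment = seg, features = feat(),
              left = NULL, right = NULL, level = 0L)
  fv <- buildFeatureVector(node, list(straightSeg(1, 0, width = 3),
                                      straightSeg(1, 1, width = 2)))
  expect_identical(names(fv),
                   c("lw_ratio", "bibr_code", "crossover_flag",
                     "crossover_pos", "acute_angle"))
  expect_equal(fv[["lw_ratio"]], 12)
  expect_identical(fv[["bibr_code"]], 1)
  expect_identical(fv[["crossover_flag"]], 0)
  expect_gt(fv[["acute_angle"]], 0)
  expect_lte(fv[["acute_angle"]], pi / 2)
})

test_that("terminal nodes get code 0 and angle 0", {
  seg <- dummySegment(n = 60, width = 5)
  node <- new("SegmentNode", segment = seg, features = feat(),
              left = NULL, right = NULL, level = 2L)
  fv <- buildFeatureVector(node, list())
  expect_identical(fv[["bibr_code"]], 0)
  expect_identical(fv[["acute_angle"]], 0)
})

test_that("L/W is scale invariant for proportionally scaled bars", {
  a <- bandScene(0.6, 5, len = 60)
  b <- bandScene(0.6, 10, len = 120, size = 221)
  lwA <- vasctree:::.pathArcLength(a$path) / segmentAvgWidth(a$path, a$mask)
  lwB <- vasctree:::.pathArcLength(b$path) / segmentAvgWidth(b$path, b$mask)
  expect_lt(abs(lwA - lwB) / lwA, 0.05)
})

test_that("normalization scales to the model maximum and is idempotent", {
  n1 <- featNode(feat(lw = 88.77, ang = pi / 2))
  n2 <- featNode(feat(lw = 44.385, ang = pi / 4))
  model <- new("TreeModel", od = list(center = c(1, 1), radius = 1),
               trees = list(featTree(n1, "V1"), featTree(n2, "V2")),
               normalization = NULL, finalized = TRUE)
  norm <- normalizeModel(model)
  expect_equal(norm$params$lw_max, 88.77)
  expect_equal(norm$params$angle_scale, pi / 2)
  f1 <- norm$model@trees[[1]]@root@features
  f2 <- norm$model@trees[[2]]@root@features
  expect_equal(f1[["lw_ratio"]], 1)
  expect_equal(f1[["acute_angle"]], 1)
  expect_equal(f2[["lw_ratio"]], 0.5)
  again <- normalizeModel(norm$model)
  expect_equal(again$model@trees[[1]]@root@features, f1)
})

test_that("normalizing an empty model yields identity parameters", {
  model <- new("TreeModel", od = list(center = c(1, 1), radius = 1),
               trees = list(), normalization = NULL, finalized = TRUE)
  norm <- normalizeModel(model)
  expect_equal(norm$params$lw_max, 1)
})

test_that("built models keep features inside their domains", {
  sc <- generateScene(smallSpec(seed = 6))
  model <- buildTreeModel(sc$scene)
  for (t in model@trees)
    for (n in collectNodes(t)) {
      if (is.null(n)) next
      fv <- n@features
      expect_gt(fv[["lw_ratio"]], 0)
      expect_true(fv[["bibr_code"]] %in% c(0, 1))
      expect_true(fv[["crossover_flag"]] %in% c(0, 1))
      expect_gte(fv[["crossover_pos"]], 0)
      expect_lt(fv[["crossover_pos"]], 1)
      if (fv[["crossover_flag"]] == 0)
        expect_identical(fv[["crossover_pos"]], 0)
      expect_gte(fv[["acute_angle"]], 0)
      expect_lte(fv[["acute_angle"]], pi / 2)
    }
})
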