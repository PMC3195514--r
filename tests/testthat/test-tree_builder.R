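# Root discovery, fragmentation, region-growing traversal, tree assembly.

test_that("findVesselRoots recovers one root per vessel near the truth start", {
  sc <- generateScene(smallSpec(seed = 1))
  roots <- findVesselRoots(sc$scene)
  expect_identical(nrow(roots), 5L)
  starts <- t(vapply(sc$truth@vessels, function(v) v$root$start, numeric(2)))
  for (i in seq_len(nrow(roots))) {
    d <- sqrt((starts[, 1] - roots[i, 1])^2 + (starts[, 2] - roots[i, 2])^2)
    expect_lte(min(d), 4)
  }
})

test_that("roots come out sorted clockwise from 12 o'clock", {
  sc <- generateScene(smallSpec(seed = 2))
  roots <- findVesselRoots(sc$scene)
  ctr <- sc$scene@od$center
  ang <- apply(roots, 1, function(p)
    (atan2(p[2] - ctr[2], -(p[1] - ctr[1])) + 2 * pi) %% (2 * pi))
  expect_false(is.unsorted(ang))
})

test_that("a blank centerline yields no roots", {
  sc <- rasterScene(list(), size = 64)
  expect_identical(nrow(findVesselRoots(sc)), 0L)
})

test_that("adjacent annulus hits cluster to one representative", {
  # one horizontal line from the OD center outward crosses the annulus
  # over several adjacent pixels
  sc <- rasterScene(list(hline(32, 32:60)), size = 64,
                    od = list(center = c(32, 32), radius = 8))
  roots <- findVesselRoots(sc)
  expect_identical(nrow(roots), 1L)
})

test_that("a straight line with a split landmark fragments into 3 pieces", {
  lines <- list(hline(30, 6:30), hline(20, 31:55), hline(40, 31:55))
  # arms actually 8-connect to the junction pixel
  lines[[2]] <- rbind(cbind(29:21, 31:39), hline(20, 40:55))
  lines[[3]] <- rbind(cbind(31:39, 31:39), hline(40, 40:55))
  lm <- data.frame(row = 30, col = 30, class = "bifurcation")
  sc <- rasterScene(lines, lm, size = 64)
  frag <- fragmentCenterline(sc)
  labs <- fragmentLabels(frag)
  expect_identical(max(labs), 3L)
})

test_that("with no landmarks each connected component is one fragment", {
  sc <- rasterScene(list(hline(10, 5:40), hline(50, 5:40)), size = 64)
  frag <- fragmentCenterline(sc)
  expect_identical(max(fragmentLabels(frag)), 2L)
})

test_that("an X crossing with a crossover landmark yields 4 fragments", {
  a <- cbind(12:52, 12:52)
  b <- cbind(52:12, 12:52)
  lm <- data.frame(row = 32, col = 32, class = "crossover")
  sc <- rasterScene(list(a, b), lm, size = 64)
  frag <- fragmentCenterline(sc)
  expect_identical(max(fragmentLabels(frag)), 4L)
})

test_that("landmarks far from the centerline snap with warning or fail", {
  sc <- rasterScene(list(hline(30, 5:60)),
                    data.frame(row = 33, col = 30, class = "branch"),
                    size = 64)
  expect_warning(frag <- fragmentCenterline(sc), "snapped")
  expect_identical(frag@landmarks$row, 30)

  sc2 <- rasterScene(list(hline(30, 5:60)),
                     data.frame(row = 40, col = 30, class = "branch"),
                     size = 64)
  expect_error(fragmentCenterline(sc2), "from the centerline")
})

test_that("tracing a horizontal line walks all 10 pixels to the tip", {
  sc <- rasterScene(list(hline(30, 11:20)), size = 64)
  seg <- traceSegment(fragmentCenterline(sc), c(30, 11))
  expect_identical(seg@lengthPx, 10L)
  expect_equal(seg@path[10, ], c(30, 20), ignore_attr = TRUE)
  expect_null(seg@terminatingLandmark)
  expect_equal(seg@arcLength, 10)
})

test_that("an L-shaped fragment traces as one 8-connected path", {
  l <- rbind(hline(30, 10:15), vline(16, 31:35))
  sc <- rasterScene(list(l), size = 64)
  seg <- traceSegment(fragmentCenterline(sc), c(30, 10))
  expect_identical(seg@lengthPx, 11L)
  d <- abs(diff(seg@path))
  expect_true(all(pmax(d[, 1], d[, 2]) <= 1))
})

test_that("a trace into a split landmark records its class", {
  lines <- list(hline(30, 6:30),
                rbind(cbind(29:21, 31:39)),
                rbind(cbind(31:39, 31:39)))
  lm <- data.frame(row = 30, col = 30, class = "bifurcation")
  sc <- rasterScene(lines, lm, size = 64)
  seg <- traceSegment(fragmentCenterline(sc), c(30, 6),
                      incomingDir = c(0, 1))
  expect_identical(seg@terminatingLandmark$class, "bifurcation")
  # the path is bridged up to the landmark pixel itself
  expect_equal(seg@path[seg@lengthPx, ], c(30, 30), ignore_attr = TRUE)
})

test_that("tracing a startpixel off the raster errors", {
  sc <- rasterScene(list(hline(30, 10:20)), size = 64)
  expect_error(traceSegment(fragmentCenterline(sc), c(5, 5)),
               "not on the centerline")
})

test_that("crossover continuation goes straight through a + crossing", {
  horiz <- hline(32, 7:57)
  vert <- vline(32, 7:57)
  lm <- data.frame(row = 32, col = 32, class = "crossover")
  sc <- rasterScene(list(horiz, vert), lm, size = 64)
  frag <- fragmentCenterline(sc)
  seg <- traceSegment(frag, c(32, 7), incomingDir = c(0, 1))
  # single segment straight through; crossover near the path midpoint
  expect_equal(seg@path[seg@lengthPx, ], c(32, 57), ignore_attr = TRUE)
  expect_identical(nrow(seg@crossovers), 1L)
  expect_lt(abs(seg@crossovers$index / seg@lengthPx - 0.5), 0.1)
})

test_that("minimal-deviation rule picks the straight arm at a crossing", {
  sc <- rasterScene(list(hline(32, 7:57), cbind(52:12, 12:52)),
                    data.frame(row = 32, col = 32, class = "crossover"),
                    size = 64)
  frag <- fragmentCenterline(sc)
  vis <- vasctree:::.newVisited(frag)
  vis$v[32, 7:30] <- TRUE
  path <- hline(32, 7:30)
  nxt <- resolveCrossoverContinuation(frag, path, 1L, vis$v)
  expect_identical(nxt[1], 32)
  expect_gt(nxt[2], 32)
})

test_that("the crossing vessel can still be traced after a continuation", {
  horiz <- hline(32, 7:57)
  vert <- vline(30, 7:57)
  lm <- data.frame(row = 32, col = 30, class = "crossover")
  sc <- rasterScene(list(horiz, vert), lm, size = 64)
  frag <- fragmentCenterline(sc)
  vis <- vasctree:::.newVisited(frag)
  s1 <- traceSegment(frag, c(32, 7), incomingDir = c(0, 1), visited = vis)
  s2 <- traceSegment(frag, c(7, 30), incomingDir = c(1, 0), visited = vis)
  expect_identical(nrow(s1@crossovers), 1L)
  expect_gt(s2@lengthPx, 40)
})

test_that("a vessel without landmarks builds a single-node tree", {
  sc <- rasterScene(list(hline(32, 40:60)), size = 64,
                    od = list(center = c(32, 32), radius = 8))
  tree <- buildVesselTree(sc, c(32, 40))
  expect_identical(nodeCount(tree), 1L)
})

test_that("built trees are isomorphic to the ground truth", {
  sc <- generateScene(smallSpec(seed = 3))
  model <- buildTreeModel(sc$scene)
  expect_true(modelMatchesTruth(model, sc$truth))
})

test_that("the model has one tree per vessel and the truth's node count", {
  sc <- generateScene(smallSpec(seed = 4))
  model <- buildTreeModel(sc$scene)
  expect_length(model@trees, 5)
  expect_identical(nodeCount(model), 35L)
  expect_true(isFinalized(model))
})

test_that("an empty scene builds an empty model", {
  sc <- rasterScene(list(), size = 64)
  model <- buildTreeModel(sc)
  expect_length(model@trees, 0)
  expect_true(isFinalized(model))
})

test_that("tracing is invariant to whole-scene integer translation", {
  sc <- generateScene(smallSpec(seed = 5))
  dr <- 6L; dc <- -9L
  shift <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    src <- m[1:(nrow(m) - dr), (1 - dc):ncol(m)]
    out[(1 + dr):nrow(m), 1:(ncol(m) + dc)] <- src
    out
  }
  lm <- sc$scene@landmarks
  lm$row <- lm$row + dr
  lm$col <- lm$col + dc
  shifted <- VascularScene(shift(sc$scene@centerline), shift(sc$scene@mask),
                           lm, list(center = sc$scene@od$center + c(dr, dc),
                                    radius = sc$scene@od$radius))
  m1 <- buildTreeModel(sc$scene)
  m2 <- buildTreeModel(shifted)
  expect_identical(nodeCount(m1), nodeCount(m2))
  f1 <- lapply(m1@trees, function(t) lapply(collectNodes(t), function(n)
    if (is.null(n)) NULL else n@features))
  f2 <- lapply(m2@trees, function(t) lapply(collectNodes(t), function(n)
    if (is.null(n)) NULL else n@features))
  expect_equal(f1, f2, tolerance = 1e-12)
})
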