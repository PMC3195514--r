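# Shared fixtures: small fast scenes, hand-built rasters, synthetic feature
# trees, and an independent brute-force tree-distance oracle.

# Small scene for unit tests (half the default scale; builds in well under
# a second). The full-scale default spec is reserved for the end-to-end
# rotation and topology checks.
smallSpec <- function(seed = 1L, ...) {
  sceneSpec(imageSize = 512, seed = seed, ...)
}

feat <- function(lw = 10, bibr = 0, cross = 0, pos = 0, ang = 0) {
  stats::setNames(c(lw, bibr, cross, pos, ang),
                  c("lw_ratio", "bibr_code", "crossover_flag",
                    "crossover_pos", "acute_angle"))
}

# A minimal VesselSegment with a straight horizontal path of n pixels.
dummySegment <- function(n = 10, id = "S", width = 4,
                         crossIdx = integer(0), row = 5, col0 = 1,
                         terminating = NULL) {
  path <- cbind(rep(row, n), col0 + seq_len(n) - 1)
  cr <- if (length(crossIdx))
    data.frame(index = crossIdx, row = path[crossIdx, 1],
               col = path[crossIdx, 2])
  else data.frame(index = numeric(0), row = numeric(0), col = numeric(0))
  new("VesselSegment", id = id, path = path, terminatingLandmark = terminating,
      lengthPx = n, arcLength = vasctree:::.pathArcLength(path),
      avgWidth = width, crossovers = cr)
}

featNode <- function(features, left = NULL, right = NULL, level = 0L) {
  new("SegmentNode", segment = dummySegment(id = "synthetic"),
      features = features, left = left, right = right,
      level = as.integer(level))
}

featTree <- function(root, vesselId = "V1") {
  new("BinaryVesselTree", vesselId = vesselId, root = root,
      rootPixel = c(1, 1))
}

# Random feature tree: complete to `depth` then pruned (children survive
# with probability keep). Continuous features are drawn from wide ranges so
# random values never collide at tolerance 0.
randomFeatureTree <- function(depth = 2, keep = 0.8) {
  build <- function(level) {
    hasCross <- stats::runif(1) < 0.4
    node <- featNode(feat(lw = stats::runif(1, 2, 60),
                          bibr = sample(0:1, 1),
                          cross = as.numeric(hasCross),
                          pos = if (hasCross) stats::runif(1, 0.05, 0.95) else 0,
                          ang = stats::runif(1, 0, pi / 2)),
                     level = level)
    if (level < depth) {
      if (stats::runif(1) < keep) node@left <- build(level + 1L)
      if (stats::runif(1) < keep) node@right <- build(level + 1L)
    }
    node
  }
  featTree(build(0L))
}

# Independent oracle: materialize both trees as heap-ordered arrays of the
# complete binary tree (index 1 root, children 2i, 2i+1) and count the
# positions whose feature vectors fail nodeMatch. Shares no code with the
# preorder alignment it checks.
treeDistanceOracle <- function(t1, t2, cfg = matchConfig(), depth = 2L) {
  nPos <- 2L^(depth + 1L) - 1L
  toArray <- function(tree) {
    arr <- vector("list", nPos)
    fill <- function(node, i) {
      if (is.null(node) || i > nPos) return(invisible())
      arr[[i]] <<- node@features
      fill(node@left, 2L * i)
      fill(node@right, 2L * i + 1L)
    }
    root <- if (is(tree, "BinaryVesselTree")) tree@root else tree
    fill(root, 1L)
    arr
  }
  a <- toArray(t1)
  b <- toArray(t2)
  sum(!vapply(seq_len(nPos), function(i)
    nodeMatch(a[[i]], b[[i]], cfg), logical(1)))
}

# Hand-built scene: a horizontal centerline bar with optional landmarks.
# `lines` is a list of n x 2 integer matrices; landmarks a data.frame.
rasterScene <- function(lines, landmarks = NULL, size = 64,
                        od = list(center = c(size / 2, size / 2), radius = 8),
                        maskPad = 2) {
  cl <- matrix(0L, size, size)
  mask <- matrix(0L, size, size)
  for (ln in lines) {
    cl[ln] <- 1L
    mask <- vasctree:::.stampDiscs(mask, ln, maskPad)
  }
  if (is.null(landmarks))
    landmarks <- data.frame(row = numeric(0), col = numeric(0),
                            class = character(0))
  VascularScene(cl, mask, landmarks, od)
}

hline <- function(row, cols) cbind(rep(row, length(cols)), cols)
vline <- function(col, rows) cbind(rows, rep(col, length(rows)))

# Ordered node list (preorder, with NULL gaps implicit by shape) of a tree.
collectNodes <- function(tree) {
  out <- list()
  rec <- function(n) {
    if (is.null(n)) {
      out[[length(out) + 1L]] <<- NULL
      return(invisible())
    }
    out[[length(out) + 1L]] <<- n
    rec(n@left)
    rec(n@right)
  }
  rec(tree@root)
  out
}

# Does a built tree reproduce the ground-truth topology (shape plus
# landmark classes, left = wider daughter = the truth record's first child)?
treeMatchesTruth <- function(tree, truthRec) {
  cmp <- function(node, rec) {
    if (is.null(node) && is.null(rec)) return(TRUE)
    if (is.null(node) || is.null(rec)) return(FALSE)
    term <- node@segment@terminatingLandmark
    builtClass <- if (is.null(term)) NA_character_ else term$class
    if (!identical(is.na(builtClass), is.na(rec$landmarkClass))) return(FALSE)
    if (!is.na(rec$landmarkClass) && builtClass != rec$landmarkClass)
      return(FALSE)
    nKids <- length(rec$children)
    builtKids <- Filter(Negate(is.null), list(node@left, node@right))
    if (length(builtKids) != nKids) return(FALSE)
    if (nKids == 0) return(TRUE)
    cmp(node@left, rec$children[[1]]) && cmp(node@right, rec$children[[2]])
  }
  cmp(tree@root, truthRec)
}

modelMatchesTruth <- function(model, truth) {
  ids <- matchTreesToTruth(model, truth)
  if (anyNA(ids)) return(FALSE)
  truthIds <- vapply(truth@vessels, function(v) v$id, character(1))
  all(vapply(seq_along(ids), function(i)
    treeMatchesTruth(model@trees[[i]],
                     truth@vessels[[match(ids[i], truthIds)]]$root),
    logical(1)))
}
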