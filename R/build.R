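# Assembly of the tree model: root discovery, per-vessel binary trees,
# feature computation.

# Walk inward from an annulus representative to the true start of the
# vessel line (the connected centerline pixel closest to the OD center).
.walkToLineStart <- function(frag, rep, ctr) {
  m <- frag@raster; b <- frag@boundary
  nr <- nrow(m); nc <- ncol(m)
  cur <- rep
  repeat {
    rcur <- sqrt(sum((cur - ctr)^2))
    nbr <- sweep(.NB8, 2, cur, "+")
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= nr & nbr[, 2] >= 1 & nbr[, 2] <= nc
    nbr <- nbr[ok, , drop = FALSE]
    nbr <- nbr[m[nbr] == 1L & b[nbr] == 0L, , drop = FALSE]
    if (nrow(nbr) == 0) return(cur)
    rn <- sqrt((nbr[, 1] - ctr[1])^2 + (nbr[, 2] - ctr[2])^2)
    j <- which(rn < rcur - 0.2)
    if (!length(j)) return(cur)
    j <- j[order(rn[j])[1]]
    cur <- as.numeric(nbr[j, ])
  }
}

# Daughter discovery at a split landmark: trace from every untraced
# non-boundary pixel adjacent to the landmark's zone; each trace claims one
# arm. Paths shorter than 3 px are discarded as stubs.
.traceDaughters <- function(frag, visited, lmIndex, maxIterations) {
  lmPix <- c(frag@landmarks$row[lmIndex], frag@landmarks$col[lmIndex])
  zone <- which(frag@boundary == lmIndex, arr.ind = TRUE)
  nr <- nrow(frag@raster); nc <- ncol(frag@raster)
  ring <- function(radius) {
    off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
    off <- off[pmax(abs(off$dr), abs(off$dc)) > 0, ]
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(zone)), function(i)
      cbind(zone[i, 1] + off$dr, zone[i, 2] + off$dc))))
    keep <- cand[, 1] >= 1 & cand[, 1] <= nr &
      cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[keep, , drop = FALSE]
    keep <- frag@raster[cand] == 1L & frag@boundary[cand] == 0L
    cand <- cand[keep, , drop = FALSE]
    cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  }
  out <- list()
  traceFrom <- function(cand) {
    for (i in seq_len(nrow(cand))) {
      p <- as.numeric(cand[i, ])
      if (visited$v[p[1], p[2]]) next
      bridge <- .bresenham(lmPix, p)
      visited$v[p[1], p[2]] <- TRUE
      dir <- (p - lmPix) / sqrt(sum((p - lmPix)^2))
      tr <- .traceCore(frag, visited, bridge, dir, ignore = lmIndex,
                       maxIterations = maxIterations)
      if (nrow(tr$path) < 3) next
      out[[length(out) + 1L]] <<- tr
    }
  }
  traceFrom(ring(1L))
  # two arms can funnel through one shared neck pixel next to the zone,
  # leaving the second arm invisible from the 8-neighbourhood; widen the
  # candidate ring when an arm is missing
  if (length(out) < 2) traceFrom(ring(2L))
  out
}

.buildNode <- function(frag, visited, tr, segId, level, mask, sm,
                       maxDepthTrace, maxIterations) {
  seg <- .makeSegment(segId, tr)
  seg@avgWidth <- .avgWidthFromMask(seg@path, mask, sm)
  node <- new("SegmentNode", segment = seg,
              features = stats::setNames(rep(NA_real_, 5), .FEATURE_NAMES),
              left = NULL, right = NULL, level = as.integer(level))
  term <- tr$terminating
  if (!is.null(term) && term$class %in% c("bifurcation", "branch") &&
      level < maxDepthTrace) {
    daughters <- .traceDaughters(frag, visited, term$index, maxIterations)
    if (length(daughters) != 2)
      .vtMessage("landmark ", term$index, ": expected 2 daughters, found ",
                 length(daughters))
    if (length(daughters) > 2) daughters <- daughters[1:2]
    kids <- lapply(seq_along(daughters), function(i)
      .buildNode(frag, visited, daughters[[i]],
                 paste0(segId, letters[i]), level + 1L, mask, sm,
                 maxDepthTrace, maxIterations))
    if (length(kids) == 2) {
      wA <- kids[[1]]@segment@avgWidth
      wB <- kids[[2]]@segment@avgWidth
      swap <- FALSE
      if (!is.na(wA) && !is.na(wB)) {
        if (wB > wA) swap <- TRUE
        else if (wB == wA) {
          # tie: smaller angle to parent direction, then lexicographic start
          pd <- .fitDirection(utils::tail(seg@path, 20))
          angOf <- function(k) .acuteBetween(
            pd, .fitDirection(utils::head(k@segment@path, 20)))
          aA <- angOf(kids[[1]]); aB <- angOf(kids[[2]])
          if (aB < aA) swap <- TRUE
          else if (aB == aA) {
            sA <- kids[[1]]@segment@path[1, ]
            sB <- kids[[2]]@segment@path[1, ]
            if (sB[1] < sA[1] || (sB[1] == sA[1] && sB[2] < sA[2]))
              swap <- TRUE
          }
        }
      }
      if (swap) kids <- kids[c(2, 1)]
      node@left <- kids[[1]]
      node@right <- kids[[2]]
    } else if (length(kids) == 1) {
      node@left <- kids[[1]]
    }
  }
  node
}

#' Build the binary tree of one vessel
#'
#' Traces the root segment from a root pixel on the optic-disc annulus,
#' then recursively traces the two daughter segments at every terminating
#' bifurcation/branch landmark. The left child is the daughter of larger
#' average width (tie: smaller angle to the parent direction, then
#' lexicographic start pixel).
#'
#' @param scene a [VascularScene-class].
#' @param rootPixel `(row, col)` from [findVesselRoots()].
#' @param frag optional precomputed [FragmentedCenterline-class].
#' @param visited optional shared visited environment (so several vessels
#'   of one scene share trace flags).
#' @param vesselId id for the tree.
#' @param maxDepthTrace recursion limit in tree levels.
#' @param maxIterations per-segment trace budget; defaults to 10 x image
#'   width.
#' @return A [BinaryVesselTree-class] with widths measured and features
#'   pending.
#' @export
buildVesselTree <- function(scene, rootPixel, frag = NULL, visited = NULL,
                            vesselId = "V", maxDepthTrace = 10L,
                            maxIterations = NULL, sm = NULL) {
  stopifnot(is(scene, "VascularScene"))
  if (is.null(frag)) frag <- fragmentCenterline(scene)
  if (is.null(visited)) visited <- .newVisited(frag)
  mask <- scene@mask
  storage.mode(mask) <- "double"
  if (is.null(sm)) sm <- .smoothMask(mask)
  start <- .walkToLineStart(frag, as.numeric(rootPixel), scene@od$center)
  dir0 <- start - scene@od$center
  dir0 <- dir0 / sqrt(sum(dir0^2))
  visited$v[start[1], start[2]] <- TRUE
  tr <- .traceCore(frag, visited, rbind(start), dir0,
                   maxIterations = maxIterations)
  root <- .buildNode(frag, visited, tr, paste0(vesselId, ".S1"), 0L, mask,
                     sm, maxDepthTrace, maxIterations)
  new("BinaryVesselTree", vesselId = vesselId, root = root,
      rootPixel = as.numeric(rootPixel))
}

#' Build the full tree model of a scene
#'
#' Runs [findVesselRoots()], builds one binary vessel tree per root (trees
#' ordered clockwise from 12 o'clock), computes the five invariant features
#' of every node, and returns the finalized model.
#'
#' @param scene a [VascularScene-class].
#' @param maxDepthTrace recursion limit in tree levels.
#' @return A finalized [TreeModel-class].
#' @examples
#' sc <- generateScene(sceneSpec(nVessels = 3, seed = 7))
#' model <- buildTreeModel(sc$scene)
#' model
#' @export
buildTreeModel <- function(scene, maxDepthTrace = 10L) {
  stopifnot(is(scene, "VascularScene"))
  roots <- findVesselRoots(scene)
  frag <- fragmentCenterline(scene)
  visited <- .newVisited(frag)
  maskd <- scene@mask
  storage.mode(maskd) <- "double"
  sm <- .smoothMask(maskd)
  treesL <- lapply(seq_len(nrow(roots)), function(i)
    buildVesselTree(scene, roots[i, ], frag = frag, visited = visited,
                    vesselId = sprintf("V%d", i),
                    maxDepthTrace = maxDepthTrace, sm = sm))
  model <- new("TreeModel", od = scene@od, trees = treesL,
               normalization = NULL, finalized = FALSE)
  computeFeatures(model, scene)
}

#' Map built trees to ground-truth vessels
#'
#' Matches every tree of a model to the ground-truth vessel whose root
#' segment starts nearest the tree's root pixel. Used by the rotation
#' evaluation to read the "same vessel" entries of a distance matrix.
#'
#' @param model a [TreeModel-class] built from a synthetic scene.
#' @param truth the matching [GroundTruthTopology-class].
#' @param maxDist largest allowed root-to-root distance in pixels.
#' @return character vector of ground-truth vessel ids, one per tree.
#' @export
matchTreesToTruth <- function(model, truth, maxDist = 6) {
  stopifnot(is(model, "TreeModel"), is(truth, "GroundTruthTopology"))
  starts <- t(vapply(truth@vessels, function(v) v$root$start, numeric(2)))
  ids <- vapply(truth@vessels, function(v) v$id, character(1))
  vapply(model@trees, function(t) {
    p <- t@rootPixel
    d <- sqrt((starts[, 1] - p[1])^2 + (starts[, 2] - p[2])^2)
    j <- which.min(d)
    if (d[j] > maxDist) NA_character_ else ids[j]
  }, character(1))
}
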