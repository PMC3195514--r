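# Region-growing traversal of the fragmented centerline.

.newVisited <- function(frag) {
  e <- new.env(parent = emptyenv())
  e$v <- matrix(FALSE, nrow(frag@raster), ncol(frag@raster))
  e
}

# Direction averaged over (up to) the last `k` path pixels, as a unit vector.
.recentDir <- function(path, n, k = 5) {
  i0 <- max(1L, n - k)
  v <- path[n, ] - path[i0, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(NULL)
  v / nv
}

.stepAngle <- function(from, to, dir) {
  v <- to - from
  nv <- sqrt(sum(v^2))
  if (nv == 0 || is.null(dir)) return(0)
  acos(max(min(sum(v * dir) / nv, 1), -1))
}

#' Find the next start pixel across a crossover
#'
#' Among untraced non-boundary centerline pixels adjacent to the crossover
#' landmark's boundary zone, returns the one whose outgoing direction
#' deviates least from the incoming direction averaged over the last five
#' path pixels, so a vessel segment continues straight through the crossing.
#'
#' @param frag a [FragmentedCenterline-class].
#' @param path n x 2 matrix, the segment path traced so far.
#' @param landmarkIndex row index of the crossover landmark in
#'   `landmarks(frag)`.
#' @param visited optional logical matrix of already-traced pixels.
#' @return `(row, col)` of the continuation pixel, or `NULL` when the
#'   crossing is degenerate (no candidate).
#' @export
resolveCrossoverContinuation <- function(frag, path, landmarkIndex,
                                         visited = NULL) {
  stopifnot(is(frag, "FragmentedCenterline"))
  if (is.null(visited))
    visited <- matrix(FALSE, nrow(frag@raster), ncol(frag@raster))
  zone <- which(frag@boundary == landmarkIndex, arr.ind = TRUE)
  if (nrow(zone) == 0) return(NULL)
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(zone)), function(i) {
    sweep(.NB8, 2, as.numeric(zone[i, ]), "+")
  })))
  nr <- nrow(frag@raster); nc <- ncol(frag@raster)
  keep <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
  cand <- cand[keep, , drop = FALSE]
  keep <- frag@raster[cand] == 1L & frag@boundary[cand] == 0L &
    !visited[cand]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  n <- nrow(path)
  # the last-5-pixel average aliases to a 45-degree multiple on shallow
  # digital lines; a longer window plus a short probe walk per candidate
  # resolves the continuation reliably
  dir <- .recentDir(path, n, 20)
  if (is.null(dir)) dir <- .recentDir(path, n, 5)
  end <- path[n, ]
  dev <- vapply(seq_len(nrow(cand)), function(i) {
    pd <- .probeDir(frag, visited, end, as.numeric(cand[i, ]))
    if (is.null(dir)) return(0)
    acos(max(min(sum(pd * dir), 1), -1))
  }, numeric(1))
  ord <- order(dev, cand[, 1], cand[, 2])
  as.numeric(cand[ord[1], ])
}

# Direction of a candidate continuation, estimated by walking up to
# `steps` greedy straight steps from it (visited flags untouched).
.probeDir <- function(frag, visited, origin, first, steps = 10) {
  m <- frag@raster; b <- frag@boundary
  nr <- nrow(m); nc <- ncol(m)
  pts <- rbind(origin, first)
  cur <- first
  for (k in seq_len(steps)) {
    d <- .recentDir(pts, nrow(pts), 15)
    nbr <- sweep(.NB8, 2, cur, "+")
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= nr & nbr[, 2] >= 1 & nbr[, 2] <= nc
    nbr <- nbr[ok, , drop = FALSE]
    keep <- m[nbr] == 1L & b[nbr] == 0L & !visited[nbr]
    # do not walk back onto the probe itself
    for (i in seq_len(nrow(pts)))
      keep <- keep & !(nbr[, 1] == pts[i, 1] & nbr[, 2] == pts[i, 2])
    nbr <- nbr[keep, , drop = FALSE]
    if (nrow(nbr) == 0) break
    dv <- vapply(seq_len(nrow(nbr)), function(i)
      .stepAngle(cur, nbr[i, ], d), numeric(1))
    cur <- as.numeric(nbr[order(dv, nbr[, 1], nbr[, 2])[1], ])
    pts <- rbind(pts, cur)
  }
  v <- cur - origin
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(c(1, 0))
  v / nv
}

# Core tracer. `startPath` seeds the path (already appended, non-boundary
# pixels marked visited by the caller); `ignore` is a set of landmark
# indices that must not terminate this trace (the origin landmark of a
# daughter, and any crossover already continued through).
.traceCore <- function(frag, visited, startPath, dir, ignore = integer(0),
                       maxIterations = NULL) {
  m <- frag@raster; b <- frag@boundary
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(maxIterations)) maxIterations <- 10L * nc
  path <- matrix(0, maxIterations + nrow(startPath), 2)
  n <- nrow(startPath)
  path[seq_len(n), ] <- startPath
  crossRows <- list()
  terminating <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIterations) {
      .vtMessage("trace stopped: iteration budget reached")
      break
    }
    cur <- path[n, ]
    dcur <- .recentDir(path, n, 5)
    if (is.null(dcur)) dcur <- dir
    nbr <- sweep(.NB8, 2, cur, "+")
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= nr & nbr[, 2] >= 1 & nbr[, 2] <= nc
    nbr <- nbr[ok, , drop = FALSE]
    onn <- nbr[m[nbr] == 1L, , drop = FALSE]
    if (nrow(onn) == 0) break
    bIdx <- b[onn]
    isB <- bIdx > 0L & !(bIdx %in% ignore)
    if (any(isB)) {
      bn <- onn[isB, , drop = FALSE]
      bi <- bIdx[isB]
      dev <- vapply(seq_len(nrow(bn)), function(i)
        .stepAngle(cur, bn[i, ], dcur), numeric(1))
      pick <- order(dev, bn[, 1], bn[, 2])[1]
      li <- bi[pick]
      lmClass <- frag@landmarks$class[li]
      lmPix <- c(frag@landmarks$row[li], frag@landmarks$col[li])
      if (lmClass == "crossover") {
        bridge <- .bresenham(cur, lmPix)
        if (nrow(bridge) > 1) {
          add <- bridge[-1, , drop = FALSE]
          path[n + seq_len(nrow(add)), ] <- add
          n <- n + nrow(add)
        }
        crossRows[[length(crossRows) + 1L]] <-
          data.frame(index = n, row = lmPix[1], col = lmPix[2])
        nxt <- resolveCrossoverContinuation(frag, path[seq_len(n), ,
                                                       drop = FALSE],
                                            li, visited$v)
        ignore <- c(ignore, li)
        if (is.null(nxt)) {
          .vtMessage("degenerate crossover: no continuation, ending segment")
          break
        }
        bridge2 <- .bresenham(lmPix, nxt)
        add <- bridge2[-1, , drop = FALSE]
        path[n + seq_len(nrow(add)), ] <- add
        n <- n + nrow(add)
        visited$v[nxt[1], nxt[2]] <- TRUE
        next
      }
      # bifurcation or branch: bridge to the landmark pixel and stop
      bridge <- .bresenham(cur, lmPix)
      if (nrow(bridge) > 1) {
        add <- bridge[-1, , drop = FALSE]
        path[n + seq_len(nrow(add)), ] <- add
        n <- n + nrow(add)
      }
      terminating <- list(row = lmPix[1], col = lmPix[2],
                          class = lmClass, index = li)
      break
    }
    free <- onn[b[onn] == 0L & !visited$v[onn], , drop = FALSE]
    if (nrow(free) == 0) break
    if (nrow(free) > 1 && !is.null(dcur)) {
      dev <- vapply(seq_len(nrow(free)), function(i)
        .stepAngle(cur, free[i, ], dcur), numeric(1))
      dlong <- .recentDir(path, n, 15)
      dev2 <- if (is.null(dlong)) dev else
        vapply(seq_len(nrow(free)), function(i)
          .stepAngle(cur, free[i, ], dlong), numeric(1))
      pick <- order(dev, dev2, free[, 1], free[, 2])[1]
      if (sum(dev < dev[pick] + 1e-9) > 1)
        .vtMessage("ambiguous step at (", cur[1], ",", cur[2], ")")
    } else {
      pick <- order(free[, 1], free[, 2])[1]
    }
    nxt <- free[pick, ]
    n <- n + 1L
    path[n, ] <- nxt
    visited$v[nxt[1], nxt[2]] <- TRUE
  }
  path <- path[seq_len(n), , drop = FALSE]
  crossovers <- if (length(crossRows)) do.call(rbind, crossRows) else
    data.frame(index = numeric(0), row = numeric(0), col = numeric(0))
  list(path = path, terminating = terminating, crossovers = crossovers)
}

.makeSegment <- function(id, tr) {
  new("VesselSegment", id = id, path = tr$path,
      terminatingLandmark = tr$terminating,
      lengthPx = nrow(tr$path), arcLength = .pathArcLength(tr$path),
      avgWidth = NA_real_, crossovers = tr$crossovers)
}

#' Trace one vessel segment by region growing
#'
#' Walks 8-connected centerline pixels from `start`, flagging visited
#' pixels, until the next pixel belongs to a landmark boundary zone (the
#' segment then ends at that bifurcation/branch landmark), a crossover is
#' continued through (the two parts form one segment, the crossover
#' recorded on the path), no unvisited neighbour remains (terminal tip), or
#' the iteration budget is exhausted. Ambiguous steps take the neighbour
#' minimizing the direction change.
#'
#' @param frag a [FragmentedCenterline-class].
#' @param start `(row, col)` of an untraced non-boundary centerline pixel.
#' @param incomingDir optional unit `(drow, dcol)` giving the direction of
#'   arrival at `start` (used to disambiguate the first step).
#' @param visited optional shared visited environment from a previous trace
#'   (created by the tree builder); pass `NULL` for a standalone trace.
#' @param maxIterations iteration budget; defaults to 10 x image width.
#' @param segmentId id for the returned segment.
#' @return A [VesselSegment-class] (width unmeasured).
#' @export
traceSegment <- function(frag, start, incomingDir = NULL, visited = NULL,
                         maxIterations = NULL, segmentId = "S") {
  stopifnot(is(frag, "FragmentedCenterline"))
  start <- as.numeric(start)
  if (!.inBounds(start, dim(frag@raster)) ||
      frag@raster[start[1], start[2]] != 1L)
    stop(sprintf("start pixel (%d, %d) is not on the centerline raster",
                 start[1], start[2]))
  if (is.environment(visited)) vis <- visited else vis <- .newVisited(frag)
  vis$v[start[1], start[2]] <- TRUE
  tr <- .traceCore(frag, vis, rbind(start), incomingDir,
                   maxIterations = maxIterations)
  .makeSegment(segmentId, tr)
}

#' Find vessel root pixels on the optic-disc boundary
#'
#' Scans the annulus `[radius, radius + 3]` around the optic-disc center
#' for centerline pixels, clusters 8-connected hits to a single
#' representative (the lexicographic minimum `(row, col)`), and returns the
#' representatives sorted by angle from the optic-disc center, clockwise
#' starting at 12 o'clock.
#'
#' @param scene a [VascularScene-class].
#' @return n x 2 matrix of `(row, col)` root pixels (0 rows when no vessel
#'   crosses the annulus).
#' @export
findVesselRoots <- function(scene) {
  stopifnot(is(scene, "VascularScene"))
  m <- scene@centerline
  ctr <- scene@od$center
  r0 <- scene@od$radius
  on <- which(m == 1L, arr.ind = TRUE)
  if (nrow(on) == 0) return(matrix(numeric(0), 0, 2))
  d <- sqrt((on[, 1] - ctr[1])^2 + (on[, 2] - ctr[2])^2)
  hits <- on[d >= r0 & d <= r0 + 3, , drop = FALSE]
  if (nrow(hits) == 0) return(matrix(numeric(0), 0, 2))
  # cluster 8-connected hits
  lab <- integer(nrow(hits))
  nextLab <- 0L
  for (i in seq_len(nrow(hits))) {
    if (lab[i] != 0L) next
    nextLab <- nextLab + 1L
    stack <- i
    lab[i] <- nextLab
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      adj <- which(lab == 0L &
                   abs(hits[, 1] - hits[j, 1]) <= 1 &
                   abs(hits[, 2] - hits[j, 2]) <= 1)
      lab[adj] <- nextLab
      stack <- c(stack, adj)
    }
  }
  reps <- t(vapply(seq_len(nextLab), function(l) {
    px <- hits[lab == l, , drop = FALSE]
    px[order(px[, 1], px[, 2])[1], ]
  }, numeric(2)))
  ang <- apply(reps, 1, .clockAngle, center = ctr)
  reps <- reps[order(ang), , drop = FALSE]
  dimnames(reps) <- NULL
  reps
}
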