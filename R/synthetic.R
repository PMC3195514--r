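# Seeded synthetic vascular scenes with exact ground truth.
#
# Each vessel occupies its own angular sector around the optic disc and is a
# full binary tree of gently curved segments: at every split the wider daughter
# stays close to the parent direction and the narrower daughter (an extra
# x0.87 width factor, so the "smallest daughter" is always unique) deviates by
# the sampled branching angle. Crossings are short independent strokes that
# intersect one tree segment at >= ~30 degrees, standing in for a segment of
# a vessel not rooted in the modelled field of view.

#' Specification of a synthetic vascular scene
#'
#' @param imageSize side of the square image in pixels.
#' @param odCenter optic-disc center `(row, col)`; defaults to the image
#'   center (which is also the rotation center of [rotateScene()]).
#' @param odRadius optic-disc radius in pixels; defaults to ~8.6% of the
#'   image side (88 px at the default 1024).
#' @param nVessels number of vessels rooted on the optic-disc boundary.
#' @param maxDepth levels of branching events per vessel (depth 2 gives
#'   1 + 2 + 4 = 7 segments when nothing terminates early).
#' @param rootWidth width of a root segment in pixels.
#' @param widthDecay multiplicative width decay per level, in (0, 1]; the
#'   narrower daughter receives an extra factor 0.87 (so the
#'   smallest daughter at a junction is always unique).
#' @param branchAngleRange range (radians) of the acute deviation of the
#'   narrow daughter from the parent direction; must stay below pi/2.
#' @param segmentLengthRange range of segment lengths in pixels; defaults
#'   to ~10-13% of the image side (100-132 px at the default 1024).
#' @param crossoverProb per-vessel probability of one crossing stroke over
#'   the vessel's root segment.
#' @param bifurcationProb probability that a split is labelled a
#'   bifurcation (otherwise a branch).
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return A validated spec list (class `"vt_scene_spec"`).
#' @export
sceneSpec <- function(imageSize = 1024, odCenter = NULL, odRadius = NULL,
                      nVessels = 5, maxDepth = 2, rootWidth = 8,
                      widthDecay = 0.9, branchAngleRange = c(0.45, 1.1),
                      segmentLengthRange = NULL,
                      crossoverProb = 0.5, bifurcationProb = 0.5,
                      seed = 1L) {
  if (is.null(odCenter)) odCenter <- c((imageSize + 1) / 2, (imageSize + 1) / 2)
  if (is.null(odRadius)) odRadius <- round(0.086 * imageSize)
  if (is.null(segmentLengthRange))
    segmentLengthRange <- round(c(0.098, 0.129) * imageSize)
  spec <- list(imageSize = as.integer(imageSize), odCenter = odCenter,
               odRadius = odRadius, nVessels = as.integer(nVessels),
               maxDepth = as.integer(maxDepth), rootWidth = rootWidth,
               widthDecay = widthDecay, branchAngleRange = branchAngleRange,
               segmentLengthRange = segmentLengthRange,
               crossoverProb = crossoverProb,
               bifurcationProb = bifurcationProb, seed = as.integer(seed))
  class(spec) <- "vt_scene_spec"
  .validateSceneSpec(spec)
  spec
}

.validateSceneSpec <- function(spec) {
  if (spec$nVessels < 1) stop("nVessels must be >= 1")
  if (spec$maxDepth < 0) stop("maxDepth must be >= 0")
  if (spec$widthDecay <= 0 || spec$widthDecay > 1)
    stop("widthDecay must be in (0, 1]")
  if (spec$crossoverProb < 0 || spec$crossoverProb > 1)
    stop("crossoverProb must be in [0, 1]")
  if (any(spec$branchAngleRange >= pi / 2) || any(spec$branchAngleRange <= 0))
    stop("branchAngleRange must be strictly inside (0, pi/2) (acute)")
  reach <- spec$odRadius +
    (spec$maxDepth + 1) * max(spec$segmentLengthRange) +
    spec$rootWidth / 2 + 4
  if (reach > spec$imageSize / 2)
    stop(sprintf(paste0("geometry does not fit: od_radius + max cumulative ",
                        "segment length (%.0f px) exceeds the image half-size ",
                        "(%.0f px)"), reach, spec$imageSize / 2))
  if (pi / spec$nVessels - 0.15 < 0.18)
    stop("too many vessels for non-overlapping sectors at this image size")
  invisible(TRUE)
}

# Adjust (direction, length) so the segment endpoint stays inside the
# subtree's angular wedge (angles relative to the vessel's sector center),
# inside the rotation-safe radius, and moves outward from the optic disc.
.fitSegment <- function(start, dirAng, len, thetaV, wedge, width, odCenter,
                        imgCenter, rmax, segId) {
  rel <- function(x) (x - thetaV + pi) %% (2 * pi) - pi
  rs <- .clockAngle(start, odCenter)
  len0 <- len
  for (i in 1:80) {
    end <- start + len * .clockDir(dirAng)
    rEnd <- sqrt(sum((end - odCenter)^2))
    marg <- (width / 2 + 1.5) / max(rEnd, 60)
    a <- rel(.clockAngle(end, odCenter))
    okWedge <- a >= wedge[1] + marg && a <= wedge[2] - marg
    okR <- sqrt(sum((end - imgCenter)^2)) <= rmax
    okProg <- (rEnd - sqrt(sum((start - odCenter)^2))) >= 0.18 * len
    if (okWedge && okR && okProg)
      return(list(dir = dirAng, len = len, end = end))
    if (!okR && len > 32) { len <- len * 0.92; next }
    if (a < wedge[1] + marg) {
      dirAng <- dirAng + 0.07          # steer the endpoint clockwise
    } else if (a > wedge[2] - marg) {
      dirAng <- dirAng - 0.07
    } else if (!okProg) {
      d <- (rs - dirAng + pi) %% (2 * pi) - pi
      dirAng <- dirAng + 0.07 * sign(d)  # back toward radially outward
    } else {
      len <- len * 0.92
    }
    # cap obliqueness so the segment keeps moving outward; if the wedge
    # is still out of reach at the cap, a longer segment must bridge it
    off <- (dirAng - rs + pi) %% (2 * pi) - pi
    if (abs(off) > 1.25) {
      dirAng <- rs + 1.25 * sign(off)
      if (len < 1.4 * len0) len <- len * 1.05
    }
  }
  stop(sprintf(paste0("generation error: cannot fit segment %s inside the ",
                      "image bounds (wedge [%.3f, %.3f], start angle %.3f)"),
               segId, wedge[1], wedge[2],
               rel(.clockAngle(start, odCenter))))
}

# Plan one vessel: a binary tree of curved segments. Each subtree owns a
# disjoint angular wedge of the vessel's sector (split at the junction's
# angular position), which guarantees that sibling and cousin branches
# never intersect.
.planVessel <- function(vid, thetaV, spec, imgCenter, rmax, usable) {
  counter <- new.env()
  counter$n <- 0L
  lenR <- spec$segmentLengthRange
  bar <- spec$branchAngleRange
  rel <- function(x) (x - thetaV + pi) %% (2 * pi) - pi
  plan <- function(start, dirAng, width, level, wedge, bendSign = NULL) {
    if (is.null(bendSign)) bendSign <- sample(c(-1, 1), 1)
    counter$n <- counter$n + 1L
    sid <- sprintf("V%d.S%d", vid, counter$n)
    len <- stats::runif(1, lenR[1], lenR[2])
    fit <- .fitSegment(start, dirAng, len, thetaV, wedge, width,
                       spec$odCenter, imgCenter, rmax, sid)
    # gentle curvature: bulge toward `bendSign` (perpendicular to the chord)
    chordAng <- .clockAngle(fit$end, start)
    sag <- stats::runif(1, 2, 3.5)
    ctrl <- (start + fit$end) / 2 +
      sag * .clockDir(chordAng + bendSign * pi / 2)
    rec <- list(id = sid, start = start, end = fit$end, dir = fit$dir,
                ctrl = ctrl, len = fit$len, width = width, level = level,
                wiggle = list(a = stats::runif(1, 0.55, 0.7),
                              p = stats::runif(1, 26, 36),
                              ph = stats::runif(1, 0, 2 * pi)),
                landmarkClass = NA_character_, landmarkPixel = NULL,
                crossover = NULL, children = list())
    if (level < spec$maxDepth) {
      rec$landmarkClass <- if (stats::runif(1) < spec$bifurcationProb)
        "bifurcation" else "branch"
      # split the wedge at the junction's angular position (kept away from
      # the wedge edges so neither daughter gets a sliver)
      rad <- .clockAngle(fit$end, spec$odCenter)
      m <- rel(rad)
      span <- wedge[2] - wedge[1]
      m <- min(max(m, wedge[1] + 0.38 * span), wedge[2] - 0.38 * span)
      side <- sample(c(-1, 1), 1)
      phi <- stats::runif(1, bar[1], bar[2])
      psi <- stats::runif(1, 0.35, 0.5)
      buf <- 0.06 * span
      wedgeWide <- if (side > 0) c(wedge[1], m - buf) else c(m + buf, wedge[2])
      wedgeNarrow <- if (side > 0) c(m + buf, wedge[2]) else c(wedge[1], m - buf)
      # each daughter bends away from its sibling near the junction
      wide <- plan(fit$end, rad - side * psi,
                   width * spec$widthDecay, level + 1L, wedgeWide,
                   bendSign = -side)
      narrow <- plan(fit$end, rad + side * max(phi - psi, 0.5),
                     width * spec$widthDecay * 0.87, level + 1L,
                     wedgeNarrow, bendSign = side)
      sep <- .angDiff(.dirOf(wide), .dirOf(narrow))
      if (sep < 0.4)
        .vtMessage(sid, ": daughters separated by only ",
                   round(sep, 2), " rad")
      rec$children <- list(wide, narrow)
    }
    rec
  }
  dir0 <- thetaV + stats::runif(1, -0.05, 0.05)
  start0 <- spec$odCenter + spec$odRadius * .clockDir(thetaV)
  plan(start0, dir0, spec$rootWidth, 0L, c(-usable, usable))
}

.dirOf <- function(rec) rec$dir

.countPlanned <- function(rec) {
  1L + sum(vapply(rec$children, .countPlanned, integer(1)))
}

.planStroke <- function(rootRec, vid, spec, imgCenter, rmax) {
  u <- stats::runif(1, 0.4, 0.6)
  pts <- .segmentPoints(rootRec)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  k <- which.min(abs(arc - u * arc[length(arc)]))
  k <- min(max(k, 2L), nrow(pts) - 1L)
  q <- pts[k, ]
  tangent <- .clockAngle(pts[k + 1L, ], pts[k - 1L, ])
  sdir <- tangent + sample(c(-1, 1), 1) * stats::runif(1, 0.75, 1.05)
  half <- 11
  p0 <- q - half * .clockDir(sdir)
  p1 <- q + half * .clockDir(sdir)
  okRadius <- function(p)
    sqrt(sum((p - spec$odCenter)^2)) > spec$odRadius + 5 &&
    sqrt(sum((p - imgCenter)^2)) <= rmax
  if (!okRadius(p0) || !okRadius(p1)) return(NULL)
  list(p0 = p0, p1 = p1, width = 0.6 * spec$rootWidth, point = q,
       frac = u, vesselId = sprintf("V%d", vid), segmentId = rootRec$id)
}

.collectSegments <- function(rec, vid, acc = list()) {
  acc[[length(acc) + 1L]] <- c(rec[c("id", "start", "end", "width",
                                     "level", "landmarkClass")],
                               list(vesselId = vid))
  for (ch in rec$children) acc <- .collectSegments(ch, vid, acc)
  acc
}

# Rasterize vessels + strokes; snap landmark pixels; returns scene rasters,
# the landmark table and the truth records annotated with landmark pixels.
.renderTruth <- function(vessels, strokes, spec) {
  size <- spec$imageSize
  cl <- matrix(0L, size, size)
  mask <- matrix(0L, size, size)
  segPx <- list()
  annotate <- function(rec) {
    pts <- .segmentPoints(rec)
    px <- .curveChain(pts)
    cl[px] <<- 1L
    mask <<- .bandMask(mask, pts, max(rec$width / 2, 1.25))
    segPx[[rec$id]] <<- px
    if (!is.na(rec$landmarkClass))
      rec$landmarkPixel <- round(rec$end)
    rec$children <- lapply(rec$children, annotate)
    rec
  }
  vessels <- lapply(vessels, function(v) {
    v$root <- annotate(v$root)
    v
  })
  for (s in strokes) {
    pts <- .bezierPoints(s$p0, (s$p0 + s$p1) / 2, s$p1)
    cl[.curveChain(pts)] <- 1L
    mask <- .bandMask(mask, pts, max(s$width / 2, 1.25))
  }
  # crossover landmark = target-segment pixel nearest the true intersection
  strokes <- lapply(strokes, function(s) {
    px <- segPx[[s$segmentId]]
    d2 <- (px[, 1] - s$point[1])^2 + (px[, 2] - s$point[2])^2
    s$pixel <- px[which.min(d2), ]
    s
  })
  attachCross <- function(rec, s) {
    if (rec$id == s$segmentId)
      rec$crossover <- list(point = s$point, pixel = s$pixel, frac = s$frac)
    rec$children <- lapply(rec$children, attachCross, s = s)
    rec
  }
  for (s in strokes)
    vessels <- lapply(vessels, function(v) {
      if (v$id == s$vesselId) v$root <- attachCross(v$root, s)
      v
    })
  lmRows <- list()
  harvest <- function(rec, vid) {
    if (!is.na(rec$landmarkClass))
      lmRows[[length(lmRows) + 1L]] <<- data.frame(
        row = rec$landmarkPixel[1], col = rec$landmarkPixel[2],
        class = rec$landmarkClass, vesselId = vid, segmentId = rec$id,
        stringsAsFactors = FALSE)
    if (!is.null(rec$crossover))
      lmRows[[length(lmRows) + 1L]] <<- data.frame(
        row = rec$crossover$pixel[1], col = rec$crossover$pixel[2],
        class = "crossover", vesselId = vid, segmentId = rec$id,
        stringsAsFactors = FALSE)
    for (ch in rec$children) harvest(ch, vid)
  }
  for (v in vessels) harvest(v$root, v$id)
  lm <- if (length(lmRows)) do.call(rbind, lmRows) else
    data.frame(row = numeric(0), col = numeric(0), class = character(0),
               vesselId = character(0), segmentId = character(0))
  list(centerline = cl, mask = mask, landmarks = lm, vessels = vessels,
       strokes = strokes)
}

#' Generate a synthetic vascular scene with ground truth
#'
#' Draws `nVessels` binary vessel trees radiating from the optic-disc
#' boundary, renders the 1-pixel centerline raster and the width-dilated
#' vessel mask, and returns both the [VascularScene-class] and the exact
#' [GroundTruthTopology-class]. The same spec (including its seed) always
#' produces bit-identical output.
#'
#' @param spec a [sceneSpec()].
#' @return list with elements `scene` and `truth`.
#' @examples
#' sc <- generateScene(sceneSpec(nVessels = 3, seed = 7))
#' sc$scene
#' @export
generateScene <- function(spec) {
  stopifnot(inherits(spec, "vt_scene_spec"))
  .validateSceneSpec(spec)
  withr::with_seed(spec$seed, .generateSceneImpl(spec))
}

.generateSceneImpl <- function(spec) {
  size <- spec$imageSize
  imgCenter <- c((size + 1) / 2, (size + 1) / 2)
  rmax <- size / 2 - spec$rootWidth / 2 - 3
  nV <- spec$nVessels
  halfSector <- pi / nV
  usable <- halfSector - 0.15
  offset <- stats::runif(1, 0, 2 * pi)
  thetas <- (offset + (seq_len(nV) - 1) * 2 * pi / nV +
             stats::runif(nV, -0.05, 0.05) * halfSector) %% (2 * pi)
  vessels <- list()
  strokes <- list()
  for (v in seq_len(nV)) {
    root <- .planVessel(v, thetas[v], spec, imgCenter, rmax, usable)
    vessels[[v]] <- list(id = sprintf("V%d", v), theta = thetas[v],
                         root = root)
    if (stats::runif(1) < spec$crossoverProb) {
      s <- .planStroke(root, v, spec, imgCenter, rmax)
      if (!is.null(s)) strokes[[length(strokes) + 1L]] <- s
    }
  }
  rend <- .renderTruth(vessels, strokes, spec)
  scene <- VascularScene(rend$centerline, rend$mask,
                         rend$landmarks[, c("row", "col", "class")],
                         od = list(center = spec$odCenter,
                                   radius = spec$odRadius))
  truth <- new("GroundTruthTopology", vessels = rend$vessels,
               strokes = rend$strokes, landmarks = rend$landmarks,
               spec = unclass(spec))
  list(scene = scene, truth = truth)
}

#' Rotate a synthetic scene and its ground truth
#'
#' Rotates the ground-truth geometry analytically about the image center and
#' re-rasterizes both rasters with the generator's renderer; landmark
#' coordinates and the optic-disc center are rotated analytically and rounded
#' to the nearest pixel. Tree topology and landmark classes are unchanged:
#' only coordinates (and hence the pixel discretization) move.
#'
#' @param scene the [VascularScene-class] the truth was rendered to.
#' @param truth the matching [GroundTruthTopology-class].
#' @param angle rotation angle in degrees, `|angle| <= 45`.
#' @return list with elements `scene` and `truth`.
#' @export
rotateScene <- function(scene, truth, angle) {
  stopifnot(is(scene, "VascularScene"), is(truth, "GroundTruthTopology"))
  if (abs(angle) > 45) stop("|angle| must be <= 45 degrees")
  spec <- truth@spec
  size <- spec$imageSize
  ctr <- c((size + 1) / 2, (size + 1) / 2)
  rot <- function(p) as.numeric(.rotatePoints(rbind(p), ctr, angle))
  margin <- spec$rootWidth / 2 + 2
  rotRec <- function(rec, vid) {
    rec$start <- rot(rec$start)
    rec$end <- rot(rec$end)
    rec$ctrl <- rot(rec$ctrl)
    for (p in list(rec$start, rec$end))
      if (p[1] < margin || p[1] > size - margin ||
          p[2] < margin || p[2] > size - margin)
        stop(sprintf("rotation by %.1f degrees pushes vessel %s outside the image",
                     angle, vid))
    rec$dir <- .clockAngle(rec$end, rec$start)
    if (!is.null(rec$crossover)) {
      rec$crossover$point <- rot(rec$crossover$point)
      rec$crossover <- rec$crossover[c("point", "frac")]
    }
    rec$landmarkPixel <- NULL
    rec$children <- lapply(rec$children, rotRec, vid = vid)
    rec
  }
  vessels <- lapply(truth@vessels, function(v) {
    v$root <- rotRec(v$root, v$id)
    v
  })
  strokes <- lapply(truth@strokes, function(s) {
    s$p0 <- rot(s$p0); s$p1 <- rot(s$p1); s$point <- rot(s$point)
    s$pixel <- NULL
    s
  })
  spec2 <- spec
  spec2$odCenter <- round(rot(spec$odCenter))
  rend <- .renderTruth(vessels, strokes, spec2)
  sceneR <- VascularScene(rend$centerline, rend$mask,
                          rend$landmarks[, c("row", "col", "class")],
                          od = list(center = spec2$odCenter,
                                    radius = spec$odRadius))
  truthR <- new("GroundTruthTopology", vessels = rend$vessels,
                strokes = rend$strokes, landmarks = rend$landmarks,
                spec = spec2)
  list(scene = sceneR, truth = truthR)
}
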