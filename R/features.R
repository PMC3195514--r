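# The five invariant features of a vessel segment:
#   L/W ratio, bifurcation/branch code, crossover flag, relative crossover
#   position, acute angle between the widest and narrowest vessel at the
#   terminating landmark.
# All five are invariant to translation, rotation and uniform scaling up
# to pixel discretization.

# Gaussian smoothing (separable, sigma 1, +-3 px) of the binary mask.
# Profile measurement interpolates the 0.5 level of this field: for a hard
# binary edge the bilinear 0.5-crossing quantizes to half-pixel steps, while
# the smoothed field recovers the sub-pixel boundary position from the
# jagged edge pattern.
.smoothMask <- function(mask) {
  k <- stats::dnorm(-3:3, sd = 1)
  k <- k / sum(k)
  pad <- 3L
  conv1 <- function(x) {
    x2 <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
    stats::filter(x2, k, sides = 2)[(pad + 1):(pad + length(x))]
  }
  out <- apply(mask, 2, conv1)
  t(apply(out, 1, conv1))
}

# Half-width of the mask band on one side of each path point: first 0.5
# crossing of the bilinearly interpolated mask along the perpendicular ray,
# refined by linear interpolation between samples.
.profileHalf <- function(mask, pr, pc, nr_, nc_, step, tmax) {
  tgrid <- seq(step, tmax, by = step)
  v <- .bilinearSample(mask,
                       rep(pr, length(tgrid)) +
                         rep(tgrid, each = length(pr)) * rep(nr_, length(tgrid)),
                       rep(pc, length(tgrid)) +
                         rep(tgrid, each = length(pc)) * rep(nc_, length(tgrid)))
  v <- matrix(v, nrow = length(pr))
  v0 <- .bilinearSample(mask, pr, pc)
  half <- numeric(length(pr))
  for (i in seq_along(pr)) {
    idx <- which(v[i, ] < 0.5)
    if (!length(idx)) { half[i] <- tmax; next }
    j <- idx[1]
    tPrev <- if (j == 1) 0 else tgrid[j - 1]
    vPrev <- if (j == 1) v0[i] else v[i, j - 1]
    half[i] <- if (vPrev > 0.5)
      tPrev + step * (vPrev - 0.5) / (vPrev - v[i, j]) else tPrev
  }
  half
}

# Indices of path points whose profiles are measured: segment ends are
# trimmed because junction ink (the union with the parent, sibling and
# daughter bands) widens every profile over a stretch of roughly
# (width_parent + width_self) / (2 sin(branch angle)) pixels.
.profileIdx <- function(n, trim = 11L) {
  trim <- max(4L, min(trim, (n - 10L) %/% 2L))
  if (n >= 2L * trim + 4L) seq(trim, n - trim + 1L) else seq_len(n)
}

# Per-point perpendicular profile widths along a path.
.profileWidths <- function(path, mask, step = 0.25, tmax = 9) {
  n <- nrow(path)
  sr <- .movingAvg(path[, 1], 7)
  sc <- .movingAvg(path[, 2], 7)
  idx <- .profileIdx(n)
  h <- min(3L, n - 1L)
  i0 <- pmax(1L, idx - h); i1 <- pmin(n, idx + h)
  dr <- sr[i1] - sr[i0]; dc <- sc[i1] - sc[i0]
  nv <- sqrt(dr^2 + dc^2)
  nv[nv == 0] <- 1
  nr_ <- -dc / nv; nc_ <- dr / nv
  w <- .profileHalf(mask, sr[idx], sc[idx], nr_, nc_, step, tmax) +
    .profileHalf(mask, sr[idx], sc[idx], -nr_, -nc_, step, tmax)
  # sub-pixel phase speed of the band's quantization axis: profiles where
  # the tangent is axis-aligned sit at a locked phase and carry no
  # independent width information
  attr(w, "phaseWeight") <- pmin(abs(dr), abs(dc)) / nv + 0.02
  w
}

.avgWidthFromMask <- function(path, mask, smoothed = NULL) {
  if (nrow(path) == 0) return(NA_real_)
  inMask <- mask[path]
  if (any(inMask == 0)) {
    bad <- path[which(inMask == 0)[1], ]
    stop(sprintf("path pixel (%d, %d) lies outside the vessel mask",
                 bad[1], bad[2]))
  }
  if (is.null(smoothed)) smoothed <- .smoothMask(mask)
  w <- .profileWidths(path, smoothed)
  pw <- attr(w, "phaseWeight")
  # an inked path pixel implies at least one pixel of band: guards the 0.5
  # level for structures so thin that smoothing pulls their peak below it
  w <- pmax(w, 1)
  # junction and crossing ink only ever *widens* a profile, so clean
  # profiles form a tight lower cluster (sub-pixel spread) and the
  # contamination sits >1 px above it. An absolute window above a low
  # quantile keeps the whole clean cluster while dropping the
  # contaminated stretch; the phase-speed weights then average the
  # remaining profiles uniformly over sub-pixel phase.
  q <- stats::quantile(w, 0.35, names = FALSE)
  keep <- w <= q + 1.2
  sum(w[keep] * pw[keep]) / sum(pw[keep])
}

#' Average vessel width along a segment
#'
#' Width is measured by perpendicular profiles: a lightly Gaussian-smoothed
#' copy of the binary mask is sampled with bilinear interpolation along the
#' ray perpendicular to the local centerline direction at each path point,
#' and the per-point width is the distance between the 0.5-level boundary
#' crossings on the two sides. The segment width averages the per-point
#' widths after trimming the junction-contaminated segment ends, dropping
#' upward outliers (junction or crossing ink only ever widens a profile),
#' and weighting by the sub-pixel phase speed of the band, which keeps the
#' estimate stable under rotation of the raster.
#'
#' @param segment a [VesselSegment-class] (or an n x 2 path matrix).
#' @param mask binary vessel mask.
#' @return Average width in pixels.
#' @export
segmentAvgWidth <- function(segment, mask) {
  path <- if (is(segment, "VesselSegment")) segment@path else segment
  storage.mode(mask) <- "double"
  .avgWidthFromMask(path, mask)
}

#' Length-to-width ratio of a segment
#'
#' The segment's arc length divided by its average width; dimensionless and
#' scale-invariant.
#'
#' @param segment a [VesselSegment-class] with `avgWidth` measured.
#' @return L/W ratio.
#' @export
lwRatio <- function(segment) {
  stopifnot(is(segment, "VesselSegment"))
  w <- segment@avgWidth
  if (is.na(w)) stop("segment width not measured")
  if (w <= 0) stop("segment width must be > 0")
  segment@arcLength / w
}

#' Encode a terminating landmark as the bifurcation/branch code
#'
#' @param landmark a landmark list or one-row data.frame with a `class`
#'   field; must be a bifurcation or a branch.
#' @return 1 for a bifurcation, 0 for a branch.
#' @export
encodeLandmark <- function(landmark) {
  klass <- if (is.list(landmark) && !is.null(landmark$class))
    landmark$class else as.character(landmark)
  if (klass == "bifurcation") return(1)
  if (klass == "branch") return(0)
  stop(sprintf("landmark class '%s' does not terminate a segment %s", klass,
               "(crossovers are passed through, not terminated at)"))
}

#' Crossover flag and relative position of a segment
#'
#' Flag is 1 iff any crossover lies on the path; the position is the ratio
#' of the (first) crossover's path index to the segment's pixel count, and
#' 0 when there is no crossover.
#'
#' @param segment a traced [VesselSegment-class].
#' @return numeric `(crossover_flag, crossover_pos)`.
#' @export
crossoverFeatures <- function(segment) {
  stopifnot(is(segment, "VesselSegment"))
  cr <- segment@crossovers
  if (nrow(cr) == 0) return(c(crossover_flag = 0, crossover_pos = 0))
  idx <- min(cr$index)
  c(crossover_flag = 1, crossover_pos = idx / segment@lengthPx)
}

.endDirection <- function(path, atEnd, window = 36) {
  n <- nrow(path)
  k <- min(window, n)
  pts <- if (atEnd) path[(n - k + 1):n, , drop = FALSE]
         else path[1:k, , drop = FALSE]
  if (k < 3) {
    .vtMessage("segment shorter than 3 px near landmark; endpoint fallback")
    v <- path[n, ] - path[1, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(c(1, 0))
    return(v / nv)
  }
  .fitDirection(pts)
}

#' Acute angle at a splitting landmark
#'
#' The parent and its daughters are sorted by average width; the angle is
#' the acute angle between the centerline directions of the widest and the
#' narrowest of them, each direction estimated by a least-squares line fit
#' over the path pixels nearest the landmark.
#'
#' @param parent the parent [VesselSegment-class] (its path ends at the
#'   landmark).
#' @param daughters list of daughter segments (paths start at the landmark).
#' @param window number of path pixels used for each direction fit.
#' @return Acute angle in radians, in `[0, pi/2]`.
#' @export
acuteAngle <- function(parent, daughters, window = 36) {
  stopifnot(is(parent, "VesselSegment"), length(daughters) >= 1)
  segs <- c(list(parent), daughters)
  atEnd <- c(TRUE, rep(FALSE, length(daughters)))
  widths <- vapply(segs, function(s) s@avgWidth, numeric(1))
  if (any(is.na(widths))) stop("segment widths not measured")
  iw <- which.max(widths)
  inar <- which.min(widths)
  if (iw == inar) inar <- which(widths == min(widths))[length(widths)]
  u <- .endDirection(segs[[iw]]@path, atEnd[iw], window)
  v <- .endDirection(segs[[inar]]@path, atEnd[inar], window)
  .acuteBetween(u, v)
}

#' Assemble the five-feature vector of a node
#'
#' Order: L/W ratio, bifurcation/branch code, crossover flag, crossover
#' position, acute angle. Terminal segments (no daughters) get code 0 and
#' angle 0.
#'
#' @param node a [SegmentNode-class] with traced segment and measured width.
#' @param daughters list of daughter segments (possibly empty).
#' @param window direction-fit window for [acuteAngle()].
#' @return Named numeric of length 5.
#' @export
buildFeatureVector <- function(node, daughters = list(), window = 36) {
  stopifnot(is(node, "SegmentNode"))
  seg <- node@segment
  lw <- lwRatio(seg)
  term <- seg@terminatingLandmark
  hasSplit <- !is.null(term) && term$class %in% c("bifurcation", "branch") &&
    length(daughters) > 0
  bibr <- if (hasSplit) encodeLandmark(term) else 0
  cf <- crossoverFeatures(seg)
  ang <- if (hasSplit) acuteAngle(seg, daughters, window) else 0
  stats::setNames(c(lw, bibr, cf[["crossover_flag"]],
                    cf[["crossover_pos"]], ang), .FEATURE_NAMES)
}

#' Compute features for every node of a model
#'
#' @param model a [TreeModel-class] with traced segments.
#' @param scene the scene the model was built from (for widths, if any are
#'   missing).
#' @param window direction-fit window for [acuteAngle()].
#' @return The finalized model.
#' @export
computeFeatures <- function(model, scene = NULL, window = 36) {
  stopifnot(is(model, "TreeModel"))
  maskd <- NULL
  sm <- NULL
  fill <- function(node) {
    if (is.null(node)) return(NULL)
    node@left <- fill(node@left)
    node@right <- fill(node@right)
    if (is.na(node@segment@avgWidth)) {
      if (is.null(scene)) stop("scene needed to measure segment widths")
      if (is.null(sm)) {
        if (is.null(scene)) stop("scene needed to measure segment widths")
        maskd <<- scene@mask
        storage.mode(maskd) <<- "double"
        sm <<- .smoothMask(maskd)
      }
      node@segment@avgWidth <- .avgWidthFromMask(node@segment@path, maskd, sm)
    }
    kids <- Filter(Negate(is.null), list(node@left, node@right))
    node@features <- buildFeatureVector(node,
                                        lapply(kids, function(k) k@segment),
                                        window)
    node
  }
  model@trees <- lapply(model@trees, function(t) {
    t@root <- fill(t@root)
    t
  })
  model@finalized <- TRUE
  model
}

#' Normalize a model's continuous features
#'
#' Divides every acute angle by `pi/2` and every L/W ratio by the
#' model-wide maximum (or by supplied parameters, so two models can share a
#' scale). The parameters are stored on the model and the matcher undoes
#' them before comparing, so matching results are identical whether or not
#' models are normalized. Off by default in the pipeline.
#'
#' @param model a finalized [TreeModel-class].
#' @param params optional list (`lw_max`, `angle_scale`) to reuse.
#' @return list with elements `model` and `params`.
#' @export
normalizeModel <- function(model, params = NULL) {
  stopifnot(is(model, "TreeModel"))
  if (!model@finalized) stop("model must be finalized before normalizing")
  if (!is.null(model@normalization))
    return(list(model = model, params = model@normalization))
  lws <- numeric(0)
  walk <- function(node) {
    if (is.null(node)) return(invisible())
    lws <<- c(lws, node@features[["lw_ratio"]])
    walk(node@left); walk(node@right)
  }
  for (t in model@trees) walk(t@root)
  if (is.null(params)) {
    params <- list(lw_max = if (length(lws)) max(lws) else 1,
                   angle_scale = pi / 2)
  }
  scale <- function(node) {
    if (is.null(node)) return(NULL)
    node@features[["lw_ratio"]] <- node@features[["lw_ratio"]] / params$lw_max
    node@features[["acute_angle"]] <-
      node@features[["acute_angle"]] / params$angle_scale
    node@left <- scale(node@left)
    node@right <- scale(node@right)
    node
  }
  model@trees <- lapply(model@trees, function(t) {
    t@root <- scale(t@root)
    t
  })
  model@normalization <- params
  list(model = model, params = params)
}

# Undo normalization on a raw feature vector (used by the matcher).
.denormalize <- function(feats, params) {
  if (is.null(params) || is.null(feats)) return(feats)
  feats[["lw_ratio"]] <- feats[["lw_ratio"]] * params$lw_max
  feats[["acute_angle"]] <- feats[["acute_angle"]] * params$angle_scale
  feats
}
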