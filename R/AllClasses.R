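#' @import methods
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

.LANDMARK_CLASSES <- c("bifurcation", "branch", "crossover")

.FEATURE_NAMES <- c("lw_ratio", "bibr_code", "crossover_flag",
                    "crossover_pos", "acute_angle")

#' VascularScene: rasters, landmarks and optic-disc geometry
#'
#' The input world of the tree-model pipeline: a binary vessel-centerline
#' raster (1-pixel-wide skeleton), a binary vessel mask (the filled vessels,
#' from which widths are measured by distance transform), a landmark table,
#' and the optic-disc circle from which vessels originate. All coordinates
#' are 1-based `(row, col)` in R; on disk they are serialized 0-based.
#'
#' @slot centerline integer matrix of 0/1, the vessel skeleton.
#' @slot mask integer matrix of 0/1, same dimensions, the filled vessels.
#' @slot landmarks `data.frame` with columns `row`, `col`, `class`
#'   (one of `"bifurcation"`, `"branch"`, `"crossover"`).
#' @slot od list with `center` (numeric `(row, col)`) and `radius` (pixels).
#' @export
setClass("VascularScene",
         representation(centerline = "matrix", mask = "matrix",
                        landmarks = "data.frame", od = "list"))

setValidity("VascularScene", function(object) {
  msg <- character()
  if (!identical(dim(object@centerline), dim(object@mask)))
    msg <- c(msg, sprintf("raster size mismatch: centerline is %dx%d, mask is %dx%d",
                          nrow(object@centerline), ncol(object@centerline),
                          nrow(object@mask), ncol(object@mask)))
  if (!all(object@centerline %in% c(0L, 1L)))
    msg <- c(msg, "centerline raster must be binary (0/1)")
  if (!all(object@mask %in% c(0L, 1L)))
    msg <- c(msg, "vessel mask must be binary (0/1)")
  lm <- object@landmarks
  if (!all(c("row", "col", "class") %in% names(lm)))
    msg <- c(msg, "landmarks need columns row, col, class")
  else {
    bad <- setdiff(unique(lm$class), .LANDMARK_CLASSES)
    if (length(bad))
      msg <- c(msg, sprintf("unknown landmark class: %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(.LANDMARK_CLASSES, collapse = ", ")))
    if (nrow(lm) && (any(lm$row < 1) || any(lm$row > nrow(object@centerline)) ||
                     any(lm$col < 1) || any(lm$col > ncol(object@centerline))))
      msg <- c(msg, "landmark coordinates outside raster bounds")
  }
  if (!is.numeric(object@od$center) || length(object@od$center) != 2)
    msg <- c(msg, "od$center must be a numeric (row, col) pair")
  if (!is.numeric(object@od$radius) || length(object@od$radius) != 1 ||
      object@od$radius <= 0)
    msg <- c(msg, "od$radius must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a VascularScene
#'
#' @param centerline,mask binary matrices of identical dimensions.
#' @param landmarks `data.frame` with `row`, `col`, `class` columns
#'   (1-based pixel coordinates).
#' @param od list with `center = c(row, col)` and `radius`.
#' @return A validated [VascularScene-class] object.
#' @export
VascularScene <- function(centerline, mask, landmarks, od) {
  storage.mode(centerline) <- "integer"
  storage.mode(mask) <- "integer"
  landmarks <- as.data.frame(landmarks)
  if (nrow(landmarks)) landmarks$class <- as.character(landmarks$class)
  new("VascularScene", centerline = centerline, mask = mask,
      landmarks = landmarks, od = od)
}

#' Ground-truth topology of a synthetic vascular scene
#'
#' Exact geometry and labels the generator drew: one nested segment record
#' per vessel (a full binary tree down to the requested depth), the crossing
#' strokes, and the global landmark table. Used as the oracle that tree
#' building and matching are checked against.
#'
#' @slot vessels list of vessel records; each has `id` and a nested `root`
#'   segment record (`id`, `start`, `end`, `width`, `level`,
#'   `landmarkClass`, `landmarkPixel`, `crossover`, `children`).
#' @slot strokes list of crossing strokes (`p0`, `p1`, `width`, landmark pixel).
#' @slot landmarks `data.frame` of all landmarks with `row`, `col`, `class`,
#'   `vesselId`, `segmentId`.
#' @slot spec the [sceneSpec()] list the scene was generated from.
#' @export
setClass("GroundTruthTopology",
         representation(vessels = "list", strokes = "list",
                        landmarks = "data.frame", spec = "list"))

#' A traced vessel segment
#'
#' An ordered run of centerline pixels between two landmarks (or between the
#' optic-disc boundary / a landmark and a terminal tip). Consecutive path
#' pixels are 8-adjacent.
#'
#' @slot id segment identifier.
#' @slot path n x 2 integer matrix of `(row, col)` pixels.
#' @slot terminatingLandmark list (`row`, `col`, `class`, `index`) or `NULL`
#'   for a terminal tip.
#' @slot lengthPx number of path pixels.
#' @slot arcLength smoothed Euclidean arc length in pixel units (equals
#'   `lengthPx` for axis-aligned straight runs); the `L` of the L/W ratio.
#' @slot avgWidth mean vessel width along the path (pixels); `NA` until
#'   measured against a mask.
#' @slot crossovers `data.frame` (`index`, `row`, `col`) of crossover
#'   landmarks encountered along the path, `index` being the 1-based
#'   position of the crossover pixel in `path`.
#' @export
setClass("VesselSegment",
         representation(id = "character", path = "matrix",
                        terminatingLandmark = "ListOrNULL",
                        lengthPx = "numeric", arcLength = "numeric",
                        avgWidth = "numeric", crossovers = "data.frame"))

setValidity("VesselSegment", function(object) {
  p <- object@path
  if (!is.numeric(p) || ncol(p) != 2) return("path must be an n x 2 matrix")
  if (nrow(p) >= 2) {
    d <- abs(diff(p))
    if (any(pmax(d[, 1], d[, 2]) > 1))
      return("consecutive path pixels must be 8-adjacent")
  }
  if (object@lengthPx != nrow(p))
    return("lengthPx must equal the number of path pixels")
  if (nrow(object@crossovers) &&
      (any(object@crossovers$index < 1) ||
       any(object@crossovers$index > object@lengthPx)))
    return("crossover index outside [1, lengthPx]")
  TRUE
})

#' A node of a binary vessel tree
#'
#' Holds one [VesselSegment-class] plus its five-feature vector and the
#' left/right children (each a `SegmentNode` or `NULL`). The root segment
#' has `level` 0.
#'
#' @slot segment the traced segment.
#' @slot features named numeric of length 5 (`lw_ratio`, `bibr_code`,
#'   `crossover_flag`, `crossover_pos`, `acute_angle`); `NA` until computed.
#' @slot left,right child nodes or `NULL`.
#' @slot level depth of the node (root = 0).
#' @export
setClass("SegmentNode",
         representation(segment = "VesselSegment", features = "numeric",
                        left = "ANY", right = "ANY", level = "integer"))

#' One vessel as a binary tree
#'
#' @slot vesselId identifier (discovery order, clockwise from 12 o'clock).
#' @slot root the root [SegmentNode-class].
#' @slot rootPixel `(row, col)` of the starting pixel on the optic-disc
#'   annulus.
#' @export
setClass("BinaryVesselTree",
         representation(vesselId = "character", root = "SegmentNode",
                        rootPixel = "numeric"))

#' The tree model of a retinal image
#'
#' The optic disc is the root; each vessel originating from it is one
#' [BinaryVesselTree-class], ordered clockwise from 12 o'clock.
#'
#' @slot od optic-disc list (`center`, `radius`).
#' @slot trees list of [BinaryVesselTree-class].
#' @slot normalization `NULL`, or a list (`lw_max`, `angle_scale`) when the
#'   model's features have been normalized.
#' @slot finalized `TRUE` once all features are computed.
#' @export
setClass("TreeModel",
         representation(od = "list", trees = "list",
                        normalization = "ListOrNULL", finalized = "logical"))

#' Matching configuration
#'
#' @slot relTolerance relative tolerance applied to the L/W ratio and the
#'   crossover position (default 0.05, the +-5 percent rule).
#' @slot angleTolerance absolute tolerance on the acute angle in radians
#'   (default 0.05 * pi/2; set to 0 to compare angles exactly).
#' @slot candidateDepth tree levels compared (default 2: levels 0..2,
#'   up to 7 nodes).
#' @export
setClass("MatchConfig",
         representation(relTolerance = "numeric", angleTolerance = "numeric",
                        candidateDepth = "integer"))

setValidity("MatchConfig", function(object) {
  if (object@relTolerance < 0 || object@angleTolerance < 0)
    return("tolerances must be >= 0")
  if (object@candidateDepth < 0L) return("candidateDepth must be >= 0")
  TRUE
})

#' Construct a MatchConfig
#'
#' @param relTolerance relative tolerance on L/W ratio and crossover
#'   position (dimensionless).
#' @param angleTolerance absolute acute-angle tolerance (radians).
#' @param candidateDepth number of tree levels compared (levels
#'   `0..candidateDepth`).
#' @return A [MatchConfig-class] object.
#' @export
matchConfig <- function(relTolerance = 0.05,
                        angleTolerance = 0.05 * pi / 2,
                        candidateDepth = 2L) {
  new("MatchConfig", relTolerance = relTolerance,
      angleTolerance = angleTolerance,
      candidateDepth = as.integer(candidateDepth))
}

#' Centerline raster annotated with segment boundaries
#'
#' @slot raster the binary centerline.
#' @slot boundary integer matrix; 0 for ordinary centerline pixels, the
#'   landmark index for pixels in a landmark's 8-neighbourhood boundary zone.
#' @slot landmarks the (snapped) landmark table.
#' @export
setClass("FragmentedCenterline",
         representation(raster = "matrix", boundary = "matrix",
                        landmarks = "data.frame"))

#' Vessel correspondence between two tree models
#'
#' @slot pairs `data.frame` with columns `treeA`, `treeB` (indices),
#'   `vesselA`, `vesselB` (ids) and `distance` (node count).
#' @slot unmatchedA,unmatchedB indices of trees left unmatched on each side.
#' @export
setClass("ModelCorrespondence",
         representation(pairs = "data.frame", unmatchedA = "integer",
                        unmatchedB = "integer"))
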