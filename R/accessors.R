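#' Accessors for vasctree objects
#'
#' Slot access for the S4 containers: `centerline()` and `vesselMask()`
#' return the binary rasters of a scene, `landmarks()` the landmark table of
#' a scene, fragmented centerline or ground truth, `opticDisc()` the
#' optic-disc list, `trees()` the list of binary vessel trees of a model,
#' `nodeCount()` the number of nodes of a tree or of a whole model,
#' `featureVector()` the five invariant features of a node, and
#' `segmentPath()`, `segmentLength()`, `segmentWidth()` the traced segment
#' geometry.
#'
#' @param x a vasctree object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("centerline", "VascularScene", function(x) x@centerline)

#' @rdname accessors
setMethod("vesselMask", "VascularScene", function(x) x@mask)

#' @rdname accessors
setMethod("landmarks", "VascularScene", function(x) x@landmarks)

#' @rdname accessors
setMethod("landmarks", "FragmentedCenterline", function(x) x@landmarks)

#' @rdname accessors
setMethod("landmarks", "GroundTruthTopology", function(x) x@landmarks)

#' @rdname accessors
setMethod("opticDisc", "VascularScene", function(x) x@od)

#' @rdname accessors
setMethod("opticDisc", "TreeModel", function(x) x@od)

#' @rdname accessors
setMethod("trees", "TreeModel", function(x) x@trees)

.countNodes <- function(node) {
  if (is.null(node)) return(0L)
  1L + .countNodes(node@left) + .countNodes(node@right)
}

#' @rdname accessors
setMethod("nodeCount", "BinaryVesselTree", function(x) .countNodes(x@root))

#' @rdname accessors
setMethod("nodeCount", "TreeModel",
          function(x) sum(vapply(x@trees, nodeCount, integer(1))))

#' @rdname accessors
setMethod("featureVector", "SegmentNode", function(x) x@features)

#' @rdname accessors
setMethod("leftChild", "SegmentNode", function(x) x@left)

#' @rdname accessors
setMethod("rightChild", "SegmentNode", function(x) x@right)

#' @rdname accessors
setMethod("segmentPath", "VesselSegment", function(x) x@path)

#' @rdname accessors
setMethod("segmentPath", "SegmentNode", function(x) x@segment@path)

#' @rdname accessors
setMethod("segmentLength", "VesselSegment", function(x) x@arcLength)

#' @rdname accessors
setMethod("segmentWidth", "VesselSegment", function(x) x@avgWidth)

#' @rdname accessors
setMethod("isFinalized", "TreeModel", function(x) x@finalized)

setMethod("show", "VascularScene", function(object) {
  cat(sprintf("VascularScene %dx%d: %d centerline px, %d mask px, %d landmarks\n",
              nrow(object@centerline), ncol(object@centerline),
              sum(object@centerline), sum(object@mask),
              nrow(object@landmarks)))
  cat(sprintf("  optic disc: center (%.1f, %.1f), radius %.1f px\n",
              object@od$center[1], object@od$center[2], object@od$radius))
  if (nrow(object@landmarks))
    print(table(object@landmarks$class))
})

setMethod("show", "TreeModel", function(object) {
  cat(sprintf("TreeModel: %d vessel tree(s), %d node(s)%s\n",
              length(object@trees), nodeCount(object),
              if (object@finalized) ", finalized" else ""))
  for (t in object@trees)
    cat(sprintf("  %s: %d node(s), root at (%d, %d)\n", t@vesselId,
                nodeCount(t), t@rootPixel[1], t@rootPixel[2]))
  if (!is.null(object@normalization))
    cat(sprintf("  normalized (lw_max = %.3f)\n", object@normalization$lw_max))
})

setMethod("show", "MatchConfig", function(object) {
  cat(sprintf("MatchConfig: relTolerance %.3f, angleTolerance %.4f rad, depth %d\n",
              object@relTolerance, object@angleTolerance,
              object@candidateDepth))
})

setMethod("show", "ModelCorrespondence", function(object) {
  cat(sprintf("ModelCorrespondence: %d pair(s), %d + %d unmatched\n",
              nrow(object@pairs), length(object@unmatchedA),
              length(object@unmatchedB)))
  if (nrow(object@pairs)) print(object@pairs)
})
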