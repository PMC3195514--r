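# Rotation robustness evaluation: rebuild the tree model from rotated
# copies of a scene and tabulate same-vessel and cross-vessel distances.

#' Evaluate matching robustness under image rotation
#'
#' For each angle the scene is rotated (ground-truth geometry rotated
#' analytically, rasters re-rendered), the tree model is rebuilt from the
#' rotated rasters, and the vessel distance matrix against the unrotated
#' model is computed twice: with the configured tolerance and with
#' tolerance 0. Rows pair each vessel with itself via the ground-truth
#' identity carried through the rotation.
#'
#' @param scene a synthetic [VascularScene-class].
#' @param truth its [GroundTruthTopology-class].
#' @param angles rotation angles in degrees.
#' @param cfg a [matchConfig()]; its tolerances are the "tolerance on"
#'   condition.
#' @return `data.frame` with columns `angle`, `vessel`,
#'   `distance_tolerance` (tolerance on), `distance_exact` (tolerance 0),
#'   `min_cross`, `max_cross` (distances to the other vessels, tolerance
#'   on), and `correspondence_ok` (does the greedy correspondence pair the
#'   vessel with its ground-truth counterpart).
#' @export
rotateEval <- function(scene, truth, angles = seq(5, 30, by = 5),
                       cfg = matchConfig()) {
  stopifnot(is(scene, "VascularScene"), is(truth, "GroundTruthTopology"))
  base <- buildTreeModel(scene)
  baseIds <- matchTreesToTruth(base, truth)
  cfg0 <- matchConfig(relTolerance = 0, angleTolerance = 0,
                      candidateDepth = cfg@candidateDepth)
  out <- list()
  for (a in angles) {
    rot <- rotateScene(scene, truth, a)
    model <- buildTreeModel(rot$scene)
    ids <- matchTreesToTruth(model, rot$truth)
    dmTol <- vesselDistanceMatrix(base, model, cfg)
    dmExact <- vesselDistanceMatrix(base, model, cfg0)
    corr <- findCorrespondence(base, model, cfg)
    for (i in seq_along(baseIds)) {
      j <- match(baseIds[i], ids)
      if (is.na(j)) next
      cross <- dmTol[i, -j]
      pairRow <- corr@pairs[corr@pairs$treeA == i, , drop = FALSE]
      ok <- nrow(pairRow) == 1 && pairRow$treeB == j
      out[[length(out) + 1L]] <- data.frame(
        angle = a, vessel = baseIds[i],
        distance_tolerance = dmTol[i, j],
        distance_exact = dmExact[i, j],
        min_cross = if (length(cross)) min(cross) else NA_integer_,
        max_cross = if (length(cross)) max(cross) else NA_integer_,
        correspondence_ok = ok, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
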