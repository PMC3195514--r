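# Preorder feature-vector matching between binary vessel trees.

#' Preorder node sequence over the complete depth-limited tree
#'
#' Traverses root, then left subtree, then right subtree, over the
#' *complete* binary tree of the given depth: absent positions are explicit
#' `NULL` gaps, so two trees of different shape align position-by-position
#' (7 positions at depth 2).
#'
#' @param tree a [BinaryVesselTree-class] (or a [SegmentNode-class]).
#' @param depthLimit levels included (0 = root only); `NULL` uses the
#'   tree's own depth.
#' @return list of [SegmentNode-class] objects and `NULL` gaps.
#' @export
preorderNodes <- function(tree, depthLimit = NULL) {
  root <- if (is(tree, "BinaryVesselTree")) tree@root else tree
  if (is.null(depthLimit)) depthLimit <- .treeDepth(root)
  rec <- function(node, d) {
    if (d < 0) return(list())
    c(list(node),
      rec(if (is.null(node)) NULL else node@left, d - 1),
      rec(if (is.null(node)) NULL else node@right, d - 1))
  }
  rec(root, depthLimit)
}

.treeDepth <- function(node) {
  if (is.null(node)) return(-1L)
  1L + max(.treeDepth(node@left), .treeDepth(node@right))
}

# Feature vectors (de-normalized) in preorder with gaps.
.preorderFeatures <- function(tree, depthLimit, params = NULL) {
  lapply(preorderNodes(tree, depthLimit), function(n)
    if (is.null(n)) NULL else .denormalize(n@features, params))
}

#' Compare two feature vectors under tolerance
#'
#' Two gaps match; a gap never matches a node. Two nodes match iff the
#' bifurcation/branch codes and crossover flags are equal, the L/W ratios
#' agree within the relative tolerance, the crossover positions agree
#' within the same tolerance (absolute), and the acute angles agree within
#' the angle tolerance.
#'
#' @param a,b named feature vectors (see [buildFeatureVector()]) or `NULL`
#'   gaps.
#' @param cfg a [matchConfig()].
#' @return `TRUE` or `FALSE`.
#' @export
nodeMatch <- function(a, b, cfg = matchConfig()) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (a[["bibr_code"]] != b[["bibr_code"]]) return(FALSE)
  if (a[["crossover_flag"]] != b[["crossover_flag"]]) return(FALSE)
  eps <- 1e-9
  if (abs(a[["lw_ratio"]] - b[["lw_ratio"]]) >
      cfg@relTolerance * max(a[["lw_ratio"]], eps)) return(FALSE)
  if (abs(a[["crossover_pos"]] - b[["crossover_pos"]]) >
      cfg@relTolerance + eps) return(FALSE)
  if (abs(a[["acute_angle"]] - b[["acute_angle"]]) >
      cfg@angleTolerance + eps) return(FALSE)
  TRUE
}

#' Node-count distance between two vessel trees
#'
#' Aligns the preorder sequences (with explicit gaps) of the two trees over
#' the complete tree of `depthLimit` levels and counts the positions whose
#' feature vectors fail [nodeMatch()]: 0 for identical trees, at most
#' `2^(depthLimit+1) - 1` (7 at depth 2).
#'
#' @param t1,t2 [BinaryVesselTree-class] objects.
#' @param cfg a [matchConfig()].
#' @param depthLimit levels compared; defaults to `cfg@candidateDepth`.
#' @param paramsA,paramsB normalization parameters of the models the trees
#'   came from (`NULL` for raw models).
#' @return Integer mismatch count.
#' @export
treeDistance <- function(t1, t2, cfg = matchConfig(), depthLimit = NULL,
                         paramsA = NULL, paramsB = NULL) {
  if (is.null(depthLimit)) depthLimit <- cfg@candidateDepth
  fa <- .preorderFeatures(t1, depthLimit, paramsA)
  fb <- .preorderFeatures(t2, depthLimit, paramsB)
  sum(!mapply(nodeMatch, fa, fb, MoreArgs = list(cfg = cfg)))
}

#' Greedy vessel correspondence between two tree models
#'
#' For each tree of model A (in model order) the distance to every not yet
#' matched tree of model B is computed at the candidate depth, and the
#' minimum-distance tree (tie: lowest B index) is paired and removed from
#' the pool. Pairing happens even when the best distance is positive — the
#' best match is relied upon — and the distance is recorded. With unequal
#' tree counts the excess trees are reported unmatched.
#'
#' @param modelA,modelB finalized [TreeModel-class] objects.
#' @param cfg a [matchConfig()].
#' @return A [ModelCorrespondence-class].
#' @export
findCorrespondence <- function(modelA, modelB, cfg = matchConfig()) {
  stopifnot(is(modelA, "TreeModel"), is(modelB, "TreeModel"))
  if (!modelA@finalized || !modelB@finalized)
    stop("both models must be finalized")
  nA <- length(modelA@trees); nB <- length(modelB@trees)
  pool <- seq_len(nB)
  rows <- list()
  for (i in seq_len(nA)) {
    if (!length(pool)) break
    d <- vapply(pool, function(j)
      treeDistance(modelA@trees[[i]], modelB@trees[[j]], cfg,
                   paramsA = modelA@normalization,
                   paramsB = modelB@normalization), numeric(1))
    j <- pool[order(d, pool)[1]]
    rows[[length(rows) + 1L]] <-
      data.frame(treeA = i, treeB = j,
                 vesselA = modelA@trees[[i]]@vesselId,
                 vesselB = modelB@trees[[j]]@vesselId,
                 distance = as.integer(min(d)), stringsAsFactors = FALSE)
    pool <- setdiff(pool, j)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treeA = integer(0), treeB = integer(0),
               vesselA = character(0), vesselB = character(0),
               distance = integer(0))
  new("ModelCorrespondence", pairs = pairs,
      unmatchedA = setdiff(seq_len(nA), pairs$treeA),
      unmatchedB = setdiff(seq_len(nB), pairs$treeB))
}

#' Full vessel-by-vessel distance matrix between two models
#'
#' Entry `(i, j)` is the node-count distance between tree `i` of model A
#' and tree `j` of model B at the candidate depth (no greedy removal).
#'
#' @param modelA,modelB finalized [TreeModel-class] objects.
#' @param cfg a [matchConfig()].
#' @return Integer matrix with vessel-id dimnames.
#' @export
vesselDistanceMatrix <- function(modelA, modelB, cfg = matchConfig()) {
  stopifnot(is(modelA, "TreeModel"), is(modelB, "TreeModel"))
  nA <- length(modelA@trees); nB <- length(modelB@trees)
  m <- matrix(0L, nA, nB,
              dimnames = list(vapply(modelA@trees, function(t) t@vesselId,
                                     character(1)),
                              vapply(modelB@trees, function(t) t@vesselId,
                                     character(1))))
  for (i in seq_len(nA))
    for (j in seq_len(nB))
      m[i, j] <- as.integer(
        treeDistance(modelA@trees[[i]], modelB@trees[[j]], cfg,
                     paramsA = modelA@normalization,
                     paramsB = modelB@normalization))
  m
}

#' Inter-image distance matrix over a set of tree models
#'
#' Entry `(i, j)` sums the pair distances of
#' `findCorrespondence(model_i, model_j)` plus a full-tree penalty
#' (`2^(depth+1) - 1` nodes) per unmatched tree. Symmetric by construction
#' (the upper triangle is mirrored); the diagonal is 0.
#'
#' @param models list of finalized [TreeModel-class] objects.
#' @param cfg a [matchConfig()].
#' @return Integer matrix.
#' @export
modelDistanceMatrix <- function(models, cfg = matchConfig()) {
  stopifnot(length(models) >= 1)
  n <- length(models)
  penalty <- as.integer(2^(cfg@candidateDepth + 1) - 1)
  m <- matrix(0L, n, n,
              dimnames = list(paste0("model", seq_len(n)),
                              paste0("model", seq_len(n))))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i) {
        corr <- findCorrespondence(models[[i]], models[[j]], cfg)
        m[i, j] <- as.integer(sum(corr@pairs$distance) +
          penalty * (length(corr@unmatchedA) + length(corr@unmatchedB)))
        m[j, i] <- m[i, j]
      }
  m
}

#' Total matching distance between two models
#'
#' Convenience wrapper: sum of pair distances of the greedy correspondence
#' plus the unmatched-tree penalty. 0 for a model against itself.
#'
#' @param modelA,modelB finalized [TreeModel-class] objects.
#' @param cfg a [matchConfig()].
#' @return Integer total distance.
#' @export
modelDistance <- function(modelA, modelB, cfg = matchConfig()) {
  corr <- findCorrespondence(modelA, modelB, cfg)
  penalty <- as.integer(2^(cfg@candidateDepth + 1) - 1)
  as.integer(sum(corr@pairs$distance) +
             penalty * (length(corr@unmatchedA) + length(corr@unmatchedB)))
}
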