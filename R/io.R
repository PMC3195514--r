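# Scene, tree-model and distance-matrix (de)serialization.
#
# On-disk coordinates are 0-based (row, col), origin top-left; every JSON
# document carries a "coordinates" field stating this. In-memory coordinates
# are 1-based R indices; the shift happens only here.

.SCENE_FILES <- c("centerline.png", "mask.png", "landmarks.json", "od.json")
.FORMAT_VERSION <- 1L

.toJSONText <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

.writeJSONFile <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(.toJSONText(x), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a vascular scene to a directory
#'
#' Produces `centerline.png`, `mask.png`, `landmarks.json` and `od.json`
#' (coordinates 0-based on disk). Writers are deterministic byte-for-byte.
#'
#' @param scene a [VascularScene-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "VascularScene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png::writePNG(scene@centerline + 0.0, file.path(dir, "centerline.png"))
  png::writePNG(scene@mask + 0.0, file.path(dir, "mask.png"))
  lm <- scene@landmarks
  lmList <- lapply(seq_len(nrow(lm)), function(i)
    list(row = lm$row[i] - 1, col = lm$col[i] - 1, class = lm$class[i]))
  .writeJSONFile(list(format_version = .FORMAT_VERSION,
                      coordinates = "0-based (row, col), origin top-left",
                      landmarks = lmList),
                 file.path(dir, "landmarks.json"))
  .writeJSONFile(list(format_version = .FORMAT_VERSION,
                      coordinates = "0-based (row, col), origin top-left",
                      row = scene@od$center[1] - 1,
                      col = scene@od$center[2] - 1,
                      radius = scene@od$radius),
                 file.path(dir, "od.json"))
  invisible(dir)
}

#' Read a vascular scene from a directory
#'
#' Expects the four files written by [writeScene()]. Rasters are binarized
#' at threshold > 0. Validation failures (missing file, raster size
#' mismatch, landmark out of bounds, unknown landmark class) raise distinct
#' errors.
#'
#' @param dir scene directory.
#' @return A validated [VascularScene-class].
#' @export
readScene <- function(dir) {
  for (f in .SCENE_FILES)
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("scene file missing: %s", file.path(dir, f)))
  cl <- png::readPNG(file.path(dir, "centerline.png"))
  mk <- png::readPNG(file.path(dir, "mask.png"))
  if (length(dim(cl)) == 3) cl <- cl[, , 1]
  if (length(dim(mk)) == 3) mk <- mk[, , 1]
  cl <- (cl > 0) + 0L
  mk <- (mk > 0) + 0L
  lj <- jsonlite::fromJSON(file.path(dir, "landmarks.json"),
                           simplifyDataFrame = TRUE)
  lm <- if (length(lj$landmarks))
    data.frame(row = lj$landmarks$row + 1, col = lj$landmarks$col + 1,
               class = as.character(lj$landmarks$class),
               stringsAsFactors = FALSE)
  else data.frame(row = numeric(0), col = numeric(0), class = character(0))
  oj <- jsonlite::fromJSON(file.path(dir, "od.json"))
  VascularScene(cl, mk, lm,
                od = list(center = c(oj$row + 1, oj$col + 1),
                          radius = oj$radius))
}

.nodeToList <- function(node) {
  if (is.null(node)) return(NULL)
  list(segment_id = node@segment@id,
       features = as.numeric(node@features),
       left = .nodeToList(node@left),
       right = .nodeToList(node@right))
}

.nodeFromList <- function(x, level = 0L) {
  if (is.null(x)) return(NULL)
  feats <- as.numeric(x$features)
  names(feats) <- .FEATURE_NAMES
  seg <- new("VesselSegment", id = as.character(x$segment_id),
             path = matrix(numeric(0), 0, 2),
             terminatingLandmark = NULL, lengthPx = 0, arcLength = 0,
             avgWidth = NA_real_,
             crossovers = data.frame(index = numeric(0), row = numeric(0),
                                     col = numeric(0)))
  new("SegmentNode", segment = seg, features = feats,
      left = .nodeFromList(x$left, level + 1L),
      right = .nodeFromList(x$right, level + 1L), level = level)
}

#' Write a tree model as JSON
#'
#' Serializes the optic-disc root and one binary tree per vessel. Each node
#' carries its segment id and the five feature values in canonical order:
#' L/W ratio, bifurcation/branch code, crossover flag, crossover position,
#' acute angle. The model must be finalized (features computed).
#'
#' @param model a finalized [TreeModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTreeModel <- function(model, path) {
  stopifnot(is(model, "TreeModel"))
  if (!model@finalized)
    stop("tree model is not finalized: compute features before writing")
  doc <- list(format_version = .FORMAT_VERSION,
              coordinates = "0-based (row, col), origin top-left",
              feature_order = as.list(.FEATURE_NAMES),
              od = list(row = model@od$center[1] - 1,
                        col = model@od$center[2] - 1,
                        radius = model@od$radius),
              normalization = model@normalization,
              trees = lapply(model@trees, function(t)
                list(vessel_id = t@vesselId,
                     root_pixel = list(row = t@rootPixel[1] - 1,
                                       col = t@rootPixel[2] - 1),
                     root = .nodeToList(t@root))))
  .writeJSONFile(doc, path)
}

#' Read a tree model written by [writeTreeModel()]
#'
#' The segment geometry (paths) is not serialized; the returned model
#' carries ids, tree shape and feature vectors, which is everything the
#' matcher consumes.
#'
#' @param path JSON file.
#' @return A finalized [TreeModel-class].
#' @export
readTreeModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$format_version) ||
      doc$format_version != .FORMAT_VERSION)
    stop(sprintf("unsupported tree-model format_version: %s",
                 format(doc$format_version)))
  trees <- lapply(doc$trees, function(t)
    new("BinaryVesselTree", vesselId = as.character(t$vessel_id),
        root = .nodeFromList(t$root),
        rootPixel = c(t$root_pixel$row + 1, t$root_pixel$col + 1)))
  norm <- doc$normalization
  if (!is.null(norm)) norm <- list(lw_max = norm$lw_max,
                                   angle_scale = norm$angle_scale)
  new("TreeModel",
      od = list(center = c(doc$od$row + 1, doc$od$col + 1),
                radius = doc$od$radius),
      trees = trees, normalization = norm, finalized = TRUE)
}

#' Write a node-count distance matrix as CSV
#'
#' Labeled header row and label column; entries are integer node counts.
#'
#' @param m square numeric matrix with row and column names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  df <- as.data.frame(m)
  utils::write.csv(df, path, row.names = TRUE, quote = TRUE)
  invisible(path)
}

#' Read a distance matrix written by [writeDistanceMatrix()]
#'
#' @param path CSV file.
#' @return An integer matrix with dimnames.
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m
}

#' Write ground-truth topology as JSON
#'
#' @param truth a [GroundTruthTopology-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruthTopology"))
  recToList <- function(rec) {
    out <- list(id = rec$id,
                start = as.numeric(rec$start) - 1,
                end = as.numeric(rec$end) - 1,
                width = rec$width, level = rec$level,
                landmark_class = if (is.na(rec$landmarkClass)) NULL
                                 else rec$landmarkClass,
                landmark_pixel = if (is.null(rec$landmarkPixel)) NULL
                                 else as.numeric(rec$landmarkPixel) - 1,
                crossover = if (is.null(rec$crossover)) NULL
                            else list(pixel = as.numeric(rec$crossover$pixel) - 1,
                                      frac = rec$crossover$frac))
    out$children <- lapply(rec$children, recToList)
    out
  }
  lm <- truth@landmarks
  doc <- list(format_version = .FORMAT_VERSION,
              coordinates = "0-based (row, col), origin top-left",
              vessels = lapply(truth@vessels, function(v)
                list(id = v$id, root = recToList(v$root))),
              landmarks = lapply(seq_len(nrow(lm)), function(i)
                list(row = lm$row[i] - 1, col = lm$col[i] - 1,
                     class = lm$class[i], vessel_id = lm$vesselId[i],
                     segment_id = lm$segmentId[i])))
  .writeJSONFile(doc, path)
}
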