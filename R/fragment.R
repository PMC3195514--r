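# Fragmentation of the centerline at landmark points.

#' Fragment a centerline at its landmarks
#'
#' Marks every centerline pixel in the 8-neighbourhood of a landmark (the
#' landmark's "boundary zone") with the landmark's index; every maximal
#' connected run of unmarked centerline pixels between zones is one
#' fragment. Landmarks within 2 px of the centerline are snapped to the
#' nearest centerline pixel silently, between 2 and 5 px with a warning,
#' and farther than 5 px raise an error.
#'
#' @param scene a [VascularScene-class].
#' @return A [FragmentedCenterline-class].
#' @export
fragmentCenterline <- function(scene) {
  stopifnot(is(scene, "VascularScene"))
  m <- scene@centerline
  b <- matrix(0L, nrow(m), ncol(m))
  lm <- scene@landmarks
  on <- which(m == 1L, arr.ind = TRUE)
  if (nrow(lm) && nrow(on) == 0)
    stop("centerline raster is empty but landmarks are present")
  snapped <- lm
  for (i in seq_len(nrow(lm))) {
    p <- c(lm$row[i], lm$col[i])
    d2 <- (on[, 1] - p[1])^2 + (on[, 2] - p[2])^2
    j <- which.min(d2)
    d <- sqrt(d2[j])
    if (d > 5)
      stop(sprintf("landmark %d (%s at %d,%d) is %.1f px from the centerline",
                   i, lm$class[i], p[1], p[2], d))
    if (d > 2)
      warning(sprintf("landmark %d (%s) snapped %.1f px to the centerline",
                      i, lm$class[i], d))
    snapped$row[i] <- on[j, 1]
    snapped$col[i] <- on[j, 2]
  }
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nrow(snapped))) {
    rr <- snapped$row[i] + (-1):1
    cc <- snapped$col[i] + (-1):1
    rr <- rr[rr >= 1 & rr <= nr]
    cc <- cc[cc >= 1 & cc <= nc]
    zone <- as.matrix(expand.grid(row = rr, col = cc))
    onZone <- zone[m[zone] == 1L, , drop = FALSE]
    b[onZone] <- i
  }
  new("FragmentedCenterline", raster = m, boundary = b, landmarks = snapped)
}

#' Connected fragments of a fragmented centerline
#'
#' Labels the maximal 8-connected runs of non-boundary centerline pixels.
#' Mostly a diagnostic; the tracer works directly on the annotated raster.
#'
#' @param frag a [FragmentedCenterline-class].
#' @return Integer matrix of fragment labels (0 = background or boundary).
#' @export
fragmentLabels <- function(frag) {
  stopifnot(is(frag, "FragmentedCenterline"))
  work <- frag@raster == 1L & frag@boundary == 0L
  lab <- matrix(0L, nrow(work), ncol(work))
  nextLab <- 0L
  idx <- which(work, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    if (lab[p[1], p[2]] != 0L) next
    nextLab <- nextLab + 1L
    queue <- list(p)
    lab[p[1], p[2]] <- nextLab
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      for (j in 1:8) {
        r <- q[1] + .NB8[j, 1]; c <- q[2] + .NB8[j, 2]
        if (r >= 1 && r <= nrow(work) && c >= 1 && c <= ncol(work) &&
            work[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextLab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}
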