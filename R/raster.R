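# Low-level raster and planar-geometry helpers (internal).
# Points are numeric (row, col); paths are n x 2 matrices, 1-based.

.NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Unit direction for a clock angle: 0 = 12 o'clock (up), increasing clockwise.
.clockDir <- function(theta) c(-cos(theta), sin(theta))

# Clock angle of point p about center (0 at 12 o'clock, clockwise, in [0, 2pi)).
.clockAngle <- function(p, center) {
  a <- atan2(p[2] - center[2], -(p[1] - center[1]))
  (a + 2 * pi) %% (2 * pi)
}

.angDiff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

# Rotate points (n x 2, (row, col)) about a center by `degrees`.
.rotatePoints <- function(pts, center, degrees) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  th <- degrees * pi / 180
  co <- cos(th); si <- sin(th)
  r <- pts[, 1] - center[1]
  c <- pts[, 2] - center[2]
  cbind(center[1] + co * r - si * c,
        center[2] + si * r + co * c)
}

# 8-connected Bresenham line between integer endpoints, inclusive.
.bresenham <- function(p0, p1) {
  r0 <- round(p0[1]); c0 <- round(p0[2])
  r1 <- round(p1[1]); c1 <- round(p1[2])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

# Dense samples of a quadratic Bezier (start, control, end), spaced ~`step`.
.bezierPoints <- function(p0, ctrl, p1, step = 0.3) {
  chord <- sqrt(sum((p1 - p0)^2))
  n <- max(8L, ceiling((chord + 2 * sqrt(sum((ctrl - (p0 + p1) / 2)^2))) /
                         step))
  tt <- seq(0, 1, length.out = n)
  cbind((1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * ctrl[1] + tt^2 * p1[1],
        (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * ctrl[2] + tt^2 * p1[2])
}

# Sampled points of a segment record: quadratic Bezier plus a small
# tapered sinusoidal undulation in the curve's local frame (so the whole
# geometry rotates rigidly with the control points). The undulation keeps
# the rendered band's sub-pixel phase moving everywhere, which every width
# estimator needs; it vanishes at the endpoints so junction points stay
# exact.
.segmentPoints <- function(rec, step = 0.3) {
  pts <- .bezierPoints(rec$start, rec$ctrl, rec$end, step)
  wig <- rec$wiggle
  if (!is.null(wig)) {
    n <- nrow(pts)
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    tg <- rbind(pts[2, ] - pts[1, ],
                (pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]) / 2,
                pts[n, ] - pts[n - 1, ])
    nv <- sqrt(rowSums(tg^2))
    nrm <- cbind(-tg[, 2], tg[, 1]) / nv
    # amplitude chirp: successive undulation extrema then land on
    # different sub-pixel offsets, so no band orientation can lock the
    # rendered ink width to one quantized value along the segment
    amp <- wig$a * (0.75 + 0.6 * s / max(s[n], 1))
    off <- amp * sin(2 * pi * s / wig$p + wig$ph)
    taper <- pmin(1, s / 8, (s[n] - s) / 8)
    pts <- pts + off * taper * nrm
  }
  pts
}

# 8-connected pixel chain along densely sampled curve points.
.curveChain <- function(pts) {
  rp <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(rp))) > 0)
  ch <- rp[keep, , drop = FALSE]
  # bridge any residual jumps (sampling is dense, so these are rare)
  out <- list(ch[1, ])
  for (i in seq_len(nrow(ch) - 1L)) {
    if (max(abs(ch[i + 1L, ] - ch[i, ])) > 1) {
      br <- .bresenham(ch[i, ], ch[i + 1L, ])
      for (k in 2:nrow(br)) out[[length(out) + 1L]] <- br[k, ]
    } else out[[length(out) + 1L]] <- ch[i + 1L, ]
  }
  ch <- do.call(rbind, out)
  # thin staircase doubling: drop a pixel whenever its chain neighbours are
  # already 8-adjacent to each other, so the rendered line is 1 px wide
  for (pass in 1:2) {
    keep <- rep(TRUE, nrow(ch))
    i <- 2L
    while (i < nrow(ch)) {
      prev <- max(which(keep[1:(i - 1L)]))
      if (max(abs(ch[i + 1L, ] - ch[prev, ])) <= 1) keep[i] <- FALSE
      i <- i + 1L
    }
    ch <- ch[keep, , drop = FALSE]
  }
  ch
}

# Set to 1 every pixel whose center is within `radius` of the sampled curve.
.bandMask <- function(m, pts, radius) {
  nr <- nrow(m); nc <- ncol(m)
  r1 <- max(1L, floor(min(pts[, 1]) - radius - 1))
  r2 <- min(nr, ceiling(max(pts[, 1]) + radius + 1))
  c1 <- max(1L, floor(min(pts[, 2]) - radius - 1))
  c2 <- min(nc, ceiling(max(pts[, 2]) + radius + 1))
  rr <- r1:r2; cc <- c1:c2
  gr <- rep(rr, times = length(cc))
  gc <- rep(cc, each = length(rr))
  dmin <- rep(Inf, length(gr))
  for (k in seq_len(nrow(pts)))
    dmin <- pmin(dmin, (gr - pts[k, 1])^2 + (gc - pts[k, 2])^2)
  hit <- dmin <= radius^2
  m[cbind(gr[hit], gc[hit])] <- 1L
  m
}

# Vectorized bilinear sampling of a matrix at fractional (row, col);
# positions outside the matrix read as 0.
.bilinearSample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out <- numeric(length(i))
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
}

# Stamp filled discs of `radius` at each of `pixels` into matrix `m` (set 1).
.stampDiscs <- function(m, pixels, radius) {
  rad <- max(radius, 1)
  ir <- ceiling(rad)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, , drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  for (k in seq_len(nrow(pixels))) {
    rr <- pixels[k, 1] + off$dr
    cc <- pixels[k, 2] + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    m[cbind(rr[ok], cc[ok])] <- 1L
  }
  m
}

# Centered moving average; the window shrinks *symmetrically* near the
# ends (an asymmetric window would drag the endpoints toward the interior
# and bias path lengths).
.movingAvg <- function(x, k) {
  n <- length(x)
  if (n <= 2 || k <= 1) return(x)
  h <- k %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hh <- pmin(h, i - 1, n - i)
  lo <- i - hh; hi <- i + hh
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Smoothed Euclidean arc length of a pixel path, in pixel units, with a
# +1 end-correction so an axis-aligned straight run of n pixels measures n.
.pathArcLength <- function(path, window = 9) {
  n <- nrow(path)
  if (n <= 1) return(as.numeric(n))
  r <- .movingAvg(path[, 1], window)
  c <- .movingAvg(path[, 2], window)
  sum(sqrt(diff(r)^2 + diff(c)^2)) + 1
}

# Principal direction (unit vector) of a point set by least squares.
.fitDirection <- function(pts) {
  n <- nrow(pts)
  if (n < 3) {
    v <- pts[n, ] - pts[1, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(c(1, 0))
    return(v / nv)
  }
  x <- sweep(pts, 2, colMeans(pts))
  sv <- svd(x, nu = 0, nv = 1)
  as.numeric(sv$v[, 1])
}

# Acute angle between two undirected unit vectors, in [0, pi/2].
.acuteBetween <- function(u, v) {
  d <- abs(sum(u * v))
  acos(max(min(d, 1), 0))
}

.chebyshev <- function(p, q) max(abs(p - q))

.inBounds <- function(p, dims) {
  p[1] >= 1 && p[1] <= dims[1] && p[2] >= 1 && p[2] <= dims[2]
}

.vtMessage <- function(...) {
  if (isTRUE(getOption("vasctree.verbose", FALSE))) message(...)
}
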