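# Planar polygon primitives. Rings are (n x 2) numeric matrices of vertices
# in order, NOT closed (the first vertex is not repeated at the end).
# Coordinates live in a mathematical y-up plane.

#' Signed area of a polygon ring
#'
#' Shoelace formula; positive for counterclockwise rings in the y-up plane.
#'
#' @param ring An \code{n x 2} numeric matrix of vertices (not closed).
#' @return Signed area (numeric scalar).
#' @export
polySignedArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a polygon ring
#' @inheritParams polySignedArea
#' @return Total edge length including the closing edge.
#' @export
polyPerimeter <- function(ring) {
  d <- ring[c(2:nrow(ring), 1), , drop = FALSE] - ring
  sum(sqrt(rowSums(d^2)))
}

#' Centroid of a polygon ring
#' @inheritParams polySignedArea
#' @return Length-2 numeric vector (area centroid).
#' @export
polyCentroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(ring))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second area moments about the centroid; returns 2x2 covariance-like matrix
# (Ixx = integral of (x-cx)^2 dA / A, etc.). Used for the principal axis.
polyMoments <- function(ring) {
  cen <- polyCentroid(ring)
  x <- ring[, 1] - cen[1]; y <- ring[, 2] - cen[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  sxx <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  syy <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  sxy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  m <- matrix(c(sxx, sxy, sxy, syy), 2, 2) / a
  if (polySignedArea(ring) < 0) m else m  # moments already normalized by a
}

# Clip ring by the half-plane a*x + b*y <= c (Sutherland-Hodgman step).
# Returns a ring matrix, possibly with 0 rows.
clipHalfPlane <- function(ring, a, b, c) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  v <- a * ring[, 1] + b * ring[, 2] - c
  inside <- v <= 0
  if (all(inside)) return(ring)
  if (!any(inside)) return(ring[integer(0), , drop = FALSE])
  nxt <- c(2:n, 1)
  outx <- numeric(2 * n); outy <- numeric(2 * n); m <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (inside[i]) {
      m <- m + 1L; outx[m] <- ring[i, 1]; outy[m] <- ring[i, 2]
      if (!inside[j]) {
        t <- v[i] / (v[i] - v[j])
        m <- m + 1L
        outx[m] <- ring[i, 1] + t * (ring[j, 1] - ring[i, 1])
        outy[m] <- ring[i, 2] + t * (ring[j, 2] - ring[i, 2])
      }
    } else if (inside[j]) {
      t <- v[i] / (v[i] - v[j])
      m <- m + 1L
      outx[m] <- ring[i, 1] + t * (ring[j, 1] - ring[i, 1])
      outy[m] <- ring[i, 2] + t * (ring[j, 2] - ring[i, 2])
    }
  }
  cbind(outx[seq_len(m)], outy[seq_len(m)])
}

# Clip a ring to the slab x0 <= x <= x1 (axis-aligned, y-up frame).
clipSlabX <- function(ring, x0, x1) {
  r <- clipHalfPlane(ring, -1, 0, -x0)
  if (nrow(r) < 3L) return(r[integer(0), , drop = FALSE])
  r <- clipHalfPlane(r, 1, 0, x1)
  if (nrow(r) < 3L) return(r[integer(0), , drop = FALSE])
  r
}

# Even-odd point-in-polygon test (single point).
pointInRing <- function(p, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y <= p[2]) & (yn > p[2])) | ((yn <= p[2]) & (y > p[2]))
  if (!any(crosses)) return(FALSE)
  t <- (p[2] - y[crosses]) / (yn[crosses] - y[crosses])
  xi <- x[crosses] + t * (xn[crosses] - x[crosses])
  sum(xi > p[1]) %% 2L == 1L
}

# Remove consecutive duplicate vertices (within tol) and a duplicated
# closing vertex.
dedupeRing <- function(ring, tol = 0) {
  n <- nrow(ring)
  if (n < 2L) return(ring)
  d <- ring[c(2:n, 1), , drop = FALSE] - ring
  keep <- sqrt(rowSums(d^2)) > tol
  # keep[i] FALSE means vertex i+1 duplicates vertex i; drop the later one
  ring[c(keep[n], keep[-n]), , drop = FALSE]
}

# Does the closed ring self-intersect (proper crossings or repeated
# non-adjacent vertices)? O(n^2); callers gate on ring size.
ringSelfIntersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  p <- ring
  q <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip adjacent segments (share an endpoint)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segIntersects(p[i, ], q[i, ], p[js, , drop = FALSE],
                          q[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

# Vectorized proper-or-touching segment intersection of (a1,a2) against
# rows of (b1,b2).
segIntersects <- function(a1, a2, b1, b2) {
  d1x <- a2[1] - a1[1]; d1y <- a2[2] - a1[2]
  d2x <- b2[, 1] - b1[, 1]; d2y <- b2[, 2] - b1[, 2]
  denom <- d1x * d2y - d1y * d2x
  ex <- b1[, 1] - a1[1]; ey <- b1[, 2] - a1[2]
  t <- (ex * d2y - ey * d2x)
  u <- (ex * d1y - ey * d1x)
  ok <- abs(denom) > 1e-14
  res <- logical(length(denom))
  tt <- t[ok] / denom[ok]; uu <- u[ok] / denom[ok]
  res[ok] <- tt > 1e-12 & tt < 1 - 1e-12 & uu > 1e-12 & uu < 1 - 1e-12
  res
}

# Snap a cloud of 2-D points so that points within tol of each other share
# identical coordinates: same-bin points fuse directly, straddling pairs in
# neighbouring grid bins are merged by union-find. Deterministic.
snapVertices <- function(pts, tol = 1e-6) {
  n <- nrow(pts)
  gx <- round(pts[, 1] / tol); gy <- round(pts[, 2] / tol)
  key <- paste(gx, gy)
  rep_idx <- match(key, key)               # same-bin representative
  u <- which(rep_idx == seq_len(n))        # bin representatives
  if (length(u) > 1L) {
    ukey <- key[u]
    parent <- seq_along(u)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1),
                  c(-1, 0, 1, -1, 1, -1, 0, 1))
    for (o in seq_len(8L)) {
      nk <- paste(gx[u] + offs[o, 1], gy[u] + offs[o, 2])
      m <- match(nk, ukey)
      hit <- which(!is.na(m))
      for (i in hit) {
        j <- m[i]
        if (j <= i) next
        if (sum((pts[u[i], ] - pts[u[j], ])^2) <= (2 * tol)^2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    if (any(parent != seq_along(u))) {
      root <- vapply(seq_along(u), find, 0L)
      rep_idx <- u[root[match(key, ukey)]]
    }
  }
  list(coords = pts[rep_idx, , drop = FALSE], rep = rep_idx)
}

# Douglas-Peucker simplification of an open polyline, endpoints kept.
simplifyPolyline <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L || tol <= 0) return(pts)
  keep <- logical(n); keep[1] <- TRUE; keep[n] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; len2 <- sum(ab^2)
    mid <- (i + 1L):(j - 1L)
    dx <- pts[mid, 1] - a[1]; dy <- pts[mid, 2] - a[2]
    if (len2 < 1e-20) {
      d2 <- dx^2 + dy^2
    } else {
      cr <- dx * ab[2] - dy * ab[1]
      d2 <- cr^2 / len2
    }
    w <- which.max(d2)
    if (d2[w] > tol^2) {
      k <- mid[w]; keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  pts[keep, , drop = FALSE]
}
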