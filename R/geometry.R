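# Whole-wing geometric traits. All statistics are dimensionless: wings are
# rescaled to unit area, so P = P~/sqrt(A) - 2*sqrt(pi) vanishes for a circle
# (isoperimetric anchoring) and internal vein length L is directly comparable
# across wings of any absolute size.

#' Rescale a wing to unit area
#'
#' Uniformly scales all coordinates (boundary, domains, graph vertices and
#' edge polylines) so the boundary encloses area 1. Dimensionless statistics
#' are unchanged; topology is untouched. Idempotent.
#'
#' @param wing A \linkS4class{SegmentedWing} with positive boundary area.
#' @return The normalized \linkS4class{SegmentedWing}.
#' @export
normalizeArea <- function(wing) {
  A <- wingArea(wing)
  if (!is.finite(A) || A <= .Machine$double.eps)
    stop("degenerate wing: boundary area is zero")
  s <- 1 / sqrt(A)
  wing@boundary <- wing@boundary * s
  wing@domains <- lapply(wing@domains, function(r) r * s)
  wing@graph@vertices$x <- wing@graph@vertices$x * s
  wing@graph@vertices$y <- wing@graph@vertices$y * s
  wing@graph@polylines <- lapply(wing@graph@polylines, function(p) p * s)
  wing@normalized <- TRUE
  validObject(wing)
  wing
}

#' Orient a wing contour for curvature analysis
#'
#' Rotates the boundary into its principal-axis frame (long axis horizontal),
#' orients it clockwise, and rotates the vertex order so the walk starts at
#' the wing base: the leftmost boundary point, ties broken by lowest y. Arc
#' length s = 0 at the base; for an elongated wing s = 0.5 falls near the tip.
#'
#' @param wing A \linkS4class{SegmentedWing}, or an \code{n x 2} ring matrix.
#' @return An \code{n x 2} matrix: the oriented contour in the principal-axis
#'   frame, starting at the base point, running clockwise.
#' @export
orientContour <- function(wing) {
  ring <- if (is(wing, "SegmentedWing")) boundary(wing) else as.matrix(wing)
  ring <- dedupeRing(ring)
  if (nrow(ring) < 3L) stop("contour needs >= 3 vertices")
  if (nrow(ring) <= 2000L && ringSelfIntersects(ring))
    stop("contour is not simple (self-intersecting)")
  M <- polyMoments(ring)
  theta <- 0.5 * atan2(2 * M[1, 2], M[1, 1] - M[2, 2])
  R <- matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
  cen <- polyCentroid(ring)
  rot <- sweep(ring, 2, cen) %*% t(R)
  if (polySignedArea(rot) > 0) rot <- rot[rev(seq_len(nrow(rot))), , drop = FALSE]
  i0 <- which(rot[, 1] == min(rot[, 1]))
  if (length(i0) > 1L) i0 <- i0[which.min(rot[i0, 2])]
  rot[c(i0:nrow(rot), seq_len(i0 - 1L)), , drop = FALSE]
}

# Uniform arc-length resampling of a closed ring to n points, keeping the
# start point at s = 0.
resampleContour <- function(ring, n) {
  m <- nrow(ring)
  nxt <- c(2:m, 1)
  seg <- sqrt(rowSums((ring[nxt, , drop = FALSE] - ring)^2))
  cs <- c(0, cumsum(seg))
  L <- cs[m + 1]
  starget <- (0:(n - 1)) / n * L
  idx <- findInterval(starget, cs, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (starget - cs[idx]) / seg[idx]
  frac[!is.finite(frac)] <- 0
  ring[idx, , drop = FALSE] +
    frac * (ring[nxt[idx], , drop = FALSE] - ring[idx, , drop = FALSE])
}

#' Least-squares (Kasa) circle fit
#'
#' Algebraic least-squares circle through a set of planar points. With
#' exactly three non-collinear points this is the circumscribed circle.
#'
#' @param pts An \code{n x 2} matrix, \code{n >= 3}.
#' @return List with \code{center} (length 2) and \code{radius}
#'   (\code{Inf} for collinear points).
#' @export
fitCircleKasa <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qr_ <- qr(A)
  if (qr_$rank < 3L) return(list(center = c(NA_real_, NA_real_), radius = Inf))
  sol <- qr.coef(qr_, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0)
    return(list(center = c(NA_real_, NA_real_), radius = Inf))
  list(center = c(sol[1], sol[2]), radius = sqrt(r2))
}

#' Curvature profile along an oriented contour
#'
#' For each sample point p_i on the arc-length-resampled contour, the
#' curvature is 1/R of the circle through p_(i-N), p_i, p_(i+N) (cyclic
#' indexing), where N is the sample offset corresponding to an arc distance
#' of \code{window} times the total perimeter — a least-squares circle fit
#' that is exact for three points. Curvature is reported as an absolute
#' value; collinear triples give 0. Note the finite window biases curvature
#' extrema low by O(window^2) where curvature varies rapidly.
#'
#' @param contour An oriented contour matrix (see \code{\link{orientContour}}).
#' @param window Fit window as a fraction of total perimeter (default 0.02,
#'   must be < 0.5).
#' @param scaled If \code{TRUE} (default), kappa is multiplied by the total
#'   perimeter, making it dimensionless (a circle then scores 2*pi).
#' @param nSamples Number of arc-length samples (default
#'   \code{max(1000, ceiling(3 / window))}).
#' @return A \linkS4class{CurvatureProfile}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)[-721]
#' circ <- cbind(cos(th), sin(th))
#' cp <- curvatureProfile(circ, scaled = TRUE)
#' range(cp@kappa) # ~ 2*pi
#' @export
curvatureProfile <- function(contour, window = 0.02, scaled = TRUE,
                             nSamples = NULL) {
  if (window <= 0 || window >= 0.5) stop("window must lie in (0, 0.5)")
  ring <- dedupeRing(as.matrix(contour))
  if (is.null(nSamples)) nSamples <- max(1000L, ceiling(3 / window))
  n <- as.integer(nSamples)
  P <- resampleContour(ring, n)
  Lp <- polyPerimeter(ring)
  N <- max(1L, as.integer(round(window * n)))
  i <- seq_len(n)
  ip <- ((i - 1L + N) %% n) + 1L
  im <- ((i - 1L - N) %% n) + 1L
  ax <- P[im, 1]; ay <- P[im, 2]
  bx <- P[, 1];  by <- P[, 2]
  cx <- P[ip, 1]; cy <- P[ip, 2]
  cross <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- sqrt((bx - ax)^2 + (by - ay)^2)
  d2 <- sqrt((cx - bx)^2 + (cy - by)^2)
  d3 <- sqrt((cx - ax)^2 + (cy - ay)^2)
  den <- d1 * d2 * d3
  kappa <- ifelse(den > 0, 2 * cross / den, 0)
  if (scaled) kappa <- kappa * Lp
  new("CurvatureProfile", s = (0:(n - 1)) / n, kappa = as.numeric(kappa),
      scaled = scaled, perimeter = Lp)
}

#' Normalized perimeter
#'
#' The wing's boundary perimeter scaled by the square root of its area and
#' offset so a circle of unit area scores exactly 0:
#' \deqn{P = \tilde{P} / \sqrt{A} - 2\sqrt{\pi}.}
#' By the isoperimetric inequality P >= 0 for any simple closed contour,
#' with equality only for a circle; the statistic is scale-invariant.
#'
#' @param wing A \linkS4class{SegmentedWing}, or a ring matrix.
#' @return The dimensionless normalized perimeter.
#' @export
normalizedPerimeter <- function(wing) {
  ring <- if (is(wing, "SegmentedWing")) boundary(wing) else as.matrix(wing)
  A <- abs(polySignedArea(ring))
  if (!is.finite(A) || A <= .Machine$double.eps)
    stop("degenerate boundary: zero area")
  polyPerimeter(ring) / sqrt(A) - 2 * sqrt(pi)
}

#' Internal vein length and morphospace coordinates
#'
#' Sums the polyline lengths of all venation-graph edges and subtracts the
#' boundary perimeter, leaving the total length of internal (cross and
#' longitudinal) veins. The wing is area-normalized first, so the returned
#' L is the scaled internal vein length; \code{LOverP} divides by the actual
#' boundary perimeter. A wing at (P, L) = (0, 0) is a circular wing without
#' internal venation.
#'
#' @param wing A \linkS4class{SegmentedWing} (normalized on the fly if not
#'   already).
#' @return A \linkS4class{ShapeStats} with slots \code{P}, \code{L},
#'   \code{LOverP}.
#' @export
internalVeinLength <- function(wing) {
  if (!isTRUE(isNormalized(wing))) wing <- normalizeArea(wing)
  pl <- edgePolylines(wing)
  if (!length(pl)) stop("wing has no venation graph")
  raw <- sum(vapply(pl, function(p) {
    d <- diff(p)
    sum(sqrt(rowSums(d^2)))
  }, 0))
  Pt <- polyPerimeter(boundary(wing))
  Lint <- raw - Pt
  if (Lint < -1e-6 * Pt)
    warning(sprintf("internal length clamped to 0 (raw - perimeter = %.3g)",
                    Lint))
  Lint <- max(Lint, 0)
  new("ShapeStats", P = normalizedPerimeter(wing), L = Lint,
      LOverP = Lint / Pt)
}
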