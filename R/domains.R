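# Per-domain shape statistics and the binned proximal-distal (base-to-tip)
# trait profile: 25 equal-width slabs perpendicular to the wing's long axis,
# each carrying the area-weighted mean domain area and circularity of the
# domains it intersects, smoothed with a Gaussian of width 2/25 span units.

#' Per-domain shape statistics
#'
#' Circularity is the isoperimetric quotient c = 4*pi*a/p^2, which is 1 for
#' a circle and tends to 0 for elongated domains; the classical
#' perimeter-to-equal-area-circumference ratio (>= 1) is its inverse square
#' root, see \code{\link{perimeterRatio}}. Fractional area divides each
#' domain's area by the whole wing area. Degenerate (numerically zero-area)
#' domains are excluded with a warning.
#'
#' @param wing A \linkS4class{SegmentedWing} (normalized on the fly if
#'   needed).
#' @return data.frame with columns \code{id}, \code{area}, \code{perimeter},
#'   \code{circularity}, \code{fractionalArea}, in domain order.
#' @export
domainMetrics <- function(wing) {
  if (!isTRUE(isNormalized(wing))) wing <- normalizeArea(wing)
  A <- wingArea(wing)
  a <- vapply(domains(wing), function(r) abs(polySignedArea(r)), 0)
  p <- vapply(domains(wing), polyPerimeter, 0)
  keep <- a > 1e-12 * A
  if (!all(keep)) {
    warning(sprintf("excluded %d degenerate zero-area domain(s)", sum(!keep)))
  }
  data.frame(id = domainIds(wing)[keep],
             area = a[keep],
             perimeter = p[keep],
             circularity = 4 * pi * a[keep] / p[keep]^2,
             fractionalArea = a[keep] / A)
}

#' Perimeter ratio from circularity
#'
#' Converts the isoperimetric quotient c = 4*pi*a/p^2 into the ratio of the
#' domain perimeter to the circumference of the equal-area circle (>= 1,
#' equal to 1 for a circle): ratio = c^(-1/2).
#'
#' @param circularity Circularity values in (0, 1].
#' @return Perimeter ratios.
#' @export
perimeterRatio <- function(circularity) 1 / sqrt(circularity)

# Rotate wing rings into the principal-axis frame with the wing base at
# low x. baseEnd: "auto" puts the denser venation end (by graph-vertex
# count) at low x; "left"/"right" select the end explicitly. Returns
# list(domains, boundary, flipped).
principalFrame <- function(wing, baseEnd = "auto") {
  ring <- boundary(wing)
  M <- polyMoments(ring)
  theta <- 0.5 * atan2(2 * M[1, 2], M[1, 1] - M[2, 2])
  R <- matrix(c(cos(-theta), sin(-theta), -sin(-theta), cos(-theta)), 2, 2)
  cen <- polyCentroid(ring)
  rot <- function(m) sweep(as.matrix(m), 2, cen) %*% t(R)
  b <- rot(ring)
  doms <- lapply(domains(wing), rot)
  v <- graphVertices(wing)
  flipped <- FALSE
  if (baseEnd == "auto" && nrow(v) > 1L) {
    vx <- rot(cbind(v$x, v$y))[, 1]
    mid <- (min(b[, 1]) + max(b[, 1])) / 2
    flipped <- sum(vx > mid) > sum(vx < mid)  # denser cluster on the right
  } else if (baseEnd == "right") {
    flipped <- TRUE
  }
  if (flipped) {
    b[, 1] <- -b[, 1]
    doms <- lapply(doms, function(m) { m[, 1] <- -m[, 1]; m })
  }
  list(domains = doms, boundary = b, flipped = flipped)
}

#' Per-domain bin overlap fractions along the proximal-distal axis
#'
#' Splits the wing span (principal axis) into \code{nBins} equal-width slabs
#' and computes, for every domain j and bin i, the fraction f_ij of the
#' domain's area falling inside the slab. Each column sums to 1: every
#' domain's area is fully assigned across bins.
#'
#' @param wing A \linkS4class{SegmentedWing}.
#' @param nBins Number of spanwise bins.
#' @param baseEnd Which end of the long axis is the wing base: \code{"auto"}
#'   (the end with the denser vertex cluster), \code{"left"} or
#'   \code{"right"} (in the principal-axis frame).
#' @return \code{nBins x nDomains} matrix of overlap fractions.
#' @export
binOverlapFractions <- function(wing, nBins = 25L, baseEnd = "auto") {
  if (nBins < 2L) stop("nBins must be >= 2")
  fr <- principalFrame(wing, baseEnd = baseEnd)
  x0 <- min(fr$boundary[, 1]); x1 <- max(fr$boundary[, 1])
  edges <- seq(x0, x1, length.out = nBins + 1L)
  k <- length(fr$domains)
  f <- matrix(0, nBins, k)
  for (j in seq_len(k)) {
    ring <- fr$domains[[j]]
    aj <- abs(polySignedArea(ring))
    rx <- range(ring[, 1])
    lo <- max(1L, findInterval(rx[1], edges, rightmost.closed = TRUE))
    hi <- min(nBins, findInterval(rx[2], edges, rightmost.closed = TRUE))
    for (i in lo:hi) {
      clip <- clipSlabX(ring, edges[i], edges[i + 1L])
      if (nrow(clip) >= 3L) f[i, j] <- abs(polySignedArea(clip)) / aj
    }
  }
  f
}

# Gaussian smoothing of a series sampled at positions `pos` (span units in
# [0,1]), reflected at both ends. Returns the smoothed series.
gaussSmoothReflect <- function(v, pos, sigma) {
  m <- length(v)
  if (m <= 1L || sigma <= 0) return(v)
  # reflect positions/values about both end positions
  pv <- c(2 * pos[1] - rev(pos[-1]), pos, 2 * pos[m] - rev(pos[-m]))
  vv <- c(rev(v[-1]), v, rev(v[-m]))
  out <- numeric(m)
  for (i in seq_len(m)) {
    w <- exp(-0.5 * ((pv - pos[i]) / sigma)^2)
    out[i] <- sum(w * vv) / sum(w)
  }
  out
}

#' Proximal-distal trait trace
#'
#' The wing span (principal axis, base at 0) is divided into \code{nBins}
#' equal rectangular bins, each encompassing all domains across that chord.
#' With overlap weights w_ij = f_ij * a_j (f_ij the fraction of domain j's
#' area in bin i, a_j its area), each bin carries the weighted mean domain
#' area sum_j w_ij a_j / sum_j w_ij and mean circularity
#' sum_j w_ij c_j / sum_j w_ij. Both series are smoothed with a discrete
#' Gaussian (standard deviation \code{sigma} in span units, reflected at the
#' ends); empty bins carry \code{NA} and are excluded from smoothing.
#'
#' @param wing A \linkS4class{SegmentedWing}; normalized on the fly.
#' @param nBins Number of spanwise bins (default 25).
#' @param sigma Gaussian smoothing width in span units (default 2/25).
#' @param rescalePerimeter If \code{TRUE}, the mean-area series is
#'   multiplied by the wing's boundary perimeter.
#' @param baseEnd See \code{\link{binOverlapFractions}}.
#' @return A \linkS4class{PDTrace}.
#' @export
pdTrace <- function(wing, nBins = 25L, sigma = 2 / 25,
                    rescalePerimeter = FALSE, baseEnd = "auto") {
  if (nBins < 2L) stop("nBins must be >= 2")
  if (!isTRUE(isNormalized(wing))) wing <- normalizeArea(wing)
  nBins <- as.integer(nBins)
  dm <- domainMetrics(wing)
  f <- binOverlapFractions(wing, nBins, baseEnd = baseEnd)
  # domainMetrics may have dropped degenerate domains; align columns
  keep <- match(dm$id, domainIds(wing))
  f <- f[, keep, drop = FALSE]
  W <- sweep(f, 2, dm$area, `*`)            # w_ij = f_ij * a_j
  wsum <- rowSums(W)
  meanA <- ifelse(wsum > 0, as.numeric(W %*% dm$area) / wsum, NA_real_)
  meanC <- ifelse(wsum > 0, as.numeric(W %*% dm$circularity) / wsum, NA_real_)
  if (rescalePerimeter) {
    Pt <- polyPerimeter(boundary(wing))
    meanA <- meanA * Pt
  }
  centers <- (seq_len(nBins) - 0.5) / nBins
  ne <- which(wsum > 0)
  smA <- meanA; smC <- meanC
  if (length(ne) > 1L) {
    smA[ne] <- gaussSmoothReflect(meanA[ne], centers[ne], sigma)
    smC[ne] <- gaussSmoothReflect(meanC[ne], centers[ne], sigma)
  }
  new("PDTrace", nBins = nBins, binCenters = centers,
      meanArea = as.numeric(meanA), meanCircularity = as.numeric(meanC),
      smoothedArea = as.numeric(smA), smoothedCircularity = as.numeric(smC),
      binWeights = as.numeric(wsum), sigma = sigma)
}
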