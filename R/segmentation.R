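# Image -> SegmentedWing. Bright membrane regions are found by thresholding,
# one front per region is seeded at its most interior point, and all fronts
# expand simultaneously with speed eps + (1 - eps) * intensity^gamma
# (first-arrival Dijkstra on the 8-connected grid). Fronts crawl through dark
# veins and race through membrane, so they meet along vein midlines and
# tessellate the wing; the label map is then traced, split into shared
# boundary chains, simplified, and polygonized into domains + venation graph.

#' Threshold a wing image into membrane components
#'
#' Pixels brighter than \code{threshold} are grouped into 4-connected
#' components labeled 1..k (raster order of first pixel); components smaller
#' than \code{minSize} pixels are discarded as speckle.
#'
#' @param image A \linkS4class{WingImage}.
#' @param threshold Intensity cut in [0, 1]; membrane is above it.
#' @param minSize Minimum component pixel count (default 25).
#' @return A \linkS4class{LabelMap} with arrival times unset (\code{NA}).
#' @export
thresholdComponents <- function(image, threshold = 0.5, minSize = 25L) {
  stopifnot(is(image, "WingImage"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  lab <- cpp_label4(pixels(image) > threshold)
  k <- max(lab)
  if (k > 0L) {
    sizes <- tabulate(lab, nbins = k)
    keep <- which(sizes >= minSize)
    remap <- integer(k)
    remap[keep] <- seq_along(keep)
    lab[] <- c(0L, remap)[lab + 1L]
  }
  arr <- matrix(NA_real_, nrow(lab), ncol(lab))
  new("LabelMap", labels = lab, arrival = arr)
}

# Wing silhouette: morphological closing of the bright (membrane) mask with
# a Euclidean disk of radius closeRadius, holes filled in between. Closing
# bridges the dark veins (including the wing margin, which touches the dark
# background), so the silhouette is the filled wing outline; veins inside it
# are crossed slowly by the fronts rather than excluded. The erosion radius
# is closeRadius - marginTrim: with marginTrim = half the margin-vein width
# the recovered outline falls on the margin-vein centerline rather than its
# inner (membrane) edge. Returns list(mask, rimDist): rimDist is the signed
# Euclidean distance to the outline (positive inside), used for sub-pixel
# rim placement during polygonization.
wingSilhouette <- function(image, threshold, closeRadius = 3L,
                           marginTrim = 0) {
  if (marginTrim < 0 || marginTrim >= closeRadius)
    stop("marginTrim must lie in [0, closeRadius)")
  bright <- pixels(image) > threshold
  H <- nrow(bright); W <- ncol(bright)
  p <- closeRadius + 2L
  rows <- p + seq_len(H); cols <- p + seq_len(W)
  padded <- matrix(FALSE, H + 2L * p, W + 2L * p)
  padded[rows, cols] <- bright
  d2b <- cpp_edt_sq(!padded)[rows, cols]           # sq. dist to membrane
  dil <- d2b <= closeRadius^2
  comp <- cpp_label4(!dil)
  borderLabs <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  borderLabs <- borderLabs[borderLabs > 0L]
  filled <- dil | (comp > 0L & !(comp %in% borderLabs)) # fill interior holes
  padded[] <- FALSE
  padded[rows, cols] <- filled
  dOut <- sqrt(cpp_edt_sq(padded)[rows, cols])     # dist to outside
  rErode <- closeRadius - marginTrim
  list(mask = filled & dOut > rErode, rimDist = dOut - rErode)
}

#' Propagate intensity-dependent fronts from per-domain seeds
#'
#' Runs a multi-source first-arrival computation over the wing silhouette
#' with local front speed \code{eps + (1 - eps) * intensity^gamma}: fronts
#' move fast through bright membrane and very slowly through dark veins, so
#' neighbouring fronts meet along vein midlines. Every silhouette pixel is
#' assigned to the seed whose front arrives first.
#'
#' @param image A \linkS4class{WingImage}.
#' @param seeds Optional integer matrix/data.frame of (row, col) seed pixels,
#'   one per membrane component. Default: the most interior point of each
#'   thresholded component (maximum distance to the component boundary, ties
#'   broken by raster order), which makes segmentation deterministic.
#' @param threshold Intensity cut separating membrane from veins/background.
#' @param eps Speed floor in (0, 1); keeps fronts from stalling on noise.
#' @param gamma Speed exponent; larger values sharpen the vein contrast.
#' @param minSize Minimum component size for auto-seeding.
#' @return A \linkS4class{LabelMap} with labels and arrival times.
#' @export
propagateFronts <- function(image, seeds = NULL, threshold = 0.5,
                            eps = 0.001, gamma = 4, minSize = 25L,
                            marginTrim = 0) {
  stopifnot(is(image, "WingImage"))
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  comp <- labelMatrix(thresholdComponents(image, threshold, minSize))
  if (is.null(seeds)) {
    k <- max(comp)
    if (k == 0L) stop("no seeds: no membrane components above threshold")
    dist <- cpp_dist_to_zero(comp > 0L)
    seeds <- matrix(0L, k, 2)
    for (j in seq_len(k)) {
      idx <- which(comp == j)
      best <- idx[which.max(dist[idx])]
      seeds[j, ] <- c((best - 1L) %% nrow(comp) + 1L,
                      (best - 1L) %/% nrow(comp) + 1L)
    }
  } else {
    seeds <- as.matrix(seeds)
    if (!nrow(seeds)) stop("no seeds given")
    sc <- comp[cbind(seeds[, 1], seeds[, 2])]
    if (any(sc == 0L))
      stop("seed ", which(sc == 0L)[1], " is not in a membrane component")
    if (anyDuplicated(sc))
      stop("two seeds lie in the same membrane component")
  }
  sil <- wingSilhouette(image, threshold, marginTrim = marginTrim)
  speed <- eps + (1 - eps) * pixels(image)^gamma
  speed[!sil$mask] <- NA_real_
  res <- cpp_first_arrival(speed, as.integer(seeds[, 1]),
                           as.integer(seeds[, 2]))
  lab <- enforce4Connectivity(res$labels, res$arrival)
  new("LabelMap", labels = lab, arrival = res$arrival,
      speedInv = 1 / speed, rimDist = sil$rimDist)
}

# 8-neighbourhood propagation can leave satellite pixels attached to their
# region only diagonally; reassign them to the earliest-arriving 4-neighbour
# region so every label is one 4-connected blob.
enforce4Connectivity <- function(lab, arr) {
  H <- nrow(lab); W <- ncol(lab)
  for (pass in 1:8) {
    changed <- FALSE
    for (k in seq_len(max(lab))) {
      mk <- lab == k
      if (!any(mk)) next
      comp <- cpp_label4(mk)
      nc <- max(comp)
      if (nc <= 1L) next
      sizes <- tabulate(comp, nbins = nc)
      main <- which.max(sizes)
      stray <- which(comp > 0L & comp != main)
      for (idx in stray) {
        r <- (idx - 1L) %% H + 1L; c <- (idx - 1L) %/% H + 1L
        best <- 0L; bestT <- Inf
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          r2 <- r + d[1]; c2 <- c + d[2]
          if (r2 < 1L || r2 > H || c2 < 1L || c2 > W) next
          l2 <- lab[r2, c2]
          if (l2 > 0L && l2 != k && arr[r2, c2] < bestT) {
            best <- l2; bestT <- arr[r2, c2]
          }
        }
        if (best > 0L) { lab[r, c] <- best; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  lab
}

# Sub-pixel refinement of label boundaries from the arrival field. For each
# 4-adjacent pixel pair (p, q) with different positive labels, the two
# fronts meet where t_p + u*m = t_q + (1-u)*m along the p->q axis
# (m = mean inverse speed), i.e. at offset delta = (t_q - t_p)/(2m) from the
# lattice edge. Both endpoints of the separating corner edge are shifted by
# delta (clamped to +/-0.45 px); each corner's final shift is the average
# over its incident boundary edges, so neighbouring rings stay identical
# along shared chains. Returns list(di, dj) of (H+1)x(W+1) corner shifts,
# or NULL when no arrival/speed information is available.
cornerSubpixelShift <- function(labelmap) {
  arr <- arrivalTimes(labelmap)
  inv <- labelmap@speedInv
  if (!length(inv) || all(is.na(arr))) return(NULL)
  rim <- labelmap@rimDist
  lab <- labelMatrix(labelmap)
  H <- nrow(lab); W <- ncol(lab)
  sumI <- matrix(0, H + 1L, W + 1L); cntI <- matrix(0L, H + 1L, W + 1L)
  sumJ <- matrix(0, H + 1L, W + 1L); cntJ <- matrix(0L, H + 1L, W + 1L)
  # offset of the true interface from the lattice edge between pixel p
  # (label > 0) and 4-neighbour q, in units of the p->q step
  pairDelta <- function(ip, iq) {
    lp <- lab[ip]; lq <- lab[iq]
    delta <- rep(NA_real_, nrow(ip))
    both <- lq > 0L
    if (any(both)) {  # two fronts: meet where arrivals balance
      m <- (inv[ip[both, , drop = FALSE]] + inv[iq[both, , drop = FALSE]]) / 2
      delta[both] <- (arr[iq[both, , drop = FALSE]] -
                        arr[ip[both, , drop = FALSE]]) / (2 * m)
    }
    if (any(!both) && length(rim)) {  # rim: interpolate the signed
      rp <- rim[ip[!both, , drop = FALSE]]          # outline distance
      rq <- rim[iq[!both, , drop = FALSE]]
      delta[!both] <- ifelse(rp > rq, rp / (rp - rq) - 0.5, NA_real_)
    }
    pmin(pmax(delta, -0.45), 0.45)
  }
  # horizontal pairs: p = (r, c), q = (r, c + 1); corner edge at j = c
  sel <- which(lab[, -W, drop = FALSE] != lab[, -1, drop = FALSE] &
                 lab[, -W, drop = FALSE] > 0L, arr.ind = TRUE)
  if (nrow(sel)) {
    r <- sel[, 1]; c <- sel[, 2]
    delta <- pairDelta(cbind(r, c), cbind(r, c + 1L))
    for (k in which(is.finite(delta))) {
      for (i in c(r[k] - 1L, r[k])) {       # 0-based corner rows -> +1 index
        sumJ[i + 1L, c[k] + 1L] <- sumJ[i + 1L, c[k] + 1L] + delta[k]
        cntJ[i + 1L, c[k] + 1L] <- cntJ[i + 1L, c[k] + 1L] + 1L
      }
    }
  }
  # mirrored: p right, q left (delta sign flips)
  sel <- which(lab[, -1, drop = FALSE] != lab[, -W, drop = FALSE] &
                 lab[, -1, drop = FALSE] > 0L &
                 lab[, -W, drop = FALSE] == 0L, arr.ind = TRUE)
  if (nrow(sel)) {
    r <- sel[, 1]; c <- sel[, 2]
    delta <- -pairDelta(cbind(r, c + 1L), cbind(r, c))
    for (k in which(is.finite(delta))) {
      for (i in c(r[k] - 1L, r[k])) {
        sumJ[i + 1L, c[k] + 1L] <- sumJ[i + 1L, c[k] + 1L] + delta[k]
        cntJ[i + 1L, c[k] + 1L] <- cntJ[i + 1L, c[k] + 1L] + 1L
      }
    }
  }
  # vertical pairs: p = (r, c), q = (r + 1, c); corner edge at i = r
  sel <- which(lab[-H, , drop = FALSE] != lab[-1, , drop = FALSE] &
                 lab[-H, , drop = FALSE] > 0L, arr.ind = TRUE)
  if (nrow(sel)) {
    r <- sel[, 1]; c <- sel[, 2]
    delta <- pairDelta(cbind(r, c), cbind(r + 1L, c))
    for (k in which(is.finite(delta))) {
      for (j in c(c[k] - 1L, c[k])) {
        sumI[r[k] + 1L, j + 1L] <- sumI[r[k] + 1L, j + 1L] + delta[k]
        cntI[r[k] + 1L, j + 1L] <- cntI[r[k] + 1L, j + 1L] + 1L
      }
    }
  }
  sel <- which(lab[-1, , drop = FALSE] != lab[-H, , drop = FALSE] &
                 lab[-1, , drop = FALSE] > 0L &
                 lab[-H, , drop = FALSE] == 0L, arr.ind = TRUE)
  if (nrow(sel)) {
    r <- sel[, 1]; c <- sel[, 2]
    delta <- -pairDelta(cbind(r + 1L, c), cbind(r, c))
    for (k in which(is.finite(delta))) {
      for (j in c(c[k] - 1L, c[k])) {
        sumI[r[k] + 1L, j + 1L] <- sumI[r[k] + 1L, j + 1L] + delta[k]
        cntI[r[k] + 1L, j + 1L] <- cntI[r[k] + 1L, j + 1L] + 1L
      }
    }
  }
  di <- ifelse(cntI > 0L, sumI / pmax(cntI, 1L), 0)
  dj <- ifelse(cntJ > 0L, sumJ / pmax(cntJ, 1L), 0)
  list(di = di, dj = dj, hasI = cntI > 0L, hasJ = cntJ > 0L)
}

#' Polygonize a label map into a segmented wing
#'
#' Traces each labeled region's boundary on the pixel-corner lattice, splits
#' the traced rings at junction corners (where three or more regions,
#' counting the outside, meet), simplifies each shared chain once
#' (Douglas-Peucker), and reassembles the rings so common edges have
#' identical coordinate sequences in neighbouring domains. Non-convex
#' regions are preserved. The venation graph is derived from the shared
#' chains; coordinates are returned in the y-up plane (image row 0 maps to
#' the top, i.e. largest y).
#'
#' @param labelmap A \linkS4class{LabelMap} from \code{\link{propagateFronts}}.
#' @param simplifyTol Douglas-Peucker tolerance in pixels (<= 1; the 0.6
#'   default matches the sub-pixel accuracy of the refined boundaries).
#' @return A \linkS4class{SegmentedWing} in pixel units (not normalized).
#' @export
polygonizeLabels <- function(labelmap, simplifyTol = 0.6) {
  lab <- labelMatrix(labelmap)
  k <- max(lab)
  if (k == 0L) stop("empty label map")
  H <- nrow(lab); W <- ncol(lab)
  ringsIJ <- cpp_trace_rings(lab, k)
  present <- !vapply(ringsIJ, is.null, TRUE)
  ringsIJ <- ringsIJ[present]
  # junction corners: >= 3 distinct labels among the 4 incident pixels
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- lab
  a <- pad[1:(H + 1L), 1:(W + 1L)]     # pixel (i-1, j-1) of corner (i, j)
  b <- pad[1:(H + 1L), 2:(W + 2L)]     # pixel (i-1, j)
  cc <- pad[2:(H + 2L), 1:(W + 1L)]    # pixel (i, j-1)
  d <- pad[2:(H + 2L), 2:(W + 2L)]     # pixel (i, j)
  ndist <- 1L + (b != a) + (cc != a & cc != b) +
    (d != a & d != b & d != cc)
  # checkerboard corners (a region touching itself or another diagonally)
  # are degree-4 points of the boundary arrangement: treat as junctions so
  # chain simplification stays consistent across the two passes
  pinch <- (a == d & a != b & a != cc) | (b == cc & b != a & b != d)
  isJunction <- ndist >= 3L | pinch
  shift <- cornerSubpixelShift(labelmap)
  # Shift lattice corners onto the sub-pixel boundary. The arrival-based
  # deltas measure the boundary's NORMAL distance from the lattice edge, so
  # interior chain points are displaced along the local chain normal by the
  # reliability-weighted mean of the axis measurements (invariant to the
  # traversal direction); chain endpoints (junctions) fall back to the raw
  # axis shifts.
  applyShift <- function(pts, cyclic = FALSE) {
    if (is.null(shift)) return(pts)
    n <- nrow(pts)
    idx <- cbind(pts[, 1] + 1L, pts[, 2] + 1L)
    di <- shift$di[idx]; dj <- shift$dj[idx]
    hi <- shift$hasI[idx]; hj <- shift$hasJ[idx]
    out <- cbind(pts[, 1] + di, pts[, 2] + dj)   # axis fallback
    if (n < 3L) return(out)
    ks <- if (cyclic) seq_len(n) else 2:(n - 1L)
    prev <- if (cyclic) c(n, seq_len(n - 1L)) else (ks - 1L)
    nxt <- if (cyclic) c(2:n, 1L) else (ks + 1L)
    ti <- pts[nxt, 1] - pts[prev, 1]
    tj <- pts[nxt, 2] - pts[prev, 2]
    len <- sqrt(ti^2 + tj^2)
    ok <- len > 0
    ni <- -tj / pmax(len, 1e-12); nj <- ti / pmax(len, 1e-12)
    wI <- abs(ni) * hi[ks]; wJ <- abs(nj) * hj[ks]
    wsum <- wI + wJ
    dbar <- ifelse(wsum > 0,
                   (wI * di[ks] * sign(ni) + wJ * dj[ks] * sign(nj)) / wsum,
                   0)
    use <- ok & wsum > 0
    out[ks[use], 1] <- pts[ks[use], 1] + dbar[use] * ni[use]
    out[ks[use], 2] <- pts[ks[use], 2] + dbar[use] * nj[use]
    out
  }
  # simplify in a canonical direction so the two rings sharing a chain get
  # byte-identical polylines (Douglas-Peucker is deterministic)
  simplifyChain <- function(pts) {
    n <- nrow(pts)
    flip <- FALSE
    for (k in seq_len(n)) {    # lexicographic forward-vs-reversed comparison
      a <- pts[k, ]; b <- pts[n - k + 1L, ]
      if (a[1] != b[1]) { flip <- a[1] > b[1]; break }
      if (a[2] != b[2]) { flip <- a[2] > b[2]; break }
    }
    if (flip) {
      got <- simplifyPolyline(pts[rev(seq_len(n)), , drop = FALSE],
                              simplifyTol)
      got[rev(seq_len(nrow(got))), , drop = FALSE]
    } else {
      simplifyPolyline(pts, simplifyTol)
    }
  }
  outRings <- vector("list", length(ringsIJ))
  for (ri in seq_along(ringsIJ)) {
    ring <- ringsIJ[[ri]]                       # (i, j) corners
    n <- nrow(ring)
    jn <- which(isJunction[cbind(ring[, 1] + 1L, ring[, 2] + 1L)])
    if (!length(jn)) {
      # no junctions: closed ring; anchor at extreme corners and simplify
      imin <- which.min(ring[, 1] * (W + 2L) + ring[, 2])
      ring2 <- applyShift(ring[c(imin:n, seq_len(imin - 1L)), , drop = FALSE],
                          cyclic = TRUE)
      h <- n %/% 2L + 1L
      p1 <- simplifyPolyline(ring2[1:h, , drop = FALSE], simplifyTol)
      p2 <- simplifyPolyline(ring2[c(h:n, 1L), , drop = FALSE], simplifyTol)
      outRings[[ri]] <- rbind(p1[-nrow(p1), , drop = FALSE],
                              p2[-nrow(p2), , drop = FALSE])
      next
    }
    ring2 <- ring[c(jn[1]:n, seq_len(jn[1] - 1L)), , drop = FALSE]
    jn2 <- sort((jn - jn[1]) %% n) + 1L
    pieces <- list()
    for (t in seq_along(jn2)) {
      i0 <- jn2[t]
      i1 <- if (t < length(jn2)) jn2[t + 1L] else n + 1L
      seg <- if (i1 <= n) ring2[i0:i1, , drop = FALSE]
             else rbind(ring2[i0:n, , drop = FALSE], ring2[1, , drop = FALSE])
      sp <- simplifyChain(applyShift(seg))
      pieces[[t]] <- sp[-nrow(sp), , drop = FALSE]
    }
    outRings[[ri]] <- do.call(rbind, pieces)
  }
  # corner (i, j) -> y-up world coordinates: x = j, y = H - i
  toWorld <- function(m) cbind(m[, 2], H - m[, 1])
  segmentedWing(lapply(outRings, toWorld), ids = which(present) - 1L,
                snapTol = 1e-9)
}

#' Segment a wing image end to end
#'
#' Convenience composition of \code{\link{thresholdComponents}},
#' \code{\link{propagateFronts}} and \code{\link{polygonizeLabels}}.
#'
#' @inheritParams propagateFronts
#' @inheritParams polygonizeLabels
#' @return A \linkS4class{SegmentedWing} in pixel units.
#' @export
segmentWing <- function(image, seeds = NULL, threshold = 0.5, eps = 0.001,
                        gamma = 4, minSize = 25L, simplifyTol = 0.6,
                        marginTrim = 0) {
  lm <- propagateFronts(image, seeds = seeds, threshold = threshold,
                        eps = eps, gamma = gamma, minSize = minSize,
                        marginTrim = marginTrim)
  polygonizeLabels(lm, simplifyTol = simplifyTol)
}
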