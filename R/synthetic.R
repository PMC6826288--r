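# Ground-truthed synthetic wings: a boundary shape (circle, ellipse or
# teardrop) tessellated by a clipped centroidal-Voronoi-like partition with
# controllable domain count and seed-density gradients (spanwise base-to-tip
# and chordwise leading-to-trailing), emulating the range from sparse
# fly-like to dense dragonfly-like venation. Cells are computed exactly by
# half-plane clipping, so domain polygons, the derived boundary and the
# venation skeleton are mutually consistent to machine precision.

#' Specification for a synthetic wing
#'
#' @param nDomains Target number of vein-bounded domains (>= 1; the generated
#'   wing has exactly this many).
#' @param boundary Boundary family: \code{"circle"}, \code{"ellipse"} or
#'   \code{"teardrop"}.
#' @param aspect Span-to-chord aspect ratio (> 0; ignored for circles).
#' @param skew Teardrop taper in [0, 1): chord shrinks by this factor toward
#'   the wing tip.
#' @param gradSpan Seed-density multiplier from wing base to tip (1 =
#'   uniform; 3 = three times denser near the tip, the dragonfly pattern).
#' @param gradChord Seed-density multiplier from leading to trailing edge.
#' @param veinWidthPx Rasterized vein thickness in pixels (>= 1).
#' @param rasterSpanPx Raster width in pixels for \code{\link{rasterizeWing}}.
#' @param boundaryPoints Number of boundary polygon vertices.
#' @param lloyd Number of density-weighted Lloyd relaxation sweeps.
#' @param seed RNG seed; the same spec always generates the same wing.
#' @return An object of class \code{SynthSpec}.
#' @export
synthSpec <- function(nDomains, boundary = c("circle", "ellipse", "teardrop"),
                      aspect = 3, skew = 0.4, gradSpan = 1, gradChord = 1,
                      veinWidthPx = 3L, rasterSpanPx = 800L,
                      boundaryPoints = 256L, lloyd = 2L, seed = 1L) {
  boundary <- match.arg(boundary)
  if (nDomains < 1L) stop("nDomains must be >= 1")
  if (aspect <= 0) stop("aspect must be positive")
  if (skew < 0 || skew >= 1) stop("skew must lie in [0, 1)")
  if (veinWidthPx < 1) stop("veinWidthPx must be >= 1")
  if (gradSpan <= 0 || gradChord <= 0) stop("gradients must be positive")
  structure(list(nDomains = as.integer(nDomains), boundary = boundary,
                 aspect = aspect, skew = skew, gradSpan = gradSpan,
                 gradChord = gradChord, veinWidthPx = as.integer(veinWidthPx),
                 rasterSpanPx = as.integer(rasterSpanPx),
                 boundaryPoints = as.integer(boundaryPoints),
                 lloyd = as.integer(lloyd), seed = as.integer(seed)),
            class = "SynthSpec")
}

boundaryRing <- function(spec) {
  m <- spec$boundaryPoints
  t <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  switch(spec$boundary,
    circle = cbind(cos(t), sin(t)),
    ellipse = cbind(cos(t), sin(t) / spec$aspect),
    teardrop = cbind(cos(t),
                     sin(t) / spec$aspect * (1 - spec$skew * (1 + cos(t)) / 2)))
}

# density weight at points (bbox-relative): spanwise gradient grows toward
# +x (tip), chordwise toward -y (trailing edge)
densityWeight <- function(xy, bbox, gS, gC) {
  tx <- (xy[, 1] - bbox[1]) / (bbox[2] - bbox[1])
  ty <- (bbox[4] - xy[, 2]) / (bbox[4] - bbox[3])
  (1 + (gS - 1) * tx) * (1 + (gC - 1) * ty)
}

# Clipped Voronoi cells of seeds inside ring; neighbour cutoff: a seed
# farther than twice the cell's current max radius cannot cut the cell.
clippedVoronoi <- function(seeds, ring) {
  n <- nrow(seeds)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- ring
    d2 <- (seeds[, 1] - seeds[i, 1])^2 + (seeds[, 2] - seeds[i, 2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      rmax2 <- max((cell[, 1] - seeds[i, 1])^2 + (cell[, 2] - seeds[i, 2])^2)
      if (d2[j] > 4 * rmax2) break
      a <- seeds[j, ] - seeds[i, ]
      c0 <- sum(a * (seeds[i, ] + seeds[j, ])) / 2
      cell <- clipHalfPlane(cell, a[1], a[2], c0)
      if (nrow(cell) < 3L) break
    }
    if (nrow(cell) < 3L) stop("degenerate Voronoi cell (coincident seeds?)")
    cells[[i]] <- cell
  }
  cells
}

# density-weighted centroid of a cell (fan triangulation, density evaluated
# at triangle centroids)
weightedCentroid <- function(cell, bbox, gS, gC) {
  cen <- polyCentroid(cell)
  n <- nrow(cell)
  nxt <- c(2:n, 1)
  ax <- cell[, 1] - cen[1]; ay <- cell[, 2] - cen[2]
  bx <- cell[nxt, 1] - cen[1]; by <- cell[nxt, 2] - cen[2]
  areas <- abs(ax * by - ay * bx) / 2
  tcx <- (cell[, 1] + cell[nxt, 1] + cen[1]) / 3
  tcy <- (cell[, 2] + cell[nxt, 2] + cen[2]) / 3
  w <- areas * densityWeight(cbind(tcx, tcy), bbox, gS, gC)
  c(sum(w * tcx), sum(w * tcy)) / sum(w)
}

#' Generate a synthetic segmented wing
#'
#' Seeds are placed by rejection sampling with the spec's density gradients,
#' relaxed by density-weighted Lloyd sweeps, and turned into exact clipped
#' Voronoi cells tessellating the boundary polygon. The venation graph is the
#' cell-boundary skeleton. Deterministic for a given spec (the global RNG
#' state is saved and restored).
#'
#' @param spec A \code{\link{synthSpec}}.
#' @return A \linkS4class{SegmentedWing} with attributes \code{"seeds"} (the
#'   final generator sites) and \code{"spec"}.
#' @examples
#' w <- generateSyntheticWing(synthSpec(20, "ellipse", seed = 7))
#' nDomains(w)
#' @export
generateSyntheticWing <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  ring <- boundaryRing(spec)
  if (spec$nDomains == 1L) {
    w <- segmentedWing(list(ring))
    attr(w, "seeds") <- matrix(polyCentroid(ring), 1)
    attr(w, "spec") <- spec
    return(w)
  }
  if (spec$nDomains > spec$boundaryPoints^2)
    stop("infeasible spec: nDomains exceeds boundary resolution")
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(spec$seed)
  bbox <- c(range(ring[, 1]), range(ring[, 2]))
  n <- spec$nDomains
  Awing <- abs(polySignedArea(ring))
  # area-weighted mean density, for the local target cell spacing
  probe <- cbind(stats::runif(4000, bbox[1], bbox[2]),
                 stats::runif(4000, bbox[3], bbox[4]))
  pin <- vapply(seq_len(4000), function(i) pointInRing(probe[i, ], ring), TRUE)
  mu <- mean(densityWeight(probe[pin, , drop = FALSE], bbox,
                           spec$gradSpan, spec$gradChord))
  # Poisson-disk-style sampling: density-weighted rejection plus a minimum
  # separation of 0.7 x the local target spacing, so no near-degenerate
  # sliver cells arise (wing domain lattices are locally regular)
  sep <- 0.7
  seeds <- matrix(0, 0, 2)
  wmax <- spec$gradSpan * spec$gradChord
  guard <- 0L
  while (nrow(seeds) < n) {
    m <- (n - nrow(seeds)) * 8L
    cand <- cbind(stats::runif(m, bbox[1], bbox[2]),
                  stats::runif(m, bbox[3], bbox[4]))
    wc <- densityWeight(cand, bbox, spec$gradSpan, spec$gradChord)
    acc <- stats::runif(m) * wmax <= wc
    hmin <- sep * sqrt(Awing * mu / (n * wc))
    for (i in seq_len(m)) {
      if (!acc[i] || !pointInRing(cand[i, ], ring)) next
      if (nrow(seeds) &&
          min((seeds[, 1] - cand[i, 1])^2 + (seeds[, 2] - cand[i, 2])^2) <
            hmin[i]^2) next
      seeds <- rbind(seeds, cand[i, ])
      if (nrow(seeds) == n) break
    }
    if ((guard <- guard + 1L) > 200L) {
      if (nrow(seeds) < n)
        stop("infeasible spec: could not place ", n, " separated seeds")
    }
  }
  for (it in seq_len(spec$lloyd)) {
    cells <- clippedVoronoi(seeds, ring)
    seeds <- t(vapply(cells, weightedCentroid, numeric(2),
                      bbox = bbox, gS = spec$gradSpan, gC = spec$gradChord))
  }
  cells <- clippedVoronoi(seeds, ring)
  w <- segmentedWing(cells, snapTol = 1e-9)
  attr(w, "seeds") <- seeds
  attr(w, "spec") <- spec
  w
}

#' Rasterize a segmented wing
#'
#' Renders the wing as a grayscale image: background dark (0), membrane
#' bright (1), all venation-graph edges (including the wing margin) drawn as
#' dark strokes (0.05) of the given pixel width. No anti-aliasing, so
#' thresholding behaviour is exactly testable.
#'
#' @param wing A \linkS4class{SegmentedWing}.
#' @param veinWidthPx Vein stroke width in pixels.
#' @param rasterSpanPx Output image width in pixels (span direction).
#' @return A \linkS4class{WingImage} with attribute \code{"transform"}
#'   (list \code{scale}, \code{xmin}, \code{ymin}, \code{margin}, \code{H})
#'   mapping wing coordinates to pixel coordinates.
#' @export
rasterizeWing <- function(wing, veinWidthPx = 3, rasterSpanPx = 800) {
  if (rasterSpanPx < 8 * veinWidthPx)
    stop("raster span too small for the requested vein width")
  b <- boundary(wing)
  xr <- range(b[, 1]); yr <- range(b[, 2])
  margin <- veinWidthPx + 4
  W <- as.integer(rasterSpanPx)
  s <- (W - 2 * margin) / diff(xr)
  # resolution check: every domain must keep a detectable membrane patch
  # once the vein strokes (half-width each side) eat into it
  apx <- vapply(domains(wing), function(r) abs(polySignedArea(r)), 0) * s^2
  ppx <- vapply(domains(wing), polyPerimeter, 0) * s
  membEst <- apx - ppx * (veinWidthPx / 2)
  if (any(membEst < 25))
    stop(sprintf(
      "raster resolution too low: %d domain(s) would fall below 25 membrane px",
      sum(membEst < 25)))
  H <- as.integer(ceiling(diff(yr) * s) + 2 * margin)
  toPx <- function(m)
    cbind((m[, 1] - xr[1]) * s + margin,
          H - ((m[, 2] - yr[1]) * s + margin))   # y down
  img <- matrix(0, H, W)
  bp <- toPx(b)
  img <- cpp_fill_polygon(img, bp[, 1], bp[, 2], 1.0)
  segs <- do.call(rbind, lapply(edgePolylines(wing), function(p) {
    pp <- toPx(p)
    cbind(pp[-nrow(pp), 1], pp[-nrow(pp), 2], pp[-1, 1], pp[-1, 2])
  }))
  img <- cpp_draw_segments(img, segs, veinWidthPx, 0.05)
  out <- new("WingImage", pixels = img, pixelSize = 1 / s)
  attr(out, "transform") <- list(scale = s, xmin = xr[1], ymin = yr[1],
                                 margin = margin, H = H)
  out
}

#' Canonical synthetic fixture battery
#'
#' Twelve pinned-seed specs spanning the observed range of venation density:
#' from a single-domain circular wing through sparse fly-like tessellations
#' (5-20 domains) to dense dragonfly-like wings (up to 500 domains) with
#' tipward and trailing-edge density gradients, over all three boundary
#' families.
#'
#' @return Named list of \code{\link{synthSpec}} objects.
#' @export
fixtureBattery <- function() {
  list(
    circle1    = synthSpec(1,   "circle",                 seed = 101L),
    ellipse5   = synthSpec(5,   "ellipse",  aspect = 3,   seed = 102L),
    teardrop10 = synthSpec(10,  "teardrop", aspect = 3,   seed = 103L),
    ellipse20  = synthSpec(20,  "ellipse",  aspect = 3,   seed = 104L),
    teardrop50 = synthSpec(50,  "teardrop", aspect = 3,   seed = 105L),
    ellipse50g = synthSpec(50,  "ellipse",  aspect = 4, gradSpan = 3,
                           veinWidthPx = 2L, seed = 106L),
    teardrop100 = synthSpec(100, "teardrop", aspect = 3.5,
                            veinWidthPx = 2L, seed = 107L),
    ellipse200g = synthSpec(200, "ellipse", aspect = 4, gradSpan = 3,
                            veinWidthPx = 2L, seed = 108L),
    teardrop200c = synthSpec(200, "teardrop", aspect = 4, gradChord = 3,
                             veinWidthPx = 2L, seed = 109L),
    ellipse300 = synthSpec(300, "ellipse",  aspect = 3.5,
                           veinWidthPx = 2L, seed = 110L),
    ellipse500g = synthSpec(500, "ellipse", aspect = 3.5, gradSpan = 3,
                            veinWidthPx = 2L, seed = 111L),
    teardrop500 = synthSpec(500, "teardrop", aspect = 3.5, skew = 0.2,
                            gradSpan = 3, gradChord = 2, veinWidthPx = 2L,
                            seed = 112L))
}
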