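#' @import methods
NULL

#' Grayscale wing image
#'
#' A 2-D raster of intensities in [0, 1] with optional physical pixel size.
#' Convention (fixed throughout the package): high intensity = wing membrane,
#' low intensity = vein or background; row 1 is the top of the image.
#'
#' @slot pixels Numeric matrix of intensities in [0, 1].
#' @slot pixelSize Physical length per pixel (arbitrary units); \code{NA_real_}
#'   when unknown.
#' @export
setClass("WingImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = NA_real_),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 2L || ncol(p) < 2L) return("image must be at least 2 x 2")
    rng <- range(p, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("intensities must lie in [0, 1]")
    TRUE
  })

#' Planar venation graph
#'
#' Vein junctions are vertices; vein segments between junctions are edges,
#' each carrying the polyline it follows, an optional vein radius (half-width)
#' and a flag marking wing-margin (boundary) edges.
#'
#' @slot vertices data.frame with columns \code{id} (0-based, contiguous),
#'   \code{x}, \code{y}.
#' @slot edges data.frame with columns \code{id}, \code{a}, \code{b}
#'   (endpoint vertex ids, distinct), \code{isBoundary} (logical),
#'   \code{radius} (numeric, \code{NA} when unmeasured).
#' @slot polylines list of \code{m x 2} coordinate matrices, one per edge,
#'   running from endpoint \code{a} to endpoint \code{b}.
#' @export
setClass("VeinGraph",
  representation(vertices = "data.frame", edges = "data.frame",
                 polylines = "list"),
  validity = function(object) {
    v <- object@vertices; e <- object@edges
    if (nrow(v) > 0L && !identical(as.integer(v$id), seq_len(nrow(v)) - 1L))
      return("vertex ids must be contiguous from 0")
    if (nrow(e) > 0L) {
      if (any(e$a == e$b)) return("edge endpoints must be distinct")
      if (any(!(e$a %in% v$id)) || any(!(e$b %in% v$id)))
        return("edge endpoints must reference vertex ids")
      if (length(object@polylines) != nrow(e))
        return("one polyline per edge required")
      ia <- match(e$a, v$id); ib <- match(e$b, v$id)
      heads <- t(vapply(object@polylines, function(p) p[1, ], numeric(2)))
      tails <- t(vapply(object@polylines,
                        function(p) p[nrow(p), ], numeric(2)))
      bad <- abs(heads[, 1] - v$x[ia]) > 1e-6 |
        abs(heads[, 2] - v$y[ia]) > 1e-6 |
        abs(tails[, 1] - v$x[ib]) > 1e-6 |
        abs(tails[, 2] - v$y[ib]) > 1e-6
      if (any(bad))
        return(sprintf("polyline of edge %d does not join its endpoints",
                       e$id[which(bad)[1]]))
    }
    TRUE
  })

#' Segmented wing
#'
#' A wing as a closed boundary contour, a tessellating set of vein-bounded
#' membrane domains, and the planar venation graph. Domains are stored
#' counterclockwise, the boundary clockwise (y-up plane), so signed areas
#' have fixed signs.
#'
#' @slot boundary \code{n x 2} matrix, closed simple contour (first vertex not
#'   repeated), clockwise.
#' @slot domains list of \code{n_i x 2} matrices, counterclockwise simple rings.
#' @slot domainIds integer vector of domain ids (parallel to \code{domains}).
#' @slot graph A \linkS4class{VeinGraph}.
#' @slot normalized logical; \code{TRUE} when the boundary area is 1.
#' @export
setClass("SegmentedWing",
  representation(boundary = "matrix", domains = "list",
                 domainIds = "integer", graph = "VeinGraph",
                 normalized = "logical"),
  validity = function(object) {
    if (nrow(object@boundary) < 3L) return("boundary needs >= 3 vertices")
    if (length(object@domains) < 1L) return("a wing must have >= 1 domain")
    if (length(object@domainIds) != length(object@domains))
      return("domainIds must parallel domains")
    aB <- polySignedArea(object@boundary)
    if (aB >= 0) return("boundary must be clockwise (negative signed area)")
    aD <- vapply(object@domains, polySignedArea, 0)
    if (any(aD <= 0)) return("domains must be counterclockwise")
    ratio <- sum(aD) / abs(aB)
    if (abs(ratio - 1) > 1e-2)
      return(sprintf("domain areas sum to %.4f of boundary area", ratio))
    if (isTRUE(object@normalized) && abs(abs(aB) - 1) > 1e-6)
      return("normalized wing must have boundary area 1")
    TRUE
  })

#' Label map from wing segmentation
#'
#' Integer per-pixel domain labels (0 = vein/background) aligned to a
#' \linkS4class{WingImage}, with front arrival times where propagation was run.
#'
#' @slot labels integer matrix; 0 = background/vein, k >= 1 = domain k.
#' @slot arrival numeric matrix of first-arrival times; \code{Inf} where no
#'   front arrived, \code{NA} when only thresholding has been performed.
#' @slot speedInv inverse front speed per pixel (same shape as labels), used
#'   for sub-pixel boundary refinement during polygonization; may be a
#'   0 x 0 matrix when unavailable.
#' @slot rimDist signed Euclidean distance to the wing outline (positive
#'   inside), for sub-pixel rim placement; may be 0 x 0.
#' @export
setClass("LabelMap",
  representation(labels = "matrix", arrival = "matrix",
                 speedInv = "matrix", rimDist = "matrix"),
  prototype(speedInv = matrix(0, 0, 0), rimDist = matrix(0, 0, 0)),
  validity = function(object) {
    if (!all(dim(object@labels) == dim(object@arrival)))
      return("labels and arrival must share dimensions")
    if (any(object@labels < 0)) return("labels must be nonnegative")
    lab <- object@labels > 0
    arr <- object@arrival
    if (!all(is.na(arr)) && any(lab & !is.finite(arr)))
      return("arrival must be finite wherever labels > 0")
    TRUE
  })

#' Boundary curvature profile
#'
#' Curvature kappa sampled along the oriented wing contour at arc-length
#' fractions s in [0, 1); s = 0 at the wing base, s = 0.5 near the tip.
#'
#' @slot s numeric, strictly increasing from 0.
#' @slot kappa numeric, nonnegative (absolute curvature).
#' @slot scaled logical; \code{TRUE} when kappa is multiplied by the total
#'   perimeter (dimensionless curvature).
#' @slot perimeter the contour perimeter used for scaling.
#' @export
setClass("CurvatureProfile",
  representation(s = "numeric", kappa = "numeric", scaled = "logical",
                 perimeter = "numeric"),
  validity = function(object) {
    if (length(object@s) != length(object@kappa))
      return("s and kappa must have equal length")
    if (length(object@s) && (object@s[1] != 0 || any(diff(object@s) <= 0)))
      return("s must start at 0 and be strictly increasing")
    if (any(object@kappa < 0)) return("kappa must be nonnegative")
    TRUE
  })

#' Community partition of a venation network
#'
#' @slot labels integer vector of 0-based community ids, one per node,
#'   contiguous from 0 in order of first appearance.
#' @slot Q Newman modularity of the partition.
#' @export
setClass("CommunityPartition",
  representation(labels = "integer", Q = "numeric"),
  validity = function(object) {
    l <- object@labels
    if (length(l) && !identical(sort(unique(l)), seq_len(max(l) + 1L) - 1L))
      return("community ids must be contiguous from 0")
    if (object@Q < -0.5 - 1e-9 || object@Q > 1 + 1e-9)
      return("Q out of range [-0.5, 1]")
    TRUE
  })

#' Proximal-distal trait trace
#'
#' Area-weighted mean domain area and circularity in equal-width bins along
#' the wing's proximal-distal (base-to-tip) axis, raw and Gaussian-smoothed.
#'
#' @slot nBins number of bins.
#' @slot binCenters bin midpoints on [0, 1] along the span.
#' @slot meanArea,meanCircularity raw per-bin weighted means (\code{NA} for
#'   empty bins).
#' @slot smoothedArea,smoothedCircularity Gaussian-smoothed series.
#' @slot binWeights total overlap weight per bin.
#' @slot sigma smoothing bandwidth in span units.
#' @export
setClass("PDTrace",
  representation(nBins = "integer", binCenters = "numeric",
                 meanArea = "numeric", meanCircularity = "numeric",
                 smoothedArea = "numeric", smoothedCircularity = "numeric",
                 binWeights = "numeric", sigma = "numeric"),
  validity = function(object) {
    n <- object@nBins
    lens <- c(length(object@binCenters), length(object@meanArea),
              length(object@meanCircularity), length(object@smoothedArea),
              length(object@smoothedCircularity), length(object@binWeights))
    if (any(lens != n)) return("all per-bin slots must have length nBins")
    TRUE
  })

#' Whole-wing shape statistics
#'
#' @slot P normalized perimeter (dimensionless, 0 for a unit-area circle).
#' @slot L scaled internal vein length (dimensionless; total internal vein
#'   length after area normalization).
#' @slot LOverP internal vein length divided by the actual boundary perimeter.
#' @export
setClass("ShapeStats",
  representation(P = "numeric", L = "numeric", LOverP = "numeric"),
  validity = function(object) {
    if (object@L < 0) return("L must be nonnegative")
    TRUE
  })
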