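#' @rdname SegmentedWing-class
#' @aliases boundary,SegmentedWing-method
setMethod("boundary", "SegmentedWing", function(x) x@boundary)

#' @rdname SegmentedWing-class
setMethod("domains", "SegmentedWing", function(x) x@domains)

#' @rdname SegmentedWing-class
setMethod("domainIds", "SegmentedWing", function(x) x@domainIds)

#' @rdname SegmentedWing-class
setMethod("veinGraph", "SegmentedWing", function(x) x@graph)

#' @rdname SegmentedWing-class
setMethod("isNormalized", "SegmentedWing", function(x) x@normalized)

#' @rdname SegmentedWing-class
setMethod("nDomains", "SegmentedWing", function(x) length(x@domains))

#' @rdname VeinGraph-class
setMethod("graphVertices", "VeinGraph", function(x) x@vertices)
#' @rdname VeinGraph-class
setMethod("graphVertices", "SegmentedWing", function(x) x@graph@vertices)
#' @rdname VeinGraph-class
setMethod("graphEdges", "VeinGraph", function(x) x@edges)
#' @rdname VeinGraph-class
setMethod("graphEdges", "SegmentedWing", function(x) x@graph@edges)
#' @rdname VeinGraph-class
setMethod("edgePolylines", "VeinGraph", function(x) x@polylines)
#' @rdname VeinGraph-class
setMethod("edgePolylines", "SegmentedWing", function(x) x@graph@polylines)

#' @rdname WingImage-class
setMethod("pixels", "WingImage", function(x) x@pixels)

#' @rdname LabelMap-class
setMethod("labelMatrix", "LabelMap", function(x) x@labels)
#' @rdname LabelMap-class
setMethod("arrivalTimes", "LabelMap", function(x) x@arrival)

#' @rdname CommunityPartition-class
setMethod("communityLabels", "CommunityPartition", function(x) x@labels)
#' @rdname CommunityPartition-class
setMethod("modularity", "CommunityPartition", function(x) x@Q)
#' @rdname CommunityPartition-class
setMethod("nCommunities", "CommunityPartition",
          function(x) length(unique(x@labels)))

setMethod("show", "WingImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("WingImage: %d x %d pixels, intensity range [%.3f, %.3f]\n",
              d[1], d[2], min(object@pixels), max(object@pixels)))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %g\n", object@pixelSize))
})

setMethod("show", "SegmentedWing", function(object) {
  cat(sprintf(
    "SegmentedWing: %d domains, %d graph vertices, %d edges%s\n",
    length(object@domains), nrow(object@graph@vertices),
    nrow(object@graph@edges),
    if (isTRUE(object@normalized)) " (area-normalized)" else ""))
  cat(sprintf("  boundary: %d vertices, area %.6g, perimeter %.6g\n",
              nrow(object@boundary), abs(polySignedArea(object@boundary)),
              polyPerimeter(object@boundary)))
})

setMethod("show", "LabelMap", function(object) {
  k <- max(object@labels)
  cat(sprintf("LabelMap: %d x %d, %d labeled region%s\n",
              nrow(object@labels), ncol(object@labels), k,
              if (k == 1) "" else "s"))
})

setMethod("show", "CurvatureProfile", function(object) {
  cat(sprintf(
    "CurvatureProfile: %d samples%s, kappa range [%.4g, %.4g]\n",
    length(object@s), if (object@scaled) " (perimeter-scaled)" else "",
    min(object@kappa), max(object@kappa)))
})

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d nodes, %d communities, Q = %.4f\n",
              length(object@labels), length(unique(object@labels)),
              object@Q))
})

setMethod("show", "PDTrace", function(object) {
  ne <- sum(!is.na(object@meanArea))
  cat(sprintf("PDTrace: %d bins (%d nonempty), sigma = %.4g\n",
              object@nBins, ne, object@sigma))
})

setMethod("show", "ShapeStats", function(object) {
  cat(sprintf("ShapeStats: P = %.6g, L = %.6g, L/P~ = %.6g\n",
              object@P, object@L, object@LOverP))
})
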