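#' @rdname SegmentedWing-class
#' @param x,object A package object.
#' @export
setGeneric("boundary", function(x) standardGeneric("boundary"))

#' @rdname SegmentedWing-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname SegmentedWing-class
#' @export
setGeneric("domainIds", function(x) standardGeneric("domainIds"))

#' @rdname SegmentedWing-class
#' @export
setGeneric("veinGraph", function(x) standardGeneric("veinGraph"))

#' @rdname SegmentedWing-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname SegmentedWing-class
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' @rdname VeinGraph-class
#' @param x A \linkS4class{VeinGraph} or \linkS4class{SegmentedWing}.
#' @export
setGeneric("graphVertices", function(x) standardGeneric("graphVertices"))

#' @rdname VeinGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname VeinGraph-class
#' @export
setGeneric("edgePolylines", function(x) standardGeneric("edgePolylines"))

#' @rdname WingImage-class
#' @param x A \linkS4class{WingImage} or \linkS4class{LabelMap}.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname LabelMap-class
#' @param x A \linkS4class{LabelMap}.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname LabelMap-class
#' @export
setGeneric("arrivalTimes", function(x) standardGeneric("arrivalTimes"))

#' @rdname CommunityPartition-class
#' @param x A \linkS4class{CommunityPartition}.
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname CommunityPartition-class
#' @export
setGeneric("modularity", function(x) standardGeneric("modularity"))

#' @rdname CommunityPartition-class
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))
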