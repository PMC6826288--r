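# Integer-CSV wing format, v1. Line-oriented, comma-separated, comments
# start with '#'. Records:
#   V,<id>,<x>,<y>         vertex (ids contiguous from 0; integer coords)
#   D,<id>,<i1>,...,<ik>   domain ring as vertex indices (implicitly closed;
#                          a trailing repeat of i1 is tolerated and stripped)
#   B,<i1>,...,<ik>        boundary ring (flagged record, exactly one)
#   E,<a>,<b>,<r>          optional vein radius r for the graph edge whose
#                          endpoints coincide with vertices a and b
# The venation graph is not serialized: it is rebuilt deterministically from
# the rings by shared-segment extraction, so a write/read round trip
# preserves topology exactly.

#' Read a segmented wing from an integer-CSV file
#'
#' Parses the package's integer-coordinate wing format (see the format
#' comment block in the source and the package vignette) and reconstructs
#' the full \linkS4class{SegmentedWing}, including the venation graph.
#' Self-intersection of rings is checked exhaustively for rings with up to
#' 2000 vertices; larger rings get the repeated-vertex check only.
#'
#' @param path Path to the CSV file.
#' @return A \linkS4class{SegmentedWing}; coordinates are preserved exactly
#'   as read (no normalization applied).
#' @seealso \code{\link{writeWingCsv}}
#' @export
readWingCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty wing file: ", path)
  toks <- strsplit(lines, ",", fixed = TRUE)
  tag <- vapply(toks, `[[`, "", 1L)
  bad <- which(!tag %in% c("V", "D", "B", "E"))
  if (length(bad))
    stop(sprintf("malformed record %d: unknown tag '%s'", bad[1], tag[bad[1]]))
  num <- function(tk, rec) {
    v <- suppressWarnings(as.numeric(tk[-1]))
    if (anyNA(v)) stop(sprintf("malformed record %d: non-numeric field", rec))
    v
  }
  vids <- integer(0); vx <- numeric(0); vy <- numeric(0)
  dids <- integer(0); drings <- list()
  bring <- NULL
  erows <- list()
  for (i in seq_along(toks)) {
    v <- num(toks[[i]], i)
    if (tag[i] == "V") {
      if (length(v) != 3L) stop(sprintf("malformed record %d: V needs id,x,y", i))
      vids <- c(vids, as.integer(v[1]))
      vx <- c(vx, v[2]); vy <- c(vy, v[3])
    } else if (tag[i] == "D") {
      if (length(v) < 4L)
        stop(sprintf("malformed record %d: D ring needs >= 3 vertices", i))
      idx <- as.integer(v[-1])
      if (length(idx) > 1L && idx[1] == idx[length(idx)]) idx <- idx[-length(idx)]
      if (anyDuplicated(idx))
        stop(sprintf("malformed record %d: ring repeats a non-terminal vertex", i))
      dids <- c(dids, as.integer(v[1]))
      drings[[length(drings) + 1L]] <- idx
    } else if (tag[i] == "B") {
      if (!is.null(bring)) stop("multiple B records")
      bring <- as.integer(v)
      if (length(bring) > 1L && bring[1] == bring[length(bring)])
        bring <- bring[-length(bring)]
    } else {
      if (length(v) != 3L) stop(sprintf("malformed record %d: E needs a,b,r", i))
      erows[[length(erows) + 1L]] <- v
    }
  }
  if (!length(vids)) stop("no V records in ", path)
  if (!length(drings)) stop("no D records in ", path)
  ord <- order(vids)
  if (!identical(vids[ord], seq_along(vids) - 1L))
    stop("vertex ids must be contiguous from 0")
  coords <- unname(cbind(vx, vy))[ord, , drop = FALSE]
  nv <- nrow(coords)
  rings <- vector("list", length(drings))
  for (k in seq_along(drings)) {
    idx <- drings[[k]]
    if (any(idx < 0L | idx >= nv))
      stop(sprintf("domain %d references unknown vertex", dids[k]))
    ring <- coords[idx + 1L, , drop = FALSE]
    if (nrow(ring) <= 2000L && ringSelfIntersects(ring))
      stop(sprintf("domain %d: ring is self-intersecting", dids[k]))
    if (abs(polySignedArea(ring)) < .Machine$double.eps * 10)
      stop(sprintf("domain %d has zero area", dids[k]))
    rings[[k]] <- ring
  }
  wing <- segmentedWing(rings, ids = dids, snapTol = 1e-9)
  if (!is.null(bring)) {
    if (any(bring < 0L | bring >= nv)) stop("B record references unknown vertex")
    aB <- abs(polySignedArea(coords[bring + 1L, , drop = FALSE]))
    aW <- wingArea(wing)
    if (abs(aB / aW - 1) > 1e-2)
      warning("B record disagrees with the boundary derived from domains")
  }
  if (length(erows)) {
    e <- graphEdges(wing); vtx <- graphVertices(wing)
    for (row in erows) {
      if (row[3] <= 0) stop("E record with nonpositive radius")
      ia <- which(abs(vtx$x - coords[row[1] + 1L, 1]) < 1e-9 &
                  abs(vtx$y - coords[row[1] + 1L, 2]) < 1e-9)
      ib <- which(abs(vtx$x - coords[row[2] + 1L, 1]) < 1e-9 &
                  abs(vtx$y - coords[row[2] + 1L, 2]) < 1e-9)
      if (length(ia) == 1L && length(ib) == 1L) {
        hit <- (e$a == vtx$id[ia] & e$b == vtx$id[ib]) |
               (e$a == vtx$id[ib] & e$b == vtx$id[ia])
        e$radius[hit] <- row[3]
      }
    }
    wing@graph@edges <- e
  }
  wing
}

#' Write a segmented wing to the integer-CSV format
#'
#' Coordinates are quantized to a caller-chosen grid (default 1, i.e. nearest
#' integer) and written as a shared vertex pool plus per-domain index rings,
#' a boundary ring record and optional per-edge radius records. The file is
#' readable by \code{\link{readWingCsv}}; the round trip preserves topology
#' exactly and coordinates within half a quantization step.
#'
#' @param wing A valid \linkS4class{SegmentedWing}.
#' @param path Output file path.
#' @param grid Quantization step for coordinates (use e.g. \code{1e-6} for
#'   wings already normalized to unit area).
#' @return Invisibly, \code{path}.
#' @export
writeWingCsv <- function(wing, path, grid = 1) {
  stopifnot(is(wing, "SegmentedWing"))
  if (grid <= 0) stop("grid must be positive")
  q <- function(m) round(m / grid) * grid
  pool <- new.env(hash = TRUE, parent = emptyenv())
  poolx <- numeric(0); pooly <- numeric(0)
  getId <- function(x, y) {
    k <- paste(format(x, digits = 15), format(y, digits = 15))
    id <- pool[[k]]
    if (is.null(id)) {
      id <- length(poolx)
      poolx[[id + 1L]] <<- x; pooly[[id + 1L]] <<- y
      pool[[k]] <- id
    }
    id
  }
  ringIdx <- function(ring) {
    rq <- q(ring)
    idx <- vapply(seq_len(nrow(rq)), function(i) getId(rq[i, 1], rq[i, 2]), 0L)
    idx <- idx[c(TRUE, diff(idx) != 0L)]
    if (length(idx) > 1L && idx[1] == idx[length(idx)]) idx <- idx[-length(idx)]
    if (length(idx) < 3L)
      stop("quantization grid too coarse: a ring collapsed")
    idx
  }
  dIdx <- lapply(domains(wing), ringIdx)
  bIdx <- ringIdx(boundary(wing))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines("# wingmorph wing format v1", con)
  fmt <- function(v) {
    if (grid >= 1) format(as.integer(round(v)), scientific = FALSE)
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  for (i in seq_along(poolx))
    writeLines(sprintf("V,%d,%s,%s", i - 1L, fmt(poolx[i]), fmt(pooly[i])), con)
  for (k in seq_along(dIdx))
    writeLines(paste0("D,", domainIds(wing)[k], ",",
                      paste(dIdx[[k]], collapse = ",")), con)
  writeLines(paste0("B,", paste(bIdx, collapse = ",")), con)
  e <- graphEdges(wing)
  if (nrow(e) && any(!is.na(e$radius))) {
    vtx <- graphVertices(wing)
    for (i in which(!is.na(e$radius))) {
      pa <- q(unlist(vtx[vtx$id == e$a[i], c("x", "y")]))
      pb <- q(unlist(vtx[vtx$id == e$b[i], c("x", "y")]))
      writeLines(sprintf("E,%d,%d,%s", getId(pa[1], pa[2]), getId(pb[1], pb[2]),
                         format(e$radius[i], digits = 15)), con)
    }
  }
  invisible(path)
}

#' Load a wing image
#'
#' Reads a PNG or TIFF raster as a \linkS4class{WingImage}. Multi-channel
#' images are converted to grayscale with Rec. 709 luminance weights
#' (0.2126 R + 0.7152 G + 0.0722 B); an alpha channel is ignored. Intensities
#' are clamped to [0, 1]; row 1 is the top of the image. Dark pixels are
#' veins/background, bright pixels membrane.
#'
#' @param path Path to a .png, .tif or .tiff file.
#' @param pixelSize Optional physical length per pixel.
#' @return A \linkS4class{WingImage}.
#' @export
loadWingImage <- function(path, pixelSize = NA_real_) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("unreadable or empty image: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           stop("unsupported image format: .", ext)),
    error = function(e) stop("failed to read image ", path, ": ",
                             conditionMessage(e)))
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    a <- if (nc >= 3L)
      0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    else a[, , 1]
  }
  a <- pmin(pmax(a, 0), 1)
  new("WingImage", pixels = a, pixelSize = pixelSize)
}
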