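# SegmentedWing construction. The boundary contour and venation graph are
# both derived canonically from the tessellating domain rings: after snapping
# shared vertices, every undirected ring segment appearing in exactly one
# ring is a wing-margin (boundary) segment, one appearing in two rings is an
# internal vein shared by neighbouring domains. Following the polygonal
# reconstruction used for real wings, every distinct ring vertex is a graph
# node and every unique ring segment a graph edge, so vein junctions,
# domain corners and margin corners all appear in the network.

#' Construct a segmented wing from domain rings
#'
#' Builds a \linkS4class{SegmentedWing} from the tessellating membrane-domain
#' polygons alone: the outer boundary and the venation graph are derived from
#' the shared-segment structure of the rings, so domains, boundary and graph
#' are always mutually consistent.
#'
#' @param domains list of \code{n x 2} coordinate matrices, one simple ring
#'   per domain (orientation immaterial; stored counterclockwise).
#' @param ids optional integer domain ids (default \code{0:(k-1)}).
#' @param snapTol vertices of different rings closer than this are fused.
#' @return A \linkS4class{SegmentedWing}.
#' @examples
#' tri1 <- cbind(c(0, 1, 1), c(0, 0, 1))
#' tri2 <- cbind(c(0, 1, 0), c(0, 1, 1))
#' w <- segmentedWing(list(tri1, tri2))  # unit square split by a diagonal
#' nDomains(w)
#' nrow(graphVertices(w))  # 4 corners
#' nrow(graphEdges(w))     # 4 sides + 1 diagonal
#' @export
segmentedWing <- function(domains, ids = NULL, snapTol = 1e-9) {
  if (!length(domains)) stop("a wing must have >= 1 domain")
  domains <- lapply(domains, function(r) {
    r <- dedupeRing(as.matrix(r))
    if (nrow(r) < 3L) stop("degenerate domain ring (< 3 distinct vertices)")
    if (polySignedArea(r) < 0) r[rev(seq_len(nrow(r))), , drop = FALSE] else r
  })
  if (is.null(ids)) ids <- seq_along(domains) - 1L
  st <- veinStructureFromRings(domains, snapTol = snapTol)
  new("SegmentedWing", boundary = st$boundary, domains = domains,
      domainIds = as.integer(ids), graph = st$graph,
      normalized = abs(abs(polySignedArea(st$boundary)) - 1) <= 1e-6)
}

#' Total wing area
#' @param wing A \linkS4class{SegmentedWing}.
#' @return The (positive) area enclosed by the boundary contour.
#' @export
wingArea <- function(wing) abs(polySignedArea(boundary(wing)))

# Shared-segment structure of a set of tessellating rings.
# Returns list(boundary = CW ring matrix, graph = VeinGraph).
veinStructureFromRings <- function(rings, snapTol = 1e-9) {
  allpts <- do.call(rbind, rings)
  sn <- snapVertices(allpts, tol = snapTol)
  coords <- sn$coords
  key <- paste(round(coords[, 1] / snapTol), round(coords[, 2] / snapTol))
  poolKey <- !duplicated(key)
  poolIdx <- match(key, key[poolKey])           # 1-based pool id per point
  pool <- coords[poolKey, , drop = FALSE]
  # rings as pool-id sequences
  off <- 0L
  ringIds <- vector("list", length(rings))
  for (i in seq_along(rings)) {
    n <- nrow(rings[[i]])
    seqi <- poolIdx[(off + 1L):(off + n)]
    off <- off + n
    seqi <- seqi[c(TRUE, diff(seqi) != 0L)]
    if (length(seqi) > 1L && seqi[1] == seqi[length(seqi)])
      seqi <- seqi[-length(seqi)]
    ringIds[[i]] <- seqi
  }
  # undirected segment multiset
  segA <- integer(0); segB <- integer(0)
  for (s in ringIds) {
    a <- s; b <- c(s[-1], s[1])
    segA <- c(segA, pmin(a, b)); segB <- c(segB, pmax(a, b))
  }
  skey <- paste(segA, segB)
  tab <- table(skey)
  if (any(tab > 2L))
    warning("some vein segments are shared by more than two domains")
  uniq <- !duplicated(skey)
  uA <- segA[uniq]; uB <- segB[uniq]
  cnt <- as.integer(tab[paste(uA, uB)])
  boundary <- assembleBoundary(uA[cnt == 1L], uB[cnt == 1L], pool)
  # graph: every pool vertex used by a ring; edges = unique segments
  usedIds <- sort(unique(c(uA, uB)))
  vmap <- integer(nrow(pool)); vmap[usedIds] <- seq_along(usedIds) - 1L
  ea <- vmap[uA]; eb <- vmap[uB]
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  ord <- order(lo, hi)
  edges <- data.frame(id = seq_along(uA) - 1L, a = lo[ord], b = hi[ord],
                      isBoundary = (cnt == 1L)[ord], radius = NA_real_)
  polylines <- lapply(seq_along(uA), function(i) {
    k <- ord[i]
    ids <- if (ea[k] <= eb[k]) c(uA[k], uB[k]) else c(uB[k], uA[k])
    pool[ids, , drop = FALSE]
  })
  vertices <- data.frame(id = seq_along(usedIds) - 1L,
                         x = pool[usedIds, 1], y = pool[usedIds, 2])
  graph <- new("VeinGraph", vertices = vertices, edges = edges,
               polylines = polylines)
  list(boundary = boundary, graph = graph)
}

# Assemble boundary loop(s) from count-1 segments; returns the largest loop
# oriented clockwise.
assembleBoundary <- function(a, b, pool) {
  if (!length(a)) stop("no boundary segments found")
  ids <- sort(unique(c(a, b)))
  deg <- tabulate(match(c(a, b), ids))
  if (any(deg != 2L))
    stop("wing boundary is not a single closed loop")
  # two neighbours per boundary vertex, integer-indexed
  n1 <- integer(length(ids)); n2 <- integer(length(ids))
  ia <- match(a, ids); ib <- match(b, ids)
  for (i in seq_along(ia)) {
    if (n1[ia[i]] == 0L) n1[ia[i]] <- ib[i] else n2[ia[i]] <- ib[i]
    if (n1[ib[i]] == 0L) n1[ib[i]] <- ia[i] else n2[ib[i]] <- ia[i]
  }
  visited <- logical(length(ids))
  loops <- list()
  for (start in seq_along(ids)) {
    if (visited[start]) next
    loop <- integer(length(ids))
    m <- 0L
    prev <- 0L; cur <- start
    repeat {
      m <- m + 1L
      loop[m] <- cur
      visited[cur] <- TRUE
      nxt <- if (n1[cur] != prev) n1[cur] else n2[cur]
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- ids[loop[seq_len(m)]]
  }
  areas <- vapply(loops, function(l) abs(polySignedArea(pool[l, , drop = FALSE])), 0)
  if (length(loops) > 1L)
    warning(sprintf("boundary has %d loops; keeping the largest", length(loops)))
  ring <- pool[loops[[which.max(areas)]], , drop = FALSE]
  if (polySignedArea(ring) > 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}
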