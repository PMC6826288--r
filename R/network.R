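# Venation-network analysis: adjacency construction (unweighted,
# inverse-length 1/L^n, and vein-resistance L/r^4 stored as conductance
# r^4/L), vein-radius interpolation from sparse measurements, Newman
# modularity and maximum-modularity community detection (exact enumeration
# for small graphs, fast-greedy agglomeration otherwise).

#' Collapse degree-2 vertices into vein chains
#'
#' The geometric graph of a \linkS4class{SegmentedWing} has a vertex at every
#' polygon corner. The venation NETWORK, by contrast, has a node at every
#' vein junction and one edge per vein connecting two junctions. This
#' function contracts all maximal degree-2 paths into single edges carrying
#' their full polylines (so lengths are preserved); a closed vein loop
#' without junctions is split at two anchor vertices.
#'
#' @param g A \linkS4class{VeinGraph} (or \linkS4class{SegmentedWing}).
#' @return A \linkS4class{VeinGraph} whose vertices are junctions.
#' @export
collapseChains <- function(g) {
  if (is(g, "SegmentedWing")) g <- veinGraph(g)
  stopifnot(is(g, "VeinGraph"))
  v <- graphVertices(g); e <- graphEdges(g)
  if (!nrow(e)) return(g)
  nb <- vector("list", nrow(v))            # incident edge ids per vertex
  for (k in seq_len(nrow(e))) {
    nb[[e$a[k] + 1L]] <- c(nb[[e$a[k] + 1L]], k)
    nb[[e$b[k] + 1L]] <- c(nb[[e$b[k] + 1L]], k)
  }
  deg <- lengths(nb)
  junction <- deg != 2L
  used <- logical(nrow(e))
  other <- function(k, vid) if (e$a[k] == vid) e$b[k] else e$a[k]
  chains <- list()
  walk <- function(v0, k0) {
    ids <- k0; used[k0] <<- TRUE
    cur <- other(k0, v0)
    while (!junction[cur + 1L]) {
      nxt <- setdiff(nb[[cur + 1L]], ids[length(ids)])
      if (length(nxt) != 1L || used[nxt]) break
      ids <- c(ids, nxt); used[nxt] <<- TRUE
      cur <- other(nxt, cur)
    }
    list(from = v0, to = cur, ids = ids)
  }
  for (j in which(junction)) {
    for (k in nb[[j]]) if (!used[k]) {
      chains[[length(chains) + 1L]] <- walk(j - 1L, k)
    }
  }
  while (any(!used)) {                     # junction-free cycles
    k0 <- which(!used)[1]
    v0 <- e$a[k0]
    cyc <- walk(v0, k0)                    # runs all the way round
    ids <- cyc$ids
    h <- length(ids) %/% 2L
    if (h < 1L) break
    # split into two arcs at v0 and the half-way vertex
    vid <- v0
    for (k in ids[seq_len(h)]) vid <- other(k, vid)
    mid <- vid
    chains[[length(chains) + 1L]] <- list(from = v0, to = mid,
                                          ids = ids[seq_len(h)])
    chains[[length(chains) + 1L]] <- list(from = mid, to = v0,
                                          ids = ids[(h + 1L):length(ids)])
  }
  ends <- sort(unique(unlist(lapply(chains, function(ch) c(ch$from, ch$to)))))
  vmap <- integer(nrow(v)); vmap[ends + 1L] <- seq_along(ends) - 1L
  pls <- lapply(chains, function(ch) {
    vid <- ch$from
    out <- NULL
    for (k in ch$ids) {
      pl <- g@polylines[[k]]
      if (e$a[k] != vid) pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
      out <- if (is.null(out)) pl else rbind(out[-nrow(out), , drop = FALSE], pl)
      vid <- other(k, vid)
    }
    out
  })
  isB <- vapply(chains, function(ch) all(e$isBoundary[ch$ids]), TRUE)
  rad <- vapply(chains, function(ch) {
    r <- e$radius[ch$ids]
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  }, 0)
  edges <- data.frame(id = seq_along(chains) - 1L,
                      a = vmap[vapply(chains, `[[`, 0L, "from") + 1L],
                      b = vmap[vapply(chains, `[[`, 0L, "to") + 1L],
                      isBoundary = isB, radius = rad)
  vertices <- data.frame(id = seq_along(ends) - 1L,
                         x = v$x[ends + 1L], y = v$y[ends + 1L])
  new("VeinGraph", vertices = vertices, edges = edges, polylines = pls)
}

#' Build a venation adjacency matrix
#'
#' Symmetric N x N matrix over graph vertices. Schemes: \code{"unweighted"}
#' sets M_ij = 1 for connected vertex pairs; \code{"inverse_length"} sets
#' M_ij = 1/L^n with L the vein (polyline) length between i and j and
#' n in \{1, 2\}; \code{"resistance"} treats each vein as a Poiseuille
#' resistor L/r^4 and stores the conductance r^4/L, so shorter and thicker
#' veins couple their junctions more strongly. Parallel veins between the
#' same junction pair combine as parallel conductances (weights add);
#' unweighted entries stay 0/1.
#'
#' @param x A \linkS4class{SegmentedWing} or \linkS4class{VeinGraph}.
#' @param scheme One of \code{"unweighted"}, \code{"inverse_length"},
#'   \code{"resistance"}.
#' @param n Exponent for the inverse-length scheme (1 or 2).
#' @param radii Optional per-edge radii (recycled against the edge table)
#'   for the resistance scheme; defaults to the graph's stored radii.
#' @param collapse Collapse degree-2 chains first (see
#'   \code{\link{collapseChains}}), so matrix rows are vein junctions.
#'   Default \code{TRUE} for a \linkS4class{SegmentedWing} (whose stored
#'   graph is the geometric polygon-corner graph) and \code{FALSE} for a
#'   \linkS4class{VeinGraph} supplied directly.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
buildAdjacency <- function(x, scheme = c("unweighted", "inverse_length",
                                         "resistance"),
                           n = 1, radii = NULL,
                           collapse = is(x, "SegmentedWing")) {
  scheme <- match.arg(scheme)
  g <- if (is(x, "SegmentedWing")) veinGraph(x) else x
  stopifnot(is(g, "VeinGraph"))
  if (collapse) g <- collapseChains(g)
  v <- graphVertices(g); e <- graphEdges(g)
  N <- nrow(v)
  if (N < 2L) stop("graph needs >= 2 vertices")
  if (!nrow(e)) stop("graph has no edges")
  if (!n %in% c(1, 2)) stop("exponent n must be 1 or 2")
  len <- vapply(edgePolylines(g), function(p) sum(sqrt(rowSums(diff(p)^2))), 0)
  w <- switch(scheme,
    unweighted = rep(1, nrow(e)),
    inverse_length = 1 / len^n,
    resistance = {
      r <- if (is.null(radii)) e$radius else rep_len(radii, nrow(e))
      if (anyNA(r))
        stop("resistance scheme needs a radius for every edge; ",
             "see interpolateRadii()")
      if (any(r <= 0)) stop("vein radii must be positive")
      r^4 / len
    })
  M <- matrix(0, N, N)
  ia <- e$a + 1L; ib <- e$b + 1L
  for (k in seq_len(nrow(e))) {
    if (scheme == "unweighted") {
      M[ia[k], ib[k]] <- 1
      M[ib[k], ia[k]] <- 1
    } else {
      M[ia[k], ib[k]] <- M[ia[k], ib[k]] + w[k]
      M[ib[k], ia[k]] <- M[ia[k], ib[k]]
    }
  }
  attr(M, "scheme") <- scheme
  M
}

#' Interpolate vein radii from sparse measurements
#'
#' Assigns each graph edge a vein radius by inverse-distance-weighted
#' interpolation (power 2) of measured (position, radius) samples, evaluated
#' at the edge's arc-length midpoint. A sample coinciding with a midpoint
#' wins outright; a single sample gives a constant radius field.
#'
#' @param samples data.frame with columns \code{x}, \code{y}, \code{r}
#'   (all radii positive).
#' @param x A \linkS4class{SegmentedWing} or \linkS4class{VeinGraph}.
#' @return Numeric vector of radii, one per edge, in edge-table order.
#' @export
interpolateRadii <- function(samples, x) {
  g <- if (is(x, "SegmentedWing")) veinGraph(x) else x
  stopifnot(is(g, "VeinGraph"))
  if (!nrow(samples)) stop("need >= 1 radius sample")
  if (any(samples$r <= 0)) stop("sample radii must be positive")
  mids <- t(vapply(edgePolylines(g), function(p) {
    d <- sqrt(rowSums(diff(p)^2))
    cs <- c(0, cumsum(d))
    half <- cs[length(cs)] / 2
    i <- findInterval(half, cs, rightmost.closed = TRUE)
    i <- min(i, nrow(p) - 1L)
    t <- if (d[i] > 0) (half - cs[i]) / d[i] else 0
    p[i, ] + t * (p[i + 1L, ] - p[i, ])
  }, numeric(2)))
  vapply(seq_len(nrow(mids)), function(k) {
    d2 <- (samples$x - mids[k, 1])^2 + (samples$y - mids[k, 2])^2
    hit <- d2 < 1e-24
    if (any(hit)) return(samples$r[which(hit)[1]])
    w <- 1 / d2
    sum(w * samples$r) / sum(w)
  }, 0)
}

#' Newman modularity of a partition
#'
#' Q = (1/2m) * sum_ij (M_ij - k_i k_j / 2m) * delta(c_i, c_j), with m the
#' total edge weight and k the weighted degrees; valid for weighted and
#' unweighted symmetric matrices. The all-in-one-community partition scores
#' exactly 0.
#'
#' @param M Symmetric nonnegative adjacency matrix with zero diagonal.
#' @param labels Community label per node (any vector coercible to factor).
#' @return Modularity Q.
#' @export
modularityScore <- function(M, labels) {
  N <- nrow(M)
  if (N < 1L || !any(M > 0)) stop("empty graph")
  if (length(labels) != N) stop("labels must cover all nodes")
  k <- rowSums(M)
  two_m <- sum(k)
  lab <- as.integer(factor(labels))
  same <- outer(lab, lab, `==`)
  B <- M - outer(k, k) / two_m
  sum(B[same]) / two_m
}

#' Maximum-modularity community detection
#'
#' Partitions the venation network into communities by maximizing Newman
#' modularity. Graphs with at most 12 nodes are solved exactly by
#' enumerating all set partitions; larger graphs use deterministic
#' fast-greedy agglomeration (igraph) with the dendrogram cut at maximum
#' modularity. Components are handled naturally; labels are 0-based and
#' contiguous in order of first appearance, so the result is invariant to
#' the algorithm's internal numbering.
#'
#' @param M Symmetric adjacency matrix (see \code{\link{buildAdjacency}}).
#' @param seed Integer RNG seed (the default algorithms are deterministic;
#'   the seed fixes any tie-breaking randomness).
#' @param method \code{"auto"} (exact for N <= 12, else greedy),
#'   \code{"exact"} or \code{"greedy"}.
#' @return A \linkS4class{CommunityPartition}; its \code{Q} slot equals
#'   \code{modularityScore(M, communityLabels(.))} and is never below the
#'   single-community score of 0.
#' @export
detectCommunities <- function(M, seed = 1L,
                              method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  N <- nrow(M)
  if (is.null(N) || N < 2L) stop("need >= 2 nodes")
  if (!isSymmetric(unname(M), tol = 1e-9)) stop("adjacency must be symmetric")
  if (method == "auto") method <- if (N <= 12L) "exact" else "greedy"
  if (method == "exact" && N > 12L)
    stop("exact enumeration limited to 12 nodes; use method = 'greedy'")
  lab <- if (method == "exact") {
    cpp_exact_modularity(unname(M))$labels
  } else {
    set.seed(as.integer(seed))
    g <- igraph::graph_from_adjacency_matrix(unname(M), mode = "undirected",
                                             weighted = TRUE)
    as.integer(igraph::membership(igraph::cluster_fast_greedy(g))) - 1L
  }
  lab <- relabelFirstAppearance(lab)
  Q <- modularityScore(M, lab)
  if (Q < 0) { # never worse than the trivial single community
    lab <- rep(0L, N)
    Q <- 0
  }
  new("CommunityPartition", labels = lab, Q = Q)
}

relabelFirstAppearance <- function(lab) {
  u <- unique(lab)
  match(lab, u) - 1L
}

#' Export an adjacency matrix
#'
#' Writes a dense CSV (one row per node) or an \code{i,j,weight} edge list
#' (0-based indices, i < j, nonzero entries only).
#'
#' @param M Adjacency matrix.
#' @param path Output file.
#' @param format \code{"dense"} or \code{"edgelist"}.
#' @return Invisibly, \code{path}.
#' @export
exportAdjacency <- function(M, path, format = c("edgelist", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(M, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                     weight = M[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
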