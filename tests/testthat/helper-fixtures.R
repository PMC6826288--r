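# Shared fixtures and independent oracles for the test suite.

# closed ring of a regular m-gon with given area
regularPolygon <- function(m, area = 1) {
  t <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  r <- sqrt(2 * area / (m * sin(2 * pi / m)))
  cbind(r * cos(t), r * sin(t))
}

squareRing <- function(side = 1, origin = c(0, 0)) {
  cbind(origin[1] + c(0, side, side, 0), origin[2] + c(0, 0, side, side))
}

# unit square split by its diagonal: the canonical two-triangle wing
diagonalSquareWing <- function() {
  segmentedWing(list(cbind(c(0, 1, 1), c(0, 0, 1)),
                     cbind(c(0, 1, 0), c(0, 1, 1))))
}

# hand-built VeinGraph: vertices df columns x, y; edges matrix of 0-based
# endpoint pairs (straight segments)
makeGraph <- function(xy, ed, radius = NA_real_) {
  v <- data.frame(id = seq_len(nrow(xy)) - 1L, x = xy[, 1], y = xy[, 2])
  e <- data.frame(id = seq_len(nrow(ed)) - 1L, a = ed[, 1], b = ed[, 2],
                  isBoundary = FALSE, radius = radius)
  pl <- lapply(seq_len(nrow(ed)), function(k)
    rbind(xy[ed[k, 1] + 1L, ], xy[ed[k, 2] + 1L, ]))
  new("VeinGraph", vertices = v, edges = e, polylines = pl)
}

# independent oracle: total length of segments shared by exactly two domain
# rings (coordinates rounded to 1e-7 for keying)
sharedEdgeLengthOracle <- function(wing) {
  keys <- character(0); lens <- numeric(0)
  for (ring in domains(wing)) {
    n <- nrow(ring)
    a <- ring; b <- ring[c(2:n, 1), , drop = FALSE]
    k1 <- paste(round(a[, 1], 7), round(a[, 2], 7))
    k2 <- paste(round(b[, 1], 7), round(b[, 2], 7))
    key <- ifelse(k1 < k2, paste(k1, k2), paste(k2, k1))
    keys <- c(keys, key)
    lens <- c(lens, sqrt(rowSums((b - a)^2)))
  }
  tab <- table(keys)
  shared <- names(tab)[tab == 2L]
  sum(lens[match(shared, keys)])
}

# independent oracle: all set partitions of 1..n (Bell-number enumeration)
allPartitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in allPartitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

bruteForceBestModularity <- function(M) {
  n <- nrow(M)
  best <- -Inf
  for (p in allPartitions(n)) {
    lab <- integer(n)
    for (k in seq_along(p)) lab[p[[k]]] <- k
    q <- modularityScore(M, lab)
    if (q > best) best <- q
  }
  best
}

# match recovered domains to ground truth by centroid after aligning the
# two wings on their boundary bounding-box centres; both wings normalized
matchDomains <- function(rec, truth) {
  recN <- normalizeArea(rec); truN <- normalizeArea(truth)
  ctr <- function(x) c(mean(range(boundary(x)[, 1])),
                       mean(range(boundary(x)[, 2])))
  dc <- sweep(t(vapply(domains(recN), polyCentroid, numeric(2))), 2, ctr(recN))
  tc <- sweep(t(vapply(domains(truN), polyCentroid, numeric(2))), 2, ctr(truN))
  m <- apply(dc, 1, function(p) which.min(colSums((t(tc) - p)^2)))
  list(map = m,
       recArea = vapply(domains(recN), function(r) abs(polySignedArea(r)), 0),
       truthArea = vapply(domains(truN), function(r) abs(polySignedArea(r)), 0))
}

# small disk image: bright disk of radius r on dark background
diskImage <- function(n = 81, r = 30, bright = 1, dark = 0) {
  img <- matrix(dark, n, n)
  cen <- (n + 1) / 2
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - cen)^2 + (j - cen)^2 <= r^2) img[i, j] <- bright
  new("WingImage", pixels = img)
}
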