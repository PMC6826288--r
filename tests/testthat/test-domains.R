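test_that("circularity and fractional area match closed forms", {
  # near-circular domain: isoperimetric equality
  wc <- segmentedWing(list(regularPolygon(1000, area = 1)))
  dm <- domainMetrics(wc)
  expect_equal(dm$circularity, 1, tolerance = 1e-4)
  expect_equal(dm$fractionalArea, 1)
  # square domain: c = pi/4
  ws <- normalizeArea(segmentedWing(list(squareRing(3))))
  expect_equal(domainMetrics(ws)$circularity, pi / 4, tolerance = 1e-12)
  # perimeter ratio is the inverse square root
  expect_equal(perimeterRatio(pi / 4), sqrt(4 / pi), tolerance = 1e-12)
  # fractional areas of a tessellation sum to 1
  w <- normalizeArea(generateSyntheticWing(
    synthSpec(200, "ellipse", aspect = 3, seed = 9)))
  expect_equal(sum(domainMetrics(w)$fractionalArea), 1, tolerance = 1e-6)
})

test_that("bin overlap fractions conserve every polygon's area", {
  w <- normalizeArea(generateSyntheticWing(
    synthSpec(50, "teardrop", aspect = 3, seed = 2)))
  f <- binOverlapFractions(w, 25)
  expect_equal(unname(colSums(f)), rep(1, nDomains(w)), tolerance = 1e-6)
  f2 <- binOverlapFractions(w, 7)
  expect_equal(unname(colSums(f2)), rep(1, nDomains(w)), tolerance = 1e-6)
  expect_error(binOverlapFractions(w, 1), "nBins")
})

test_that("slab clipping agrees with exact closed-form intersections", {
  # two-domain wing split exactly at mid-span: closed-form slab overlaps
  left <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  right <- cbind(c(2, 4, 4, 2), c(0, 0, 1, 1))
  w <- segmentedWing(list(left, right))
  f <- binOverlapFractions(w, 4, baseEnd = "left")
  # each rectangle spans exactly two of the four bins, half its area in each
  expect_equal(f[, 1], c(0.5, 0.5, 0, 0), tolerance = 1e-9)
  expect_equal(f[, 2], c(0, 0, 0.5, 0.5), tolerance = 1e-9)
  wN <- normalizeArea(w)
  tr <- pdTrace(wN, nBins = 4, baseEnd = "left")
  cW <- domainMetrics(wN)
  # bins left of the split carry domain 1's stats exactly
  expect_equal(tr@meanCircularity[1:2], rep(cW$circularity[1], 2),
               tolerance = 1e-9)
  expect_equal(tr@meanArea[1:2], rep(cW$area[1], 2), tolerance = 1e-9)
})

test_that("single-domain traces are constant and smoothing is convex", {
  w <- normalizeArea(segmentedWing(list(regularPolygon(256, area = 2))))
  tr <- pdTrace(w, nBins = 10)
  ne <- !is.na(tr@meanCircularity)
  dm <- domainMetrics(w)
  expect_equal(unique(round(tr@meanCircularity[ne], 12)),
               round(dm$circularity, 12))
  expect_equal(unique(round(tr@meanArea[ne], 12)), round(dm$area, 12))
  # smoothed series stay inside the raw range; weighted means are convex
  w2 <- normalizeArea(generateSyntheticWing(
    synthSpec(80, "ellipse", aspect = 3, seed = 13)))
  tr2 <- pdTrace(w2)
  dm2 <- domainMetrics(w2)
  expect_true(all(tr2@smoothedCircularity >= min(tr2@meanCircularity) - 1e-12,
                  na.rm = TRUE))
  expect_true(all(tr2@smoothedCircularity <= max(tr2@meanCircularity) + 1e-12,
                  na.rm = TRUE))
  expect_true(all(tr2@meanCircularity >= min(dm2$circularity) - 1e-12,
                  na.rm = TRUE))
  expect_true(all(tr2@meanCircularity <= max(dm2$circularity) + 1e-12,
                  na.rm = TRUE))
})

test_that("doubling the bin count and re-aggregating reproduces the trace", {
  w <- normalizeArea(generateSyntheticWing(
    synthSpec(60, "teardrop", aspect = 3, seed = 21)))
  dm <- domainMetrics(w)
  f50 <- binOverlapFractions(w, 50, baseEnd = "left")
  W50 <- sweep(f50, 2, dm$area, `*`)
  Wc <- W50[seq(1, 49, 2), ] + W50[seq(2, 50, 2), ]
  agg <- as.numeric(Wc %*% dm$circularity) / rowSums(Wc)
  tr <- pdTrace(w, nBins = 25, baseEnd = "left")
  expect_equal(agg, tr@meanCircularity, tolerance = 1e-6)
})

test_that("a uniform tessellation of an ellipse has a flat circularity trace", {
  w <- normalizeArea(generateSyntheticWing(
    synthSpec(200, "ellipse", aspect = 3, seed = 31)))
  tr <- pdTrace(w, baseEnd = "left")
  sm <- tr@smoothedCircularity[!is.na(tr@smoothedCircularity)]
  expect_lt(max(sm) - min(sm), 0.15)
})
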