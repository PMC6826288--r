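test_that("area normalization is exact, idempotent and scale-invariant", {
  w <- segmentedWing(list(squareRing(2)))
  wN <- normalizeArea(w)
  expect_equal(wingArea(wN), 1, tolerance = 1e-12)
  expect_equal(max(abs(boundary(normalizeArea(wN)) - boundary(wN))), 0,
               tolerance = 1e-12)
  # dimensionless statistics identical under a 1000x pre-scaling
  w2 <- generateSyntheticWing(synthSpec(20, "ellipse", aspect = 3, seed = 5))
  big <- w2
  big@boundary <- big@boundary * 1000
  big@domains <- lapply(big@domains, function(r) r * 1000)
  big@graph@vertices$x <- big@graph@vertices$x * 1000
  big@graph@vertices$y <- big@graph@vertices$y * 1000
  big@graph@polylines <- lapply(big@graph@polylines, function(p) p * 1000)
  s1 <- internalVeinLength(w2); s2 <- internalVeinLength(big)
  expect_equal(s1@P, s2@P, tolerance = 1e-9)
  expect_equal(s1@L, s2@L, tolerance = 1e-9)
  expect_equal(s1@LOverP, s2@LOverP, tolerance = 1e-9)
  c1 <- domainMetrics(w2)$circularity
  c2 <- domainMetrics(big)$circularity
  expect_equal(c1, c2, tolerance = 1e-9)
  expect_error(normalizeArea(segmentedWing(list(squareRing(1e-200)))))
})

test_that("contour orientation is clockwise from the leftmost base point", {
  sq <- squareRing(1)                      # counterclockwise input
  oc <- orientContour(sq)
  expect_lt(polySignedArea(oc), 0)         # clockwise
  expect_equal(oc[1, 1], min(oc[, 1]))     # starts at leftmost x
  expect_equal(oc[1, 2], min(oc[oc[, 1] == min(oc[, 1]), 2]))  # lowest y tie
  # horizontal 2:1 ellipse: s = 0.5 lands at the far (tip) vertex
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  ell <- cbind(2 * cos(th), sin(th))
  oc2 <- orientContour(ell)
  rs <- wingmorph:::resampleContour(oc2, 1000)
  tip <- rs[501, ]                         # s = 0.5
  expect_equal(tip[1], max(oc2[, 1]), tolerance = 0.02)
  expect_equal(tip[2], 0, tolerance = 0.02)
  # bow-tie contour is rejected
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(orientContour(bow), "simple")
})

test_that("three-point circle fit reproduces exact circles", {
  # Kasa fit through exact circle samples recovers 1/R to 1e-9
  for (R in c(0.35, 1, 12)) {
    th <- c(0.3, 1.7, 4.1)
    fit <- fitCircleKasa(cbind(3 + R * cos(th), -2 + R * sin(th)))
    expect_equal(fit$radius, R, tolerance = 1e-9)
    expect_equal(fit$center, c(3, -2), tolerance = 1e-9)
  }
  expect_equal(fitCircleKasa(cbind(0:2, 0:2))$radius, Inf)
})

test_that("curvature profile matches closed forms on circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  for (R in c(0.1, 1, 10)) {
    cp <- curvatureProfile(cbind(R * cos(th), R * sin(th)), scaled = TRUE)
    expect_lt(max(abs(cp@kappa - 2 * pi)) / (2 * pi), 1e-3)
  }
  # 2:1 ellipse extrema: max a/b^2, min b/a^2 (small window so the
  # finite-window bias of the 3-point fit stays below the tolerance)
  ell <- cbind(2 * cos(th), sin(th))
  cp <- curvatureProfile(ell, window = 0.005, scaled = FALSE, nSamples = 2000)
  expect_equal(max(cp@kappa), 2, tolerance = 0.01)
  expect_equal(min(cp@kappa), 0.25, tolerance = 0.01)
  # straight sides of a long rounded rectangle are flat
  rr <- rbind(cbind(seq(-5, 5, length.out = 200), -1),
              cbind(5 + cos(seq(-pi / 2, pi / 2, length.out = 100)),
                    sin(seq(-pi / 2, pi / 2, length.out = 100))),
              cbind(seq(5, -5, length.out = 200), 1),
              cbind(-5 - cos(seq(-pi / 2, pi / 2, length.out = 100)),
                    -sin(seq(-pi / 2, pi / 2, length.out = 100))))
  cpr <- curvatureProfile(rr, window = 0.01, scaled = FALSE)
  mid <- cpr@s > 0.05 & cpr@s < 0.15       # well inside a straight side
  expect_lt(max(cpr@kappa[mid]), 1e-6)
  expect_error(curvatureProfile(ell, window = 0.5), "window")
})

test_that("curvature is symmetric for mirror-symmetric contours", {
  th <- seq(0, 2 * pi, length.out = 1501)[-1501]
  ell <- cbind(2 * cos(th), sin(th))
  cp <- curvatureProfile(orientContour(ell), window = 0.02, nSamples = 1000)
  k <- cp@kappa
  mirrored <- c(k[1], rev(k[-1]))          # kappa(s) vs kappa(1 - s)
  expect_equal(k, mirrored, tolerance = 1e-2)
})

test_that("normalized perimeter matches closed forms and the isoperimetric law", {
  expect_equal(normalizedPerimeter(squareRing(1)), 4 - 2 * sqrt(pi),
               tolerance = 1e-12)
  rect <- cbind(c(0, 8, 8, 0), c(0, 0, 2, 2))          # 4:1 rectangle
  expect_equal(normalizedPerimeter(rect), 5 - 2 * sqrt(pi),
               tolerance = 1e-12)
  expect_equal(normalizedPerimeter(regularPolygon(10000, area = 1)), 0,
               tolerance = 1e-3)
  # P >= 0 and strictly increasing along unit-area ellipses of growing aspect
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  P <- vapply(c(1, 1.5, 2, 3, 5, 8), function(a) {
    ring <- cbind(a * cos(th), sin(th) / a) / sqrt(pi)
    normalizedPerimeter(ring)
  }, 0)
  expect_true(all(P > -1e-6))
  expect_true(all(diff(P) > 0))
  expect_error(normalizedPerimeter(cbind(c(0, 1, 2), c(0, 0, 0))),
               "degenerate")
})

test_that("internal vein length subtracts the perimeter from the skeleton", {
  w <- diagonalSquareWing()
  s <- internalVeinLength(w)
  expect_equal(s@L, sqrt(2), tolerance = 1e-9)
  expect_equal(s@LOverP, sqrt(2) / 4, tolerance = 1e-9)
  expect_equal(s@P, 4 - 2 * sqrt(pi), tolerance = 1e-9)
  # circular single-domain wing sits at the morphospace origin
  w0 <- segmentedWing(list(regularPolygon(10000, area = 1)))
  s0 <- internalVeinLength(w0)
  expect_lt(abs(s0@P), 1e-3)
  expect_equal(s0@L, 0)
  # synthetic tessellation: matches the independent shared-edge oracle
  wt <- normalizeArea(generateSyntheticWing(
    synthSpec(40, "teardrop", aspect = 3, seed = 11)))
  st <- internalVeinLength(wt)
  expect_equal(st@L, sharedEdgeLengthOracle(wt), tolerance = 1e-6)
})
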