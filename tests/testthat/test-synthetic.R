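test_that("generation is deterministic per seed and hits the target count", {
  sp <- synthSpec(200, "ellipse", aspect = 3, seed = 42)
  w1 <- generateSyntheticWing(sp)
  w2 <- generateSyntheticWing(sp)
  expect_identical(domains(w1), domains(w2))
  expect_equal(nDomains(w1), 200L)
  expect_equal(sum(domainMetrics(normalizeArea(w1))$fractionalArea), 1,
               tolerance = 1e-6)
  w3 <- generateSyntheticWing(synthSpec(200, "ellipse", aspect = 3,
                                        seed = 43))
  expect_false(identical(domains(w1), domains(w3)))
  # generation does not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateSyntheticWing(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a single-domain circular wing sits at the morphospace origin", {
  w <- generateSyntheticWing(synthSpec(1, "circle",
                                       boundaryPoints = 10000L))
  s <- internalVeinLength(w)
  expect_lt(abs(s@P), 1e-3)
  expect_equal(s@L, 0)
})

test_that("spec validation rejects impossible requests", {
  expect_error(synthSpec(0), "nDomains")
  expect_error(synthSpec(5, aspect = -1), "aspect")
  expect_error(synthSpec(5, skew = 1), "skew")
  expect_error(synthSpec(5, veinWidthPx = 0), "veinWidthPx")
  # more domains than separated seeds can fit
  expect_error(generateSyntheticWing(synthSpec(300, "circle",
                                               boundaryPoints = 16L)),
               "infeasible")
})

test_that("rasterization is testably binary and resolution-checked", {
  w <- generateSyntheticWing(synthSpec(2, "ellipse", aspect = 2, seed = 1))
  img <- rasterizeWing(w, veinWidthPx = 3, rasterSpanPx = 600)
  px <- pixels(img)
  expect_true(all(px %in% c(0, 0.05, 1)))
  expect_equal(max(labelMatrix(thresholdComponents(img, 0.5))), 2L)
  # dark-pixel count strictly increases with vein width
  darks <- vapply(c(2, 3, 5), function(vw)
    sum(pixels(rasterizeWing(w, vw, 600)) < 0.5), 0)
  expect_true(all(diff(darks) > 0))
  expect_error(rasterizeWing(w, veinWidthPx = 10, rasterSpanPx = 50),
               "too small")
  # sub-resolution tessellation is refused
  wd <- generateSyntheticWing(synthSpec(400, "ellipse", aspect = 3,
                                        seed = 2))
  expect_error(rasterizeWing(wd, veinWidthPx = 3, rasterSpanPx = 300),
               "resolution")
})

test_that("the skeleton length of generated wings matches the shared-edge oracle", {
  for (seed in c(5, 6)) {
    w <- normalizeArea(generateSyntheticWing(
      synthSpec(60, "teardrop", aspect = 3, seed = seed)))
    s <- internalVeinLength(w)
    expect_equal(s@L, sharedEdgeLengthOracle(w), tolerance = 1e-6)
  }
})

test_that("a tipward density gradient shrinks distal domains", {
  w <- normalizeArea(generateSyntheticWing(
    synthSpec(200, "ellipse", aspect = 3.5, gradSpan = 3,
              veinWidthPx = 2L, seed = 108L)))
  tr <- pdTrace(w, baseEnd = "left")
  v <- tr@smoothedArea[5:20]
  expect_true(all(diff(v) < 0))
})

test_that("the fixture battery is complete and generable", {
  battery <- fixtureBattery()
  expect_length(battery, 12L)
  counts <- vapply(battery, `[[`, 0L, "nDomains")
  expect_equal(range(counts), c(1L, 500L))
  shapes <- unique(vapply(battery, `[[`, "", "boundary"))
  expect_setequal(shapes, c("circle", "ellipse", "teardrop"))
  expect_true(any(vapply(battery, `[[`, 0, "gradSpan") > 1))
  expect_true(any(vapply(battery, `[[`, 0, "gradChord") > 1))
  for (sp in battery[c("circle1", "ellipse5", "teardrop10")]) {
    w <- generateSyntheticWing(sp)
    expect_equal(nDomains(w), sp$nDomains)
  }
})
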