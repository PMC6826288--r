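test_that("thresholding separates membrane components", {
  img <- new("WingImage", pixels = {
    m <- matrix(0, 40, 61)
    m[5:35, 5:28] <- 1                      # bright block
    m[5:35, 32:56] <- 1                     # second block, 3-px dark stripe
    m
  })
  lm <- thresholdComponents(img, 0.5)
  expect_equal(max(labelMatrix(lm)), 2L)
  expect_true(all(is.na(arrivalTimes(lm))))
  # uniformly dark image has no components
  dark <- new("WingImage", pixels = matrix(0.1, 10, 10))
  expect_equal(max(labelMatrix(thresholdComponents(dark, 0.5))), 0L)
  # small components fall below minSize
  sp <- new("WingImage", pixels = {
    m <- matrix(0, 20, 20); m[3:12, 3:12] <- 1; m[16:17, 16:17] <- 1; m
  })
  expect_equal(max(labelMatrix(thresholdComponents(sp, 0.5, minSize = 25))),
               1L)
  expect_error(thresholdComponents(dark, 1.5), "threshold")
})

test_that("fronts from one seed fill a uniform bright disk", {
  img <- diskImage(n = 81, r = 30)
  lm <- propagateFronts(img)
  lab <- labelMatrix(lm)
  expect_equal(max(lab), 1L)
  # every thresholded disk pixel carries the label
  expect_true(all(lab[pixels(img) > 0.5] == 1L))
})

test_that("travel time in uniform intensity matches distance over speed", {
  for (v in c(1, 0.6)) {
    img <- new("WingImage", pixels = matrix(v, 61, 61))
    lm <- propagateFronts(img, seeds = cbind(31L, 31L), threshold = v / 2)
    arr <- arrivalTimes(lm)
    speed <- 0.001 + 0.999 * v^4
    for (d in c(10, 20)) {
      expect_equal(arr[31, 31 + d], d / speed, tolerance = 0.05)   # axial
      expect_equal(arr[31 + d, 31 + d], sqrt(2) * d / speed,
                   tolerance = 0.05)                               # diagonal
      expect_equal(arr[31 + round(d / 2), 31 + d],
                   sqrt(1.25) * d / speed, tolerance = 0.05)       # oblique
    }
  }
})

test_that("two fronts meet within one pixel of a dark ridge midline", {
  m <- matrix(0.05, 50, 81)
  m[, 1:39] <- 1; m[, 43:81] <- 1           # ridge in columns 40..42
  img <- new("WingImage", pixels = m)
  lm <- propagateFronts(img)
  lab <- labelMatrix(lm)
  expect_equal(max(lab), 2L)
  # transition column per row (last pixel of the left front's label),
  # measured on rows inside the silhouette
  lleft <- lab[25, 10]
  rows <- which(rowSums(lab == lleft) > 0 & rowSums(lab == 3 - lleft) > 0)
  trans <- vapply(rows, function(r) max(which(lab[r, ] == lleft)), 0L)
  expect_true(all(abs(trans - 41) <= 1))
})

test_that("seed validation rejects duplicates and misplaced seeds", {
  img <- diskImage(n = 61, r = 20)
  expect_error(propagateFronts(img, seeds = cbind(c(31L, 33L), c(31L, 33L))),
               "same membrane component")
  expect_error(propagateFronts(img, seeds = cbind(2L, 2L)),
               "not in a membrane component")
  dark <- new("WingImage", pixels = matrix(0, 30, 30))
  expect_error(propagateFronts(dark), "no membrane")
})

test_that("polygonization recovers abutting rectangles with a shared edge", {
  lab <- matrix(0L, 20, 30)
  lab[5:15, 4:14] <- 1L
  lab[5:15, 15:26] <- 2L
  lm <- new("LabelMap", labels = lab, arrival = matrix(1, 20, 30))
  w <- polygonizeLabels(lm)
  expect_equal(nDomains(w), 2L)
  expect_equal(nrow(graphVertices(w)), 6L)
  # shared edge is stored once and the tessellation is exact
  expect_equal(sum(!graphEdges(w)$isBoundary), 1L)
  areas <- vapply(domains(w), function(r) abs(polySignedArea(r)), 0)
  expect_equal(sum(areas), wingArea(w), tolerance = 1e-9)
  expect_equal(areas, c(11 * 11, 11 * 12))
  expect_error(polygonizeLabels(new("LabelMap",
                                    labels = matrix(0L, 5, 5),
                                    arrival = matrix(NA_real_, 5, 5))),
               "empty")
})

test_that("polygon area matches pixel count for convex and non-convex labels", {
  # disk
  img <- diskImage(n = 101, r = 40)
  lab <- labelMatrix(thresholdComponents(img, 0.5))
  lm <- new("LabelMap", labels = lab, arrival = matrix(1, 101, 101))
  w <- polygonizeLabels(lm)
  a <- abs(polySignedArea(domains(w)[[1]]))
  expect_equal(a, sum(lab == 1L), tolerance = 0.02 * sum(lab == 1L))
  # U shape (non-convex)
  u <- matrix(0L, 40, 40)
  u[5:35, 5:12] <- 1L; u[5:35, 28:35] <- 1L; u[28:35, 5:35] <- 1L
  lmu <- new("LabelMap", labels = u, arrival = matrix(1, 40, 40))
  wu <- polygonizeLabels(lmu)
  au <- abs(polySignedArea(domains(wu)[[1]]))
  expect_equal(au, sum(u == 1L), tolerance = 0.02 * sum(u == 1L))
  ring <- domains(wu)[[1]]
  expect_false(wingmorph:::ringSelfIntersects(ring))
})

test_that("segmentation is deterministic for fixed image and seeds", {
  w <- generateSyntheticWing(synthSpec(20, "ellipse", aspect = 3, seed = 3))
  img <- rasterizeWing(w, veinWidthPx = 3, rasterSpanPx = 500)
  l1 <- propagateFronts(img)
  l2 <- propagateFronts(img)
  expect_identical(labelMatrix(l1), labelMatrix(l2))
  expect_identical(arrivalTimes(l1), arrivalTimes(l2))
  w1 <- segmentWing(img)
  w2 <- segmentWing(img)
  expect_identical(domains(w1), domains(w2))
})

test_that("fronts meet where arrival times balance across the boundary", {
  w <- generateSyntheticWing(synthSpec(12, "ellipse", aspect = 2, seed = 8))
  img <- rasterizeWing(w, veinWidthPx = 3, rasterSpanPx = 420)
  lm <- propagateFronts(img)
  lab <- labelMatrix(lm); arr <- arrivalTimes(lm)
  inv <- lm@speedInv
  H <- nrow(lab); W <- ncol(lab)
  sel <- which(lab[, -W] != lab[, -1] & lab[, -W] > 0 & lab[, -1] > 0,
               arr.ind = TRUE)
  # arrival-time difference across the meeting line is at most one local step
  step <- 0.5 * (inv[sel] + inv[cbind(sel[, 1], sel[, 2] + 1L)])
  gap <- abs(arr[sel] - arr[cbind(sel[, 1], sel[, 2] + 1L)])
  expect_true(all(gap <= step * (1 + 1e-9)))
})
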