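test_that("traces descend to GM and ascend to WM on the harmonic column", {
  lab <- columnLabels(3)
  f <- solveLaplace(lab, relTol = 1e-9)
  tg <- traceToGM(f, lab, c(2, 2, 3))
  expect_identical(tg$status, "ok")
  expect_equal(tg$endpoint, c(2, 2, 1))
  expect_identical(nrow(tg$path), 3L)          # origin, 75-voxel, GM
  expect_true(all(diff(tg$psiTrace) < 0))      # strictly decreasing
  tw <- traceToWM(f, lab, c(2, 2, 3))
  expect_identical(tw$status, "ok")
  expect_equal(tw$endpoint, c(2, 2, 5))
  expect_true(all(diff(tw$psiTrace) > 0))
  # origin face-adjacent to WM: single step
  tw2 <- traceToWM(f, lab, c(2, 2, 4))
  expect_identical(tw2$steps, 1L)
  expect_error(traceToGM(f, lab, c(1, 1, 1)), "contract")
})

test_that("each step selects the extreme-potential neighbor (the 67 example)", {
  lab <- brainVolume(array(4L, c(3, 3, 3)), role = "label")
  f <- initializePotential(lab)
  psi <- array(100, c(3, 3, 3))
  psi[1, 1, 1] <- 67          # unique minimum in the neighborhood
  psi[3, 3, 3] <- 130
  f@psi@data <- psi
  tg <- traceToGM(f, lab, c(2, 2, 2))
  expect_equal(tg$path[2, ], c(1, 1, 1))   # steps to the 67-valued voxel
  tw <- traceToWM(f, lab, c(2, 2, 2))
  expect_equal(tw$path[2, ], c(3, 3, 3))
})

test_that("the WM-ward ascent follows increasing potentials to the boundary", {
  # illustrative ascent 100 -> 126 -> 140 -> 150 (WM)
  lab <- array(0L, c(3, 3, 4))
  lab[2, 2, ] <- c(4L, 4L, 4L, 3L)
  labv <- brainVolume(lab, role = "label")
  f <- initializePotential(labv)
  f@psi@data[2, 2, ] <- c(100, 126, 140, 150)
  tw <- traceToWM(f, labv, c(2, 2, 1))
  expect_identical(tw$status, "ok")
  expect_equal(tw$psiTrace, c(100, 126, 140, 150))
  expect_equal(tw$endpoint, c(2, 2, 4))
})

test_that("a flat plateau stalls the trace instead of cycling or looping", {
  lab <- brainVolume(array(4L, c(3, 3, 3)), role = "label")
  f <- initializePotential(lab)      # all GWB voxels at exactly 100
  tg <- traceToGM(f, lab, c(2, 2, 2))
  expect_identical(tg$status, "gm_unreachable")
  tw <- traceToWM(f, lab, c(2, 2, 2))
  expect_identical(tw$status, "wm_unreachable")
  # strictly monotone stepping makes a revisit impossible, so no path can be
  # longer than the number of in-field voxels
  expect_lte(nrow(tg$path), sum(volData(lab) > 0L))
})

test_that("width conventions match world-geometry hand calculations", {
  expect_equal(widthAt(c(1, 1, 2), c(1, 1, 1), c(1, 1, 3)), 2.0)
  expect_equal(widthAt(c(1, 1, 2), c(1, 1, 1), c(1, 1, 3),
                       mode = "halfpath-mean"), 1.0)
  sp <- c(0.8594, 0.8594, 0.9)
  expect_equal(widthAt(c(1, 1, 1), c(1, 1, 1), c(2, 2, 2), spacing = sp),
               sqrt(sum(sp^2)), tolerance = 1e-12)
  expect_equal(sqrt(sum(sp^2)), 1.511, tolerance = 1e-3)
  expect_error(widthAt(c(1, 1, 1), c(2, 2, 2), c(2, 2, 2)), "degenerate")
})

test_that("the width map recovers slab geometry and lesion thickening", {
  slab <- slabLabels(10, 10, bandLayers = 3, gmLayers = 3, wmLayers = 3)
  f <- solveLaplace(slab)
  wm <- computeWidthMap(f, slab)
  wArr <- volData(widthVolume(wm))
  inner <- wArr[3:8, 3:8, 4:6]
  expect_true(all(abs(inner - 4.0) < 1e-9))   # GM through 3 band voxels to WM
  expect_true(all(wArr[volData(slab) != 4L] == 0))
  # thickened central patch: patch widths exceed surround widths
  ph <- slabPhantom(shape = c(24, 24, 24), gwbThicknessMm = 3, csfMm = 0,
                    tissueSds = c(0, 0, 0),
                    lesion = list(radiusMm = 6, multiplier = 2), seed = 1)
  f2 <- solveLaplace(ph@truthLabels)
  wm2 <- computeWidthMap(f2, ph@truthLabels)
  les <- regionStats(wm2, ph@lesionMask)
  nonles <- volData(ph@lesionMask) == 0L
  sur <- regionStats(wm2, brainVolume(array(as.integer(nonles), dim(ph@lesionMask)),
                                      role = "mask"))
  expect_gt(les$mean, sur$mean)
  # away from the rim the doubled band measures 6 voxels + 2 endpoints;
  # rim voxels shortcut laterally toward the thinner surround
  ctr <- which(volData(ph@lesionMask)[12, 12, ] == 1L)
  wCtr <- unname(volData(widthVolume(wm2))[12, 12, ctr[3]])
  expect_gte(wCtr, 7.0)           # 6-voxel band + 2 endpoints...
  expect_lte(wCtr, sqrt(51))      # ...up to one voxel of lateral drift
  expect_equal(les$max, 7.0, tolerance = 0.15)
})

test_that("an empty GWB set yields an all-zero width map with empty stats", {
  slab <- slabLabels(4, 4, bandLayers = 1)
  f <- solveLaplace(slab)
  noGwb <- volData(slab)
  noGwb[noGwb == 4L] <- 2L
  wm <- computeWidthMap(f, brainVolume(noGwb, role = "label"))
  expect_true(all(volData(widthVolume(wm)) == 0))
  expect_identical(widthStats(wm)$n, 0L)
})

test_that("paths are monotone, terminate, and the map is deterministic", {
  ph <- shellPhantom(shape = c(28, 28, 28), wmRadiusMm = 5, gwbThicknessMm = 3,
                     gmThicknessMm = 4, tissueSds = c(0, 0, 0), seed = 1)
  lab <- ph@truthLabels
  f <- solveLaplace(lab)
  gwbIdx <- which(volData(lab) == 4L, arr.ind = TRUE)
  maxSteps <- sum(dim(lab))
  set.seed(3)
  for (r in sample(nrow(gwbIdx), 25)) {
    tg <- traceToGM(f, lab, gwbIdx[r, ])
    tw <- traceToWM(f, lab, gwbIdx[r, ])
    expect_identical(tg$status, "ok")
    expect_identical(tw$status, "ok")
    expect_true(all(diff(tg$psiTrace) < 0))
    expect_true(all(diff(tw$psiTrace) > 0))
    expect_lte(tg$steps, maxSteps)
    expect_lte(tw$steps, maxSteps)
  }
  a <- computeWidthMap(f, lab)
  b <- computeWidthMap(f, lab)
  expect_identical(volData(widthVolume(a)), volData(widthVolume(b)))
  expect_identical(volData(statusVolume(a)), volData(statusVolume(b)))
})

test_that("width is recovered across thicknesses and under in-plane rotation", {
  means <- numeric(0)
  for (w in c(2, 4)) {
    ph <- slabPhantom(shape = c(16, 16, 24), gwbThicknessMm = w, csfMm = 0,
                      tissueSds = c(0, 0, 0), seed = w)
    f <- solveLaplace(ph@truthLabels)
    s <- widthStats(computeWidthMap(f, ph@truthLabels))
    expect_gte(s$mean, w)
    expect_lte(s$mean, w + 2)
    means <- c(means, s$mean)
  }
  expect_true(all(diff(means) > 0))
  # slab rotated 45 degrees in-plane: mean within 15% of the aligned mean
  n <- 30
  lab <- array(0L, c(n, n, 10))
  for (i in 1:n) for (j in 1:n) {
    dd <- (i + j) / sqrt(2)
    lab[i, j, ] <- if (dd < 18) 2L else if (dd < 22) 4L else 3L
  }
  labv <- brainVolume(lab, role = "label")
  fr <- solveLaplace(labv)
  sr <- widthStats(computeWidthMap(fr, labv))
  expect_lt(abs(sr$mean - 5.0) / 5.0, 0.15)
})

test_that("region statistics summarize positive widths only", {
  w <- array(0, c(3, 1, 1)); w[] <- c(2, 2, 4)
  wm <- new("WidthMap",
            width = brainVolume(w, role = "width"),
            statusMap = brainVolume(array(1L, c(3, 1, 1)), role = "label"),
            stats = list())
  s <- regionStats(wm)
  expect_equal(s$mean, 8 / 3)
  expect_equal(s$min, 2); expect_equal(s$max, 4); expect_equal(s$mode, 2)
  # voxels outside the region are ignored
  reg <- array(c(1L, 1L, 0L), c(3, 1, 1))
  s2 <- regionStats(wm, brainVolume(reg, role = "mask"))
  expect_equal(s2$mean, 2); expect_identical(s2$n, 2L)
  empty <- array(0L, c(3, 1, 1))
  expect_error(regionStats(wm, brainVolume(empty, role = "mask")),
               "empty-region")
})
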