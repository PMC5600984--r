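mkFeat <- function(a, polarity = "high_is_positive", bg = NA_real_) {
  featureMap(brainVolume(a), "test_feature", polarity, bg)
}

test_that("confusion counts follow polarity, threshold extremes and the background rule", {
  truth <- array(c(0, 1, 1, 0, 1, 0, 0, 1), c(2, 2, 2))
  perfect <- mkFeat(truth * 1.0)
  cm <- confusionAt(perfect, truth, 0.5)
  expect_identical(cm[["fp"]], 0L)
  expect_identical(cm[["fn"]], 0L)
  # threshold below the minimum: everything positive
  low <- confusionAt(perfect, truth, -1)
  expect_identical(low[["tn"]], 0L)
  expect_identical(low[["fn"]], 0L)
  # 3-voxel toy with the gradient background-exclusion rule
  toy <- mkFeat(array(c(2, 6, 10), c(3, 1, 1)), "low_is_positive", bg = 5)
  tr3 <- array(c(0, 1, 1), c(3, 1, 1))
  cm3 <- confusionAt(toy, tr3, 8)
  expect_identical(cm3, c(tp = 1L, tn = 0L, fp = 0L, fn = 1L))
  expect_error(confusionAt(perfect, array(0, c(3, 3, 3)), 1), "geometry")
})

test_that("sweeps match brute-force recounts on random volumes", {
  for (cfg in list(list(pol = "high_is_positive", bg = NA_real_),
                   list(pol = "low_is_positive", bg = 5))) {
    set.seed(13)
    vals <- array(runif(12^3, 0, 20), c(12, 12, 12))
    truth <- array(runif(12^3) < 0.2, c(12, 12, 12))
    feat <- mkFeat(vals, cfg$pol, cfg$bg)
    cur <- curveData(thresholdSweep(feat, truth, nThresholds = 33))
    for (i in seq_len(nrow(cur))) {
      orc <- confusionOracle(as.vector(vals), as.vector(truth),
                             cur$threshold[i], cfg$pol, cfg$bg)
      expect_identical(c(tp = cur$tp[i], tn = cur$tn[i], fp = cur$fp[i],
                         fn = cur$fn[i]), orc)
      n <- sum(orc)
      p <- if (orc[["tp"]] + orc[["fp"]] > 0) orc[["tp"]] / (orc[["tp"]] + orc[["fp"]]) else 0
      r <- if (orc[["tp"]] + orc[["fn"]] > 0) orc[["tp"]] / (orc[["tp"]] + orc[["fn"]]) else 0
      expect_equal(cur$precision[i], p)
      expect_equal(cur$recall[i], r)
      expect_equal(cur$f_score[i], if (p + r > 0) 2 * p * r / (p + r) else 0)
    }
    # count conservation at every threshold
    expect_true(all(cur$tp + cur$tn + cur$fp + cur$fn ==
                      cur$tp[1] + cur$tn[1] + cur$fp[1] + cur$fn[1]))
    # F bounded by twice precision and twice recall
    expect_true(all(cur$f_score <= 2 * cur$recall + 1e-12))
    expect_true(all(cur$f_score <= 2 * cur$precision + 1e-12))
  }
})

test_that("an uninformative feature sits on the chance diagonal; polarity symmetry holds", {
  set.seed(14)
  truth <- array(runif(512) < 0.3, c(8, 8, 8))
  # feature independent of truth: tpr == fpr at every threshold
  vals <- array(rep(seq(0, 1, length.out = 8), each = 64), c(8, 8, 8))
  cur <- curveData(thresholdSweep(mkFeat(vals), truth, nThresholds = 16))
  expect_equal(cur$tpr, cur$fpr, tolerance = 0.08)
  # negating a high_is_positive feature and flipping polarity gives the same
  # confusion counts at mirrored thresholds
  vals2 <- array(runif(512), c(8, 8, 8))
  hi <- mkFeat(vals2, "high_is_positive")
  lo <- mkFeat(-vals2, "low_is_positive")
  for (t in c(0.2, 0.5, 0.8)) {
    expect_identical(confusionAt(hi, truth, t), confusionAt(lo, truth, -t))
  }
})

test_that("best F-score picks the maximum with smallest-threshold ties", {
  mono <- new("EvalCurve",
              curve = data.frame(threshold = 1:4, tp = 1, tn = 1, fp = 1, fn = 1,
                                 tpr = 0.5, fpr = 0.5, precision = 0.5,
                                 recall = 0.5, f_score = c(0.1, 0.2, 0.3, 0.9)),
              polarity = "high_is_positive", nEval = 4L)
  expect_equal(bestFScore(mono)[["threshold"]], 4)
  zero <- mono; zero@curve$f_score <- 0
  expect_equal(bestFScore(zero)[["threshold"]], 1)
  tie <- mono; tie@curve$f_score <- c(0.4, 0.9, 0.9, 0.1)
  expect_equal(bestFScore(tie)[["threshold"]], 2)
  perfect <- thresholdSweep(mkFeat(array(c(0, 1), c(2, 2, 2))),
                            array(c(0, 1), c(2, 2, 2)), nThresholds = 8)
  expect_equal(max(curveData(perfect)$f_score), 1.0)
})

test_that("lesion-slice selection is seeded and restricted to lesion slices", {
  truth <- array(0L, c(4, 4, 10))
  truth[, , c(3, 6, 9)] <- 1L
  m1 <- selectLesionSlices(brainVolume(truth, role = "mask"), 2, seed = 5)
  m2 <- selectLesionSlices(brainVolume(truth, role = "mask"), 2, seed = 5)
  expect_identical(volData(m1), volData(m2))
  kept <- which(apply(volData(m1) == 1L, 3, all))
  expect_true(all(kept %in% c(3, 6, 9)))
  expect_length(kept, 2L)
})
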