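# Evaluation metrics against hand-derived values and brute-force oracles.

test_that("Dice matches hand-enumerated overlap cases", {
  d <- c(5, 5, 1)
  sq3 <- array(FALSE, d); sq3[1:3, 1:3, 1] <- TRUE       # 9 voxels
  sub <- array(FALSE, d); sub[1:2, 1:3, 1] <- TRUE       # 6 voxels, inside
  expect_equal(diceScore(sq3, sq3), 1)
  expect_equal(diceScore(sub, sq3), 2 * 6 / (9 + 6))
  far <- array(FALSE, d); far[5, 5, 1] <- TRUE
  expect_equal(diceScore(far, sq3), 0)
  expect_error(diceScore(sq3, array(FALSE, d)), "empty ground truth")
})

test_that("HD95 equals the brute-force surface-distance oracle", {
  # flat slab shifted by one voxel: distance = spacing along that axis
  d <- c(10, 8, 3)
  a <- array(FALSE, d); a[2:8, 2:7, 2] <- TRUE
  b <- array(FALSE, d); b[3:9, 2:7, 2] <- TRUE
  expect_equal(hd95(a, a, c(0.16, 0.16, 0.16)), 0)
  expect_equal(hd95(a, b, c(0.16, 0.16, 0.16)),
               hd95Oracle(a, b, c(0.16, 0.16, 0.16)))
  expect_equal(hd95(a, b, c(0.5, 0.5, 0.5)),
               hd95Oracle(a, b, c(0.5, 0.5, 0.5)))
  # spacing linearity
  expect_equal(hd95(a, b, c(0.5, 0.5, 0.5)),
               hd95(a, b, c(0.16, 0.16, 0.16)) * 0.5 / 0.16)
})

test_that("metrics agree with oracles on random mask pairs", {
  set.seed(42)
  sp <- c(0.16, 0.2, 0.5)
  for (i in 1:25) {
    y <- randomMask(); yt <- randomMask()
    expect_equal(diceScore(y, yt), diceOracle(y, yt))
    expect_equal(hd95(y, yt, sp), hd95Oracle(y, yt, sp), tolerance = 1e-12)
    expect_equal(compactnessScore(y, yt, sp), csOracle(y, yt, sp))
    # Dice never exceeds volume similarity
    expect_lte(diceScore(y, yt), volumeSimilarity(y, yt) + 1e-12)
    # symmetry properties
    expect_equal(diceScore(y, yt), 2 * sum(y & yt) / (sum(y) + sum(yt)))
    expect_equal(volumeSimilarity(y, yt), volumeSimilarity(yt, y))
    expect_equal(compactnessScore(y, yt, sp), compactnessScore(yt, y, sp))
    expect_equal(hd95(y, yt, sp), hd95(yt, y, sp))
    pr <- precisionRecall(y, yt); rp <- precisionRecall(yt, y)
    expect_equal(unname(pr["precision"]), unname(rp["recall"]))
  }
})

test_that("volume similarity depends only on volumes", {
  d <- c(6, 6, 2)
  a <- array(FALSE, d); a[1:2, 1:5, 1] <- TRUE   # 10 voxels
  b <- array(FALSE, d); b[4:5, 1:4, 2] <- TRUE   # 8 voxels, disjoint
  expect_equal(volumeSimilarity(b, a), 1 - 2 / 18)
  same <- array(FALSE, d); same[3:4, 1:5, 2] <- TRUE  # 10 voxels disjoint
  expect_equal(volumeSimilarity(same, a), 1)
  expect_equal(volumeSimilarity(array(FALSE, d), a), 0)
})

test_that("compactness score separates cube from bar and is translation invariant", {
  d <- c(10, 10, 10)
  cube <- array(FALSE, d); cube[1:2, 1:2, 1:2] <- TRUE     # area 24, vol 8
  bar <- array(FALSE, d); bar[1, 1, 1:8] <- TRUE           # area 34, vol 8
  cube2 <- array(FALSE, d); cube2[5:6, 7:8, 3:4] <- TRUE
  expect_equal(compactnessScore(cube, cube2, c(1, 1, 1)), 1)
  Cc <- 24^1.5 / 8; Cb <- 34^1.5 / 8
  expect_equal(compactnessScore(bar, cube, c(1, 1, 1)),
               1 - 2 * abs(Cb - Cc) / (Cb + Cc))
})

test_that("precision and recall follow containment arithmetic", {
  d <- c(8, 4, 2)
  yt <- array(FALSE, d); yt[1:4, 1, 1] <- TRUE            # 4 voxels
  sup <- array(FALSE, d); sup[1:8, 1, 1] <- TRUE          # superset, 8
  sub <- array(FALSE, d); sub[1:2, 1, 1] <- TRUE          # subset, 2
  expect_equal(unname(precisionRecall(sup, yt)), c(0.5, 1.0))
  expect_equal(unname(precisionRecall(sub, yt)), c(1.0, 0.5))
  expect_equal(unname(precisionRecall(yt, yt)), c(1, 1))
  expect_error(precisionRecall(array(FALSE, d), yt), "empty prediction")
})

test_that("evaluatePair reports all six metrics per ROI and isolates failures", {
  ph <- smallPhantomPair(seed = 3)
  truth <- ph$labels
  rep0 <- evaluatePair(truth, truth)
  expect_s3_class(rep0, "MetricsReport")
  expect_equal(rep0$dice, c(1, 1))
  expect_equal(rep0$hd95, c(0, 0))
  expect_equal(rep0$vs, c(1, 1))
  expect_equal(rep0$cs, c(1, 1))
  expect_equal(rep0$precision, c(1, 1))
  expect_equal(rep0$recall, c(1, 1))
  expect_equal(rep0$volume_pred, rep0$volume_truth)

  # corrupt the prediction: drop the contralateral class entirely
  lab <- labelArray(truth)
  lab[lab == 2L] <- 0L
  pred <- LabelMap(lab, brainMask(truth), voxelSpacing(truth))
  rep1 <- evaluatePair(pred, truth)
  contra <- rep1[rep1$roi == "contra", ]
  # undefined without a predicted region: boundary distance, shape, precision
  expect_true(all(is.na(c(contra$hd95, contra$cs, contra$precision))))
  # still well-defined: no overlap, no volume, nothing recovered
  expect_equal(contra$dice, 0)
  expect_equal(contra$vs, 0)
  expect_equal(contra$recall, 0)
  expect_false(anyNA(rep1[rep1$roi == "ipsi",
                          c("dice", "hd95", "vs", "cs", "precision", "recall")]))
  expect_true(length(attr(rep1, "notes")) > 0)
})

test_that("evaluatePair matches metric-by-metric oracle recomputation", {
  set.seed(9)
  ph <- smallPhantomPair(seed = 5, injury = "TBI", lesionSeverity = 0.5,
                         atrophyFraction = 0.2)
  truth <- ph$labels
  # speckled corruption of the truth as a fake prediction
  lab <- labelArray(truth)
  flip <- sample(length(lab), 40)
  lab[flip] <- (lab[flip] + 1L) %% 3L
  pred <- LabelMap(lab, brainMask(truth), voxelSpacing(truth))
  rep1 <- evaluatePair(pred, truth)
  sp <- voxelSpacing(truth)
  for (code in 1:2) {
    y <- labelArray(pred) == code; yt <- labelArray(truth) == code
    row <- rep1[if (code == 1) 1 else 2, ]
    expect_equal(row$dice, diceOracle(y, yt))
    expect_equal(row$hd95, hd95Oracle(y, yt, sp), tolerance = 1e-12)
    expect_equal(row$cs, csOracle(y, yt, sp))
    expect_equal(row$volume_truth, sum(yt) * prod(sp))
  }
})
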