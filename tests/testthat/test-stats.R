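# Permutation testing, multiplicity correction, bootstrap differences and
# the heteroscedastic volume model.

test_that("paired permutation test is exact for small n", {
  expect_equal(pairedPermutationTest(c(3, 1, 4), c(3, 1, 4)), 1.0)
  # all-positive unit differences, n = 5: only the two all-same sign
  # patterns reach |mean| = 1
  expect_equal(pairedPermutationTest(rep(1, 5)), 2 / 32)
  # two-sidedness: swapping the members flips the sign, not the p-value
  set.seed(1)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  expect_equal(pairedPermutationTest(x, y), pairedPermutationTest(y, x))
})

test_that("Monte-Carlo p stays within 3 binomial SEs of full enumeration", {
  set.seed(10)
  for (rep in 1:5) {
    d <- rnorm(12, mean = 0.4)
    pExact <- pairedPermutationTest(d, iterations = 2^12)  # enumerated
    pMC <- pairedPermutationTest(d, iterations = 4000, seed = rep)
    se <- sqrt(pExact * (1 - pExact) / 4000)
    expect_lt(abs(pMC - pExact), 3 * se + 1 / 4000)
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroniAdjust(0.01, m = 5), 0.05)
  expect_equal(bonferroniAdjust(0.5, m = 4), 1.0)
  expect_equal(bonferroniAdjust(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroniAdjust(0.3, m = 1), 0.3)
  expect_error(bonferroniAdjust(c(0.1, 0.2), m = 1), "m must be")
})

fakeReport <- function(dice_i, dice_c) {
  df <- data.frame(roi = c("ipsi", "contra"), dice = c(dice_i, dice_c),
                   hd95 = c(0.2, 0.2), vs = c(0.9, 0.9), cs = c(0.95, 0.95),
                   precision = c(0.9, 0.9), recall = c(0.9, 0.9))
  class(df) <- c("MetricsReport", "data.frame")
  df
}

test_that("inter-hemispheric differences recover constructed offsets", {
  reps <- lapply(1:6, function(i) fakeReport(0.85, 0.90))
  out <- interhemisphericDifferences(reps, nBoot = 500, seed = 2)
  expect_equal(out$mean_diff[out$metric == "dice"], -0.05)
  expect_equal(out$mean_diff[out$metric == "vs"], 0)
  expect_true(all(out$ci_lo <= out$mean_diff & out$mean_diff <= out$ci_hi))
  expect_true(all(out$n == 6))
})

test_that("bootstrap CI covers the true mean at near-nominal rate", {
  set.seed(33)
  cover <- 0; reps <- 200
  for (r in seq_len(reps)) {
    d <- rnorm(20, mean = 0.3, sd = 1)
    rl <- lapply(d, function(di) fakeReport(0.8 + di / 100, 0.8))
    out <- interhemisphericDifferences(rl, nBoot = 400, seed = r)
    ci <- out[out$metric == "dice", ]
    if (ci$ci_lo <= 0.003 && 0.003 <= ci$ci_hi) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.86)   # percentile bootstrap, n = 20
})

test_that("hippocampal volumes are voxel count times voxel volume", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1] <- 1L   # 100 voxels
  lab[1, 1, 3:4] <- 2L
  lm0 <- LabelMap(lab, spacing = c(0.16, 0.16, 0.16))
  v <- computeVolumes(lm0)
  expect_equal(unname(v["ipsi"]), 100 * 0.16^3)
  expect_equal(unname(v["contra"]), 2 * 0.16^3)
  # invariance to axis permutation
  lmP <- LabelMap(aperm(lab, c(3, 1, 2)), spacing = c(0.16, 0.16, 0.16))
  expect_equal(computeVolumes(lmP), v)
  lab0 <- LabelMap(array(0L, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(unname(computeVolumes(lab0)), c(0, 0))
})

simulateVolumeTable <- function(beta, sig2ByT, nAnimals = 20,
                                timepoints = c(2, 9, 30, 150)) {
  grid <- expand.grid(animal = seq_len(nAnimals), t = timepoints, R = 0:1)
  grid$B <- as.integer(grid$animal <= nAnimals / 2)
  X <- model.matrix(~ t + R + B + t:R + t:B + R:B, data = grid)
  mu <- as.vector(X %*% beta)
  grid$volume <- mu + rnorm(nrow(grid),
                            sd = sqrt(sig2ByT[as.character(grid$t)]))
  grid
}

test_that("FGLS reduces to OLS when per-timepoint variances are equal", {
  set.seed(5)
  tps <- c(2, 9)
  grid <- expand.grid(animal = 1:8, t = tps, R = 0:1)
  grid$B <- as.integer(grid$animal <= 4)
  X <- model.matrix(~ t + R + B + t:R + t:B + R:B, data = grid)
  beta <- c(30, -0.01, 2, -1, 0.01, -0.02, 0.5)
  e1 <- rnorm(sum(grid$t == tps[1]))
  e <- numeric(nrow(grid))
  e[grid$t == tps[1]] <- e1
  e[grid$t == tps[2]] <- e1   # identical residual pattern per timepoint
  grid$volume <- as.vector(X %*% beta) + e
  fit <- fitVolumeModel(grid)
  ols <- lm(volume ~ t + R + B + t:R + t:B + R:B, data = grid)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(as.vector(fit$fitted + fit$residuals), grid$volume)
})

test_that("volume-model coefficients are recovered from simulated data", {
  set.seed(77)
  beta <- c(32, -0.02, 3, -2, 0.015, -0.03, -0.8)
  sig2 <- c(`2` = 1, `9` = 2, `30` = 4, `150` = 8)
  hit <- 0; reps <- 25
  for (r in seq_len(reps)) {
    tab <- simulateVolumeTable(beta, sig2)
    fit <- fitVolumeModel(tab)
    ok <- abs(fit$coefficients$estimate - beta) <= 3 * fit$coefficients$se
    if (all(ok)) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.8)
})

test_that("rank-deficient designs are rejected with the collinear term named", {
  grid <- expand.grid(animal = 1:6, t = c(2, 9), R = 0:1)
  grid$B <- grid$R          # perfectly collinear
  grid$volume <- rnorm(nrow(grid), 30)
  expect_error(fitVolumeModel(grid), "collinear")
})

test_that("volumeTable lays out animal x timepoint x hemisphere rows", {
  ph <- smallPhantomPair(seed = 2)
  samples <- list(list(labels = ph$labels, animal = "S01", group = "sham",
                       timepoint = 9))
  tab <- volumeTable(samples)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$R, c(1L, 0L))
  expect_equal(tab$B, c(0L, 0L))
  v <- computeVolumes(ph$labels)
  expect_equal(tab$volume, unname(v[c("ipsi", "contra")]))
})
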