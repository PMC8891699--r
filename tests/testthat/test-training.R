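# Augmentation, the rectified-Adam rule and the training loop contracts.

test_that("augmentation branches behave as specified", {
  ph <- smallPhantomPair(seed = 3)
  # probability zero: exact identity
  set.seed(1)
  out <- augmentScale(ph$volume, ph$labels, trainConfig(augmentProb = 0))
  expect_identical(volumeData(out$volume), volumeData(ph$volume))
  expect_identical(labelArray(out$labels), labelArray(ph$labels))
  # unit scale: identity within interpolation tolerance
  set.seed(1)
  out1 <- augmentScale(ph$volume, ph$labels,
                       trainConfig(augmentProb = 1, scaleRange = c(1, 1)))
  expect_lt(max(abs(volumeData(out1$volume) - volumeData(ph$volume))), 1e-9)
  expect_identical(labelArray(out1$labels), labelArray(ph$labels))
})

test_that("scaling a centred cube grows its voxel count by about alpha^3", {
  d <- c(48L, 48L, 48L)
  lab <- array(0L, d); lab[9:40, 9:40, 9:40] <- 1L
  v <- VolumeGrid(array(rnorm(prod(d)), d), c(1, 1, 1))
  l <- LabelMap(lab, array(1L, d), c(1, 1, 1))
  set.seed(2)
  cfg <- trainConfig(augmentProb = 1)
  cfg$scaleRange <- c(1.05, 1.05)   # force the scale draw to alpha = 1.05
  out <- augmentScale(v, l, cfg)
  ratio <- sum(labelArray(out$labels) == 1L) / sum(lab == 1L)
  expect_lt(abs(ratio - 1.05^3), 1.05^3 * 0.1)
})

test_that("the rectified-Adam update matches an independent reference trace", {
  cfg <- trainConfig(lr = 0.1, seed = 1)
  # reference: scalar implementation of the published update written
  # directly from the formulas, on the quadratic bowl f = theta^2 / 2
  ref <- local({
    th <- 1; m <- 0; v <- 0
    b1 <- 0.9; b2 <- 0.999; rhoInf <- 2 / (1 - b2) - 1
    out <- numeric(25)
    for (t in 1:25) {
      gr <- th
      m <- b1 * m + (1 - b1) * gr
      v <- b2 * v + (1 - b2) * gr^2
      mh <- m / (1 - b1^t)
      rhoT <- rhoInf - 2 * t * b2^t / (1 - b2^t)
      th <- if (rhoT > 4) {
        r <- sqrt((rhoT - 4) * (rhoT - 2) * rhoInf /
                  ((rhoInf - 4) * (rhoInf - 2) * rhoT))
        th - 0.1 * r * mh / (sqrt(v / (1 - b2^t)) + 1e-8)
      } else th - 0.1 * mh
      out[t] <- th
    }
    out
  })
  params <- list(theta = 1)
  st <- radamInitState(params)
  got <- numeric(25)
  for (t in 1:25) {
    up <- radamStep(params, list(theta = params$theta), st, cfg)
    params <- up$params; st <- up$state
    got[t] <- params$theta
  }
  expect_equal(got, ref, tolerance = 1e-12)
  # warm-up: the first updates are plain (un-rectified) momentum steps
  expect_equal(ref[1], 1 - 0.1 * 1)
})

test_that("training smoke contract: bounded history, finite losses", {
  cs <- cohortSpec(2, 1, timepoints = 9, dialect = "anisotropic2D",
                   shape = c(16L, 16L, 8L))
  coh <- generateCohort(cs, seed = 5)
  net <- buildNetwork(tinyModelConfig(2L), seed = 1)
  res <- trainSingle(net, coh$samples[1:2], coh$samples[3],
                     trainConfig(maxEpochs = 5, patience = 10, seed = 2))
  expect_lte(nrow(res$history), 5)
  expect_true(all(is.finite(res$history$train_loss)))
  expect_true(all(is.finite(res$history$val_loss)))
  expect_equal(res$bestEpoch, which.min(res$history$val_loss))
  # early-stopping rule: stop epoch minus best epoch never exceeds patience
  expect_lte(nrow(res$history) - res$bestEpoch, 10)
})

test_that("training is bit-reproducible given (seed, data, config)", {
  cs <- cohortSpec(2, 1, timepoints = 9, dialect = "anisotropic2D",
                   shape = c(16L, 16L, 8L))
  coh <- generateCohort(cs, seed = 5)
  run <- function() {
    net <- buildNetwork(tinyModelConfig(2L), seed = 1)
    trainSingle(net, coh$samples[1:2], coh$samples[3],
                trainConfig(maxEpochs = 3, patience = 10, seed = 2))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$net@params, b$net@params)
})

test_that("a constant validation loss stops training after patience epochs", {
  cs <- cohortSpec(2, 1, timepoints = 9, dialect = "anisotropic2D",
                   shape = c(16L, 16L, 8L))
  coh <- generateCohort(cs, seed = 5)
  net <- buildNetwork(tinyModelConfig(2L), seed = 1)
  # a vanishing learning rate freezes the network, so the validation loss
  # is identical every epoch and never improves on epoch 1
  res <- trainSingle(net, coh$samples[1:2], coh$samples[3],
                     trainConfig(lr = 1e-300, maxEpochs = 50, patience = 1,
                                 augmentProb = 0, seed = 2))
  expect_equal(nrow(res$history), 2)
  expect_equal(res$stopReason, "early_stop")
  expect_equal(res$bestEpoch, 1)
})

test_that("training loss decreases on a repeated single sample", {
  ph <- generatePhantom(phantomSpec(shape = c(16L, 16L, 8L),
                                    spacing = c(0.15, 0.15, 0.5), seed = 21))
  sample1 <- list(volume = ph$volume, labels = ph$labels, animal = "A")
  ph2 <- generatePhantom(phantomSpec(shape = c(16L, 16L, 8L),
                                     spacing = c(0.15, 0.15, 0.5), seed = 22))
  val <- list(volume = ph2$volume, labels = ph2$labels, animal = "B")
  net <- buildNetwork(tinyModelConfig(2L), seed = 6)
  res <- trainSingle(net, list(sample1), list(val),
                     trainConfig(maxEpochs = 20, patience = 30, seed = 3))
  expect_lt(res$history$train_loss[20], res$history$train_loss[1])
})

test_that("an intensity-separable toy task is mastered on its training data", {
  # two-intensity phantom: each hippocampus class has its own intensity,
  # so voxel intensity alone separates the classes
  d <- c(32L, 32L, 8L)
  lab <- array(0L, d)
  lab[6:12, 10:22, 2:7] <- 1L
  lab[20:26, 10:22, 2:7] <- 2L
  brn <- array(0L, d); brn[3:30, 4:28, ] <- 1L
  img <- array(0, d)
  img[brn == 1L] <- 0.6
  img[lab == 1L] <- 2; img[lab == 2L] <- -2
  set.seed(9)
  mk <- function() list(
    volume = VolumeGrid(img + array(rnorm(prod(d), 0, 0.02), d),
                        c(0.15, 0.15, 0.5)),
    labels = LabelMap(lab, brn, c(0.15, 0.15, 0.5)))
  tr <- mk(); vl <- mk(); tr$animal <- "A"; vl$animal <- "B"
  net <- buildNetwork(modelConfig(dimensionality = 2L), seed = 2)
  res <- trainSingle(net, list(tr), list(vl),
                     trainConfig(maxEpochs = 60, patience = 60, seed = 4))
  pred <- segmentVolume(res$net, tr$volume, postprocess = TRUE)
  expect_gt(diceScore(labelArray(pred) == 1L, lab == 1L), 0.95)
  expect_gt(diceScore(labelArray(pred) == 2L, lab == 2L), 0.95)
})
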