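# Architecture construction, forward-pass contracts and backpropagation.

test_that("prediction probabilities form a per-voxel simplex", {
  net <- buildNetwork(tinyModelConfig(3L), seed = 2)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  fw <- munetr:::netForward(net, x, keep = FALSE)
  s <- fw$regionProbs[, , , 1] + fw$regionProbs[, , , 2] +
       fw$regionProbs[, , , 3]
  expect_lt(max(abs(s - 1)), 1e-5)
  expect_true(all(fw$brainProb >= 0 & fw$brainProb <= 1))
  # two evaluations with the same weights are identical
  fw2 <- munetr:::netForward(net, x, keep = FALSE)
  expect_identical(fw$regionProbs, fw2$regionProbs)
})

test_that("parameter count is independent of input size; output tracks input", {
  net <- buildNetwork(tinyModelConfig(3L), seed = 1)
  n0 <- countParameters(net)
  f1 <- munetr:::netForward(net, array(rnorm(8 * 8 * 8), c(8, 8, 8)), FALSE)
  f2 <- munetr:::netForward(net, array(rnorm(16 * 16 * 8), c(16, 16, 8)), FALSE)
  expect_identical(dim(f1$regionProbs)[1:3], c(8L, 8L, 8L))
  expect_identical(dim(f2$regionProbs)[1:3], c(16L, 16L, 8L))
  expect_identical(countParameters(net), n0)
  expect_error(munetr:::netForward(net, array(0, c(9, 8, 8)), FALSE), "pad")
})

test_that("hand-counted convolution parameters are reproduced", {
  # single 2D 3x3 convolution, 1 -> 4 channels, with bias: 1*4*9 + 4 = 40
  cv <- munetr:::initConv(c(3L, 3L, 1L), 1L, 4L)
  expect_equal(length(cv$W) + length(cv$b), 40)
  # a full block of three convolutions plus its normalisation parameters
  plan <- cbind(c(1, 4, 4), c(4, 4, 4))
  blk <- munetr:::initBlockParams(c(3L, 3L, 1L), plan)
  got <- sum(vapply(blk, function(l) length(l$W) + length(l$b) +
                           length(l$gamma) + length(l$beta), 0))
  byHand <- (2 * 1 + 9 * 1 * 4 + 4) + (2 * 4 + 9 * 4 * 4 + 4) +
            (2 * 4 + 9 * 4 * 4 + 4)
  expect_equal(got, byHand)
})

test_that("encoder and decoder are symmetric in depth", {
  plans <- munetr:::blockPlans(tinyModelConfig(3L))
  expect_setequal(names(plans),
                  c("enc1", "enc2", "enc3", "btl", "dec3", "dec2", "dec1"))
  enc <- plans[c("enc1", "enc2", "enc3")]
  dec <- plans[c("dec1", "dec2", "dec3")]
  expect_equal(length(enc), length(dec))
})

test_that("index unpooling restores maxima locations exactly", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  pl <- munetr:::maxpool3_fwd(x, dim(x), c(2L, 2L, 2L))
  up <- munetr:::maxunpool3(pl$y, pl$idx, length(x), dim(x))
  # non-zeros sit exactly at the argmax positions with the pooled values
  expect_equal(up[pl$idx + 1L], as.vector(pl$y))
  expect_equal(sum(up != 0), sum(pl$y != 0))
  expect_true(all(up[-(pl$idx + 1L)] == 0))
})

test_that("backpropagation matches finite differences where the loss is smooth", {
  set.seed(7)
  net <- buildNetwork(tinyModelConfig(3L), seed = 3)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  lab <- array(sample(0:2, 512, TRUE), c(8, 8, 8))
  brn <- array(sample(0:1, 512, TRUE), c(8, 8, 8))
  fw <- munetr:::netForward(net, x, keep = TRUE)
  lg <- munetr:::lossAndGrad(fw, lab, brn)
  g <- munetr:::netBackward(net, fw, lg$gRegion, lg$gBrain)
  lossAt <- function(p) {
    n <- net; n@params <- p
    f <- munetr:::netForward(n, x, keep = FALSE)
    munetr:::lossAndGrad(f, lab, brn)$L
  }
  # parameters on the decoder/head side avoid pooling-argmax kinks
  probes <- list(list(c("blocks", "dec2", 3L, "b"), 1L),
                 list(c("blocks", "dec1", 2L, "W"), 7L),
                 list(c("regionHead", "W"), 3L),
                 list(c("brainHead", "W"), 2L),
                 list(c("blocks", "dec1", 1L, "beta"), 1L),
                 list(c("blocks", "btl", 2L, "gamma"), 1L))
  for (pr in probes) {
    path <- pr[[1]]; i <- pr[[2]]
    eps <- 1e-4
    bump <- function(d) {
      p <- net@params
      if (length(path) == 4) p[[path[1]]][[path[2]]][[as.integer(path[3])]][[path[4]]][i] <-
          p[[path[1]]][[path[2]]][[as.integer(path[3])]][[path[4]]][i] + d
      else p[[path[1]]][[path[2]]][i] <- p[[path[1]]][[path[2]]][i] + d
      p
    }
    num <- (lossAt(bump(eps)) - lossAt(bump(-eps))) / (2 * eps)
    ana <- if (length(path) == 4)
      g[[path[1]]][[path[2]]][[as.integer(path[3])]][[path[4]]][i]
    else g[[path[1]]][[path[2]]][i]
    expect_equal(ana, num, tolerance = 5e-2)
  }
})

test_that("decoded labels follow the argmax and threshold contracts", {
  d <- c(4, 4, 2)
  rp <- array(0, c(d, 3))
  rp[, , , 1] <- 0.2; rp[, , , 2] <- 0.5; rp[, , , 3] <- 0.3
  rp[1, 1, 1, ] <- c(1, 0, 0)
  lm <- decodePrediction(Prediction(rp, array(c(0.4, 0.6), d)), c(1, 1, 1))
  expect_equal(labelArray(lm)[1, 1, 1], 0L)
  expect_true(all(labelArray(lm)[-1] == 1L))
  expect_equal(unique(as.vector(brainMask(lm)[seq(1, 31, 2)])), 0L)
  # uniform probabilities: documented tie rule -> lowest class index
  rpU <- array(1 / 3, c(d, 3))
  lmU <- decodePrediction(Prediction(rpU, array(0.5, d)), c(1, 1, 1))
  expect_true(all(labelArray(lmU) == 0L))
  expect_true(all(brainMask(lmU) == 1L))   # 0.5 thresholds inclusively
})

test_that("a non-standardized input triggers a warning", {
  net <- buildNetwork(tinyModelConfig(3L), seed = 1)
  v <- VolumeGrid(array(rnorm(8 * 8 * 8, mean = 10), c(8, 8, 8)), c(1, 1, 1))
  expect_warning(predictProbs(net, v), "standardized")
})

test_that("the 2D variant slices along the lowest-resolution axis", {
  net <- buildNetwork(tinyModelConfig(2L), seed = 4)
  # slice axis = y here (0.5 mm); volume shape deliberately asymmetric
  x <- array(rnorm(16 * 8 * 16), c(16, 8, 16))
  v <- standardizeVolume(VolumeGrid(x, c(0.15, 0.5, 0.15)))
  pr <- predictProbs(net, v)
  expect_identical(dim(pr@regionProbs)[1:3], dim(x))
  # per-slice processing: permuting unrelated slices leaves others intact
  x2 <- x; x2[, 8, ] <- rnorm(16 * 16)
  v2 <- VolumeGrid(x2, c(0.15, 0.5, 0.15))
  suppressWarnings(pr2 <- predictProbs(net, v2))
  same <- abs(pr@regionProbs[, 1:4, , ] -
              suppressWarnings(predictProbs(net, v))@regionProbs[, 1:4, , ])
  expect_lt(max(same), 1e-12)
})
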