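#' Training hyper-parameters
#'
#' Defaults follow the training protocol: rectified Adam at learning rate
#' 0.001 with beta1 = 0.9, beta2 = 0.999 and no weight decay, batch size
#' one, up to 250 epochs, early stopping when the mean validation loss has
#' not improved for 10 consecutive epochs, and online augmentation that
#' rescales each sample with probability 0.5 by a factor drawn uniformly
#' from [0.95, 1.05] (no rotations).
#'
#' @param lr learning rate.
#' @param beta1,beta2 exponential decay rates of the moment estimates.
#' @param weightDecay L2 penalty (0 as trained).
#' @param maxEpochs epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param augmentProb probability of applying the scaling augmentation.
#' @param scaleRange interval for the scale factor; must contain 1.
#' @param seed seed controlling shuffling and augmentation draws.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                        weightDecay = 0, maxEpochs = 250L, patience = 10L,
                        augmentProb = 0.5, scaleRange = c(0.95, 1.05),
                        seed = 1L) {
  stopifnot(lr > 0, augmentProb >= 0, augmentProb <= 1,
            scaleRange[1] <= 1, scaleRange[2] >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weightDecay = weightDecay, batchSize = 1L,
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), augmentProb = augmentProb,
                 scaleRange = scaleRange, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Online scaling augmentation
#'
#' With probability `cfg$augmentProb`, rescales image and labels about the
#' volume centre by a single factor drawn uniformly from `cfg$scaleRange`
#' (linear interpolation for the image, nearest neighbour for labels and
#' brain mask), keeping the original grid; otherwise returns the pair
#' unchanged.  No rotations are ever applied.  Consumes the current RNG
#' stream.
#'
#' @param v a [VolumeGrid-class].
#' @param l the paired [LabelMap-class].
#' @param cfg a [trainConfig()].
#' @return list(volume, labels), possibly rescaled.
#' @export
augmentScale <- function(v, l, cfg = trainConfig()) {
  if (runif(1) >= cfg$augmentProb)
    return(list(volume = v, labels = l))
  a <- runif(1, cfg$scaleRange[1], cfg$scaleRange[2])
  d <- dim(v@data)
  img <- rescale3(v@data, d, a, FALSE)
  lab <- array(as.integer(round(rescale3(l@labels + 0, d, a, TRUE))), d)
  brn <- array(as.integer(round(rescale3(l@brain + 0, d, a, TRUE))), d)
  list(volume = VolumeGrid(img, v@spacing, v@affine),
       labels = LabelMap(lab, brn, l@spacing, l@affine))
}

# per-slice counterpart of augmentScale, acting on (X, Y, 1) arrays
augmentStep <- function(st, cfg) {
  if (runif(1) >= cfg$augmentProb) return(st)
  a <- runif(1, cfg$scaleRange[1], cfg$scaleRange[2])
  d <- dim(st$x)
  list(x = rescale3(st$x, d, a, FALSE),
       lab = array(as.integer(round(rescale3(st$lab + 0, d, a, TRUE))), d),
       brn = array(as.integer(round(rescale3(st$brn + 0, d, a, TRUE))), d))
}

# ---- rectified Adam --------------------------------------------------------

radamInitState <- function(params) {
  zeros <- function(p) {
    if (is.list(p)) lapply(p, zeros) else array(0, dim(p) %||% length(p))
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One rectified-Adam update
#'
#' Implements the published RAdam rule: bias-corrected first moment always,
#' and the variance-rectified adaptive step only once the approximated SMA
#' length exceeds 4; before that the update falls back to the un-adapted
#' momentum step.
#'
#' @param params,grads nested lists of arrays with identical structure.
#' @param state optimizer state from [radamInitState()] (internal).
#' @param cfg a [trainConfig()].
#' @return list(params, state) after the update.
#' @export
radamStep <- function(params, grads, state, cfg) {
  t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- 1e-8
  rhoInf <- 2 / (1 - b2) - 1
  rhoT <- rhoInf - 2 * t * b2^t / (1 - b2^t)
  rect <- rhoT > 4
  r <- if (rect)
    sqrt(((rhoT - 4) * (rhoT - 2) * rhoInf) /
         ((rhoInf - 4) * (rhoInf - 2) * rhoT)) else NA_real_
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(step, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    radam_leaf(p, g, m, v, cfg$lr, b1, b2, eps, cfg$weightDecay, t,
               rect, if (rect) r else 0)
  }
  out <- step(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# loss + gradients w.r.t. both logit tensors, in network (slice-last) space
lossAndGrad <- function(fw, labels, brain, weightsFrom = "truth") {
  nc <- dim(fw$regionProbs)[4]
  oh <- oneHotLabels(labels, nc)
  hc <- gdlCore(fw$regionProbs, oh, weightsFrom, wantGrad = TRUE)
  # softmax backward: gz_c = p_c (g_c - sum_k g_k p_k)
  d <- dim(fw$regionProbs)
  P <- matrix(fw$regionProbs, prod(d[1:3]), nc)
  G <- matrix(hc$grad, prod(d[1:3]), nc)
  gRegion <- array(P * (G - rowSums(G * P)), d)
  gBrain <- NULL; LB <- 0
  if (!is.null(fw$brainProb)) {
    if (sum(brain) > 0) {
      br <- brainCore(fw$brainProb, brain, wantGrad = TRUE)
      LB <- br$value
      pb <- fw$brainProb
      gBrain <- dim4(br$grad * pb * (1 - pb))
    } else {
      # slice entirely outside the brain: no skull-stripping supervision
      gBrain <- dim4(array(0, dim(fw$brainProb)))
    }
  }
  list(L = hc$value + LB, L_HC = hc$value, L_Brain = LB,
       gRegion = gRegion, gBrain = gBrain)
}

sliceArr <- function(a, z) array(a[, , z], c(dim(a)[1:2], 1L))

sampleLoss <- function(net, x, lab, brn, weightsFrom = "truth") {
  fw <- netForward(net, x, keep = FALSE)
  nc <- dim(fw$regionProbs)[4]
  hc <- tryCatch(
    gdlCore(fw$regionProbs, oneHotLabels(lab, nc), weightsFrom)$value,
    error = function(e) NA_real_)   # slice without any foreground truth
  lb <- if (!is.null(fw$brainProb) && sum(brn) > 0)
    brainCore(fw$brainProb, brn)$value else 0
  if (is.na(hc)) lb else hc + lb
}

# Mean validation loss over validation volumes.  Validation always runs a
# single whole-volume forward pass (the inference-time normalisation
# semantics), so early stopping tracks the quantity that matters at test
# time for both variants.
evalLoss <- function(net, sample, perm) {
  v <- standardizeVolume(sample$volume)
  xp <- aperm(v@data, perm)
  lab <- aperm(sample$labels@labels, perm)
  brn <- aperm(sample$labels@brain, perm)
  sampleLoss(net, xp, lab, brn)
}

#' Train a single network
#'
#' Minimises the composite loss with rectified Adam at batch size one,
#' applying the scaling augmentation and per-sample standardization online
#' (augmentation first, then standardization).  Stops at `maxEpochs` or
#' once the mean validation loss has not improved for `patience`
#' consecutive epochs, and restores the weights of the best-validation
#' epoch.  Fully reproducible given (seed, data, config).
#'
#' @param net a freshly built [MUNet-class].
#' @param trainSet,valSet disjoint lists of samples, each a list with
#'   elements `volume` ([VolumeGrid-class]) and `labels`
#'   ([LabelMap-class]).
#' @param cfg a [trainConfig()].
#' @param weightsFrom class-weight source for the generalized Dice loss.
#' @return list(net, history, bestEpoch, stopReason); `history` is a
#'   data.frame with per-epoch train and validation loss.
#' @export
trainSingle <- function(net, trainSet, valSet, cfg = trainConfig(),
                        weightsFrom = "truth") {
  stopifnot(is(net, "MUNet"), length(trainSet) >= 1, length(valSet) >= 1)
  ta <- unlist(lapply(trainSet, `[[`, "animal"))
  va <- unlist(lapply(valSet, `[[`, "animal"))
  if (length(ta) && length(va) && length(intersect(ta, va)))
    stop("trainSingle: train and validation sets share animals")
  perm <- permToSliceLast(sliceAxis(net@config,
                                    trainSet[[1]]$volume@spacing))
  withSeed(cfg$seed, {
    params <- net@params
    state <- radamInitState(params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    best <- Inf; bestEpoch <- 0L; bestParams <- params
    stopReason <- "max_epochs"
    is2d <- net@config@dimensionality == 2L
    for (epoch in seq_len(cfg$maxEpochs)) {
      eploss <- numeric(0)
      if (is2d) {
        # a 2D training sample is one coronal slice (batch size one)
        vols <- lapply(trainSet, function(s) {
          v <- standardizeVolume(s$volume)
          list(x = aperm(v@data, perm),
               lab = aperm(s$labels@labels, perm),
               brn = aperm(s$labels@brain, perm))
        })
        nz <- dim(vols[[1]]$x)[3]
        deck <- cbind(rep(seq_along(vols), each = nz),
                      rep(seq_len(nz), times = length(vols)))
        deck <- deck[sample(nrow(deck)), , drop = FALSE]
        steps <- lapply(seq_len(nrow(deck)), function(r)
          list(x = sliceArr(vols[[deck[r, 1]]]$x, deck[r, 2]),
               lab = sliceArr(vols[[deck[r, 1]]]$lab, deck[r, 2]),
               brn = sliceArr(vols[[deck[r, 1]]]$brn, deck[r, 2])))
        steps <- lapply(steps, augmentStep, cfg = cfg)
      } else {
        ord <- sample(length(trainSet))
        steps <- lapply(ord, function(i) {
          aug <- augmentScale(trainSet[[i]]$volume, trainSet[[i]]$labels, cfg)
          v <- standardizeVolume(aug$volume)
          list(x = aperm(v@data, perm),
               lab = aperm(aug$labels@labels, perm),
               brn = aperm(aug$labels@brain, perm))
        })
      }
      for (st in steps) {
        netNow <- net; netNow@params <- params
        fw <- netForward(netNow, st$x, keep = TRUE)
        lg <- lossAndGrad(fw, st$lab, st$brn, weightsFrom)
        if (!is.finite(lg$L))
          stop("trainSingle: non-finite loss at epoch ", epoch,
               " (diverged); inspect learning rate and inputs")
        g <- netBackward(netNow, fw, lg$gRegion, lg$gBrain)
        upd <- radamStep(params, g, state, cfg)
        params <- upd$params; state <- upd$state
        eploss <- c(eploss, lg$L)
      }
      netNow <- net; netNow@params <- params
      vloss <- mean(vapply(valSet, function(s) evalLoss(netNow, s, perm), 0))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(eploss),
                                     val_loss = vloss))
      if (vloss < best) {
        best <- vloss; bestEpoch <- epoch; bestParams <- params
      }
      if (epoch - bestEpoch >= cfg$patience) {
        stopReason <- "early_stop"
        break
      }
    }
    net@params <- bestParams
    list(net = net, history = hist, bestEpoch = bestEpoch,
         stopReason = stopReason)
  })
}
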