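#' Model configuration for the multi-task segmentation network
#'
#' The network is a U-Net-like encoder-decoder: three encoder blocks and a
#' bottleneck with per-block channel widths `channels` (default 16, 32, 64,
#' 64 from shallowest to deepest), each block consisting of three
#' iterations of Leaky ReLU activation, batch normalisation and "same"
#' zero-padded convolution, in that order.  Blocks are connected downward
#' by 2x max-pooling with retained indices and upward by index-based
#' unpooling; skip connections concatenate each encoder block output onto
#' the corresponding decoder stage.  Because index unpooling requires the
#' unpooled tensor to carry exactly the channel count of the pooled encoder
#' feature, the last convolution of each decoder block maps down to the
#' channel width of the next-shallower level.  Two heads emit per-voxel
#' outputs from the full-resolution decoder feature: a 3-class softmax
#' (background / ipsilateral / contralateral hippocampus) and a sigmoid
#' brain-mask probability, each a 1x1 convolution.
#'
#' The 2D variant (for anisotropic multi-slice acquisitions) uses 3x3
#' kernels and pools only in-plane, processing coronal slices
#' independently; the 3D variant uses 3x3x3 kernels and pools all axes.
#'
#' @param dimensionality 2 or 3 (kernel and pooling dimensionality).
#' @param channels integer(4) channel plan, shallowest encoder block to
#'   bottleneck.
#' @param kernel odd kernel size (3 for the compact network, 5 for the
#'   larger baseline it descends from).
#' @param nClasses number of region classes including background.
#' @param slope negative slope of the Leaky ReLU activations.
#' @param brainHead include the skull-stripping head.
#' @return A `ModelConfig` object.
#' @export
modelConfig <- function(dimensionality = 3L, channels = c(16L, 32L, 64L, 64L),
                        kernel = 3L, nClasses = 3L, slope = 0.01,
                        brainHead = TRUE) {
  new("ModelConfig", dimensionality = as.integer(dimensionality),
      channels = as.integer(channels), kernel = as.integer(kernel),
      nClasses = as.integer(nClasses), slope = slope,
      brainHead = brainHead)
}

#' @rdname modelConfig
#' @export
setClass("ModelConfig",
  representation(dimensionality = "integer", channels = "integer",
                 kernel = "integer", nClasses = "integer", slope = "numeric",
                 brainHead = "logical"),
  validity = function(object) {
    if (!object@dimensionality %in% c(2L, 3L))
      return("dimensionality must be 2 or 3")
    if (length(object@channels) != 4L || any(object@channels < 1L))
      return("channels must be four positive integers (3 encoder blocks + bottleneck)")
    if (object@kernel %% 2L != 1L) return("kernel size must be odd")
    if (object@nClasses < 2L) return("need at least two region classes")
    TRUE
  })

#' Trained network container
#'
#' @slot config the [modelConfig()] used to build the network.
#' @slot params nested list of trainable arrays (per block: gamma, beta,
#'   convolution weights and biases; plus the two heads).
#' @slot seed initialisation seed.
#' @export
setClass("MUNet",
  representation(config = "ModelConfig", params = "list", seed = "integer"))

setMethod("show", "MUNet", function(object) {
  cat(sprintf("MUNet: %dD variant, kernel %d, channels %s, %s parameters\n",
              object@config@dimensionality, object@config@kernel,
              paste(object@config@channels, collapse = "/"),
              format(countParameters(object), big.mark = ",")))
})

kernelDims <- function(cfg) {
  k <- cfg@kernel
  c(k, k, if (cfg@dimensionality == 3L) k else 1L)
}

poolDims <- function(cfg) {
  c(2L, 2L, if (cfg@dimensionality == 3L) 2L else 1L)
}

initConv <- function(kd, cin, cout) {
  fanin <- prod(kd) * cin
  list(W = array(rnorm(prod(kd) * cin * cout, 0, sqrt(2 / fanin)),
                 c(kd, cin, cout)),
       b = numeric(cout))
}

initBlockParams <- function(kd, plan) {
  lapply(seq_len(nrow(plan)), function(i)
    c(list(gamma = rep(1, plan[i, 1]), beta = numeric(plan[i, 1])),
      initConv(kd, plan[i, 1], plan[i, 2])))
}

# channel plan (cin, cout) of the three convolutions in each block
blockPlans <- function(cfg) {
  ch <- cfg@channels
  c1 <- ch[1]; c2 <- ch[2]; c3 <- ch[3]; c4 <- ch[4]
  list(enc1 = cbind(c(1, c1, c1), c(c1, c1, c1)),
       enc2 = cbind(c(c1, c2, c2), c(c2, c2, c2)),
       enc3 = cbind(c(c2, c3, c3), c(c3, c3, c3)),
       btl  = cbind(c(c3, c4, c4), c(c4, c4, c4)),
       dec3 = cbind(c(c4 + c3, c3, c3), c(c3, c3, c2)),
       dec2 = cbind(c(c2 + c2, c2, c2), c(c2, c2, c1)),
       dec1 = cbind(c(c1 + c1, c1, c1), c(c1, c1, c1)))
}

#' Build the network
#'
#' Weights use He initialisation; construction is deterministic given
#' `seed`.
#'
#' @param cfg a [modelConfig()].
#' @param seed initialisation seed.
#' @return A [MUNet-class].
#' @export
buildNetwork <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "ModelConfig"))
  kd <- kernelDims(cfg)
  plans <- blockPlans(cfg)
  params <- withSeed(seed, {
    p <- list(blocks = lapply(plans, function(pl) initBlockParams(kd, pl)))
    c1 <- cfg@channels[1]
    p$regionHead <- initConv(c(1L, 1L, 1L), c1, cfg@nClasses)
    if (cfg@brainHead) p$brainHead <- initConv(c(1L, 1L, 1L), c1, 1L)
    p
  })
  new("MUNet", config = cfg, params = params, seed = as.integer(seed))
}

#' Count trainable parameters
#'
#' Number of trainable scalars: convolution weights and biases plus the
#' scale and shift of every batch-normalisation layer.  The count is
#' independent of input size (the network is fully convolutional).
#'
#' @param net a [MUNet-class].
#' @return Integer parameter count.
#' @export
countParameters <- function(net) {
  stopifnot(is(net, "MUNet"))
  sum(vapply(rapply(net@params, length, how = "unlist"), identity, 0L))
}

dim4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

blockForward <- function(blk, x, slope, keep = TRUE) {
  caches <- vector("list", length(blk))
  for (i in seq_along(blk)) {
    ly <- blk[[i]]
    bn <- lbn_fwd(x, dim(x), ly$gamma, ly$beta, slope, 1e-5)
    if (keep) {
      # retain the im2col buffer (when small) so the backward pass can
      # skip re-gathering the convolution patches
      cv <- conv3_fwd_cache(bn$y, dim(bn$y), ly$W, dim(ly$W), ly$b, 24)
      y <- cv$y
      caches[[i]] <- list(inAct = x, xhat = bn$xhat, invstd = bn$invstd,
                          h = bn$y, hdim = dim(bn$y), col = cv$col)
    } else {
      y <- conv3_fwd(bn$y, dim(bn$y), ly$W, dim(ly$W), ly$b)
    }
    x <- y
  }
  list(out = x, caches = caches)
}

blockBackward <- function(blk, caches, gout, slope) {
  grads <- vector("list", length(blk))
  for (i in rev(seq_along(blk))) {
    ly <- blk[[i]]; ca <- caches[[i]]
    cb <- conv3_bwd(ca$h, ca$hdim, ly$W, dim(ly$W), gout, ca$col)
    bb <- lbn_bwd(cb$gx, ca$xhat, ca$invstd, ly$gamma, ca$inAct, slope,
                  ca$hdim)
    gout <- bb$gx
    grads[[i]] <- list(gamma = bb$ggamma, beta = bb$gbeta,
                       W = cb$gw, b = cb$gb)
  }
  list(gin = gout, grads = grads)
}

checkShape <- function(cfg, d) {
  pd <- poolDims(cfg)
  need <- pd^3L   # three pooling stages
  bad <- d[1:3] %% need != 0L
  if (any(bad))
    stop("input shape ", paste(d[1:3], collapse = "x"),
         " not divisible by the pooling chain; pad axes ",
         paste(which(bad), collapse = ", "), " to multiples of ",
         paste(need[bad], collapse = ", "))
}

# Full forward pass on a (x, y, z) array (slice axis already third).
netForward <- function(net, x, keep = TRUE) {
  cfg <- net@config
  checkShape(cfg, dim(x))
  pd <- poolDims(cfg)
  B <- net@params$blocks
  sl <- cfg@slope
  x <- dim4(x)

  e1 <- blockForward(B$enc1, x, sl, keep)
  p1 <- maxpool3_fwd(e1$out, dim(e1$out), pd)
  e2 <- blockForward(B$enc2, p1$y, sl, keep)
  p2 <- maxpool3_fwd(e2$out, dim(e2$out), pd)
  e3 <- blockForward(B$enc3, p2$y, sl, keep)
  p3 <- maxpool3_fwd(e3$out, dim(e3$out), pd)
  bt <- blockForward(B$btl, p3$y, sl, keep)

  u3 <- maxunpool3(bt$out, p3$idx, length(e3$out), dim(e3$out))
  d3 <- blockForward(B$dec3, abind4(u3, e3$out), sl, keep)
  u2 <- maxunpool3(d3$out, p2$idx, length(e2$out), dim(e2$out))
  d2 <- blockForward(B$dec2, abind4(u2, e2$out), sl, keep)
  u1 <- maxunpool3(d2$out, p1$idx, length(e1$out), dim(e1$out))
  d1 <- blockForward(B$dec1, abind4(u1, e1$out), sl, keep)

  rh <- net@params$regionHead
  regionLogits <- conv3_fwd(d1$out, dim(d1$out), rh$W, dim(rh$W), rh$b)
  brainLogit <- NULL
  if (!is.null(net@params$brainHead)) {
    bh <- net@params$brainHead
    brainLogit <- conv3_fwd(d1$out, dim(d1$out), bh$W, dim(bh$W), bh$b)
  }
  sm <- softmax4(regionLogits)
  list(regionProbs = sm,
       brainProb = if (!is.null(brainLogit)) plogis(adrop4(brainLogit)),
       cache = if (keep)
         list(e1 = e1, e2 = e2, e3 = e3, bt = bt, d3 = d3, d2 = d2, d1 = d1,
              p1 = p1, p2 = p2, p3 = p3, d1out = d1$out,
              regionProbs = sm,
              brainProb = if (!is.null(brainLogit)) plogis(adrop4(brainLogit))))
}

# concatenate two 4D arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

softmax4 <- function(l) {
  d <- dim(l)
  pm <- matrix(l, prod(d[1:3]), d[4])
  mx <- Reduce(pmax, lapply(seq_len(d[4]), function(c) pm[, c]))
  pm <- exp(pm - mx)
  array(pm / rowSums(pm), d)
}

adrop4 <- function(x) {
  d <- dim(x)
  array(x, d[1:3])
}

# Backward pass: gradients of the loss w.r.t. the two logit tensors in,
# parameter gradients (same structure as params) out.
netBackward <- function(net, fw, gRegionLogits, gBrainLogit = NULL) {
  cfg <- net@config; sl <- cfg@slope
  B <- net@params$blocks; ca <- fw$cache
  g <- list(blocks = list())

  rh <- net@params$regionHead
  cbR <- conv3_bwd(ca$d1out, dim(ca$d1out), rh$W, dim(rh$W), gRegionLogits)
  g$regionHead <- list(W = cbR$gw, b = cbR$gb)
  gd1 <- cbR$gx
  if (!is.null(net@params$brainHead) && !is.null(gBrainLogit)) {
    bh <- net@params$brainHead
    cbB <- conv3_bwd(ca$d1out, dim(ca$d1out), bh$W, dim(bh$W), gBrainLogit)
    g$brainHead <- list(W = cbB$gw, b = cbB$gb)
    gd1 <- gd1 + cbB$gx
  }

  splitChan <- function(gin, n1) {
    d <- dim(gin)
    list(a = array(gin[, , , seq_len(n1)], c(d[1:3], n1)),
         b = array(gin[, , , n1 + seq_len(d[4] - n1)], c(d[1:3], d[4] - n1)))
  }

  bd1 <- blockBackward(B$dec1, ca$d1$caches, gd1, sl)
  s1 <- splitChan(bd1$gin, cfg@channels[1])
  gD2 <- maxunpool3_bwd(s1$a, ca$p1$idx, dim(ca$d2$out))
  bd2 <- blockBackward(B$dec2, ca$d2$caches, gD2, sl)
  s2 <- splitChan(bd2$gin, cfg@channels[2])
  gD3 <- maxunpool3_bwd(s2$a, ca$p2$idx, dim(ca$d3$out))
  bd3 <- blockBackward(B$dec3, ca$d3$caches, gD3, sl)
  s3 <- splitChan(bd3$gin, cfg@channels[4])
  gBT <- maxunpool3_bwd(s3$a, ca$p3$idx, dim(ca$bt$out))
  bbt <- blockBackward(B$btl, ca$bt$caches, gBT, sl)

  gP3 <- bbt$gin
  gE3 <- maxpool3_bwd(gP3, ca$p3$idx, length(ca$e3$out), dim(ca$e3$out)) + s3$b
  be3 <- blockBackward(B$enc3, ca$e3$caches, gE3, sl)
  gE2 <- maxpool3_bwd(be3$gin, ca$p2$idx, length(ca$e2$out), dim(ca$e2$out)) + s2$b
  be2 <- blockBackward(B$enc2, ca$e2$caches, gE2, sl)
  gE1 <- maxpool3_bwd(be2$gin, ca$p1$idx, length(ca$e1$out), dim(ca$e1$out)) + s1$b
  be1 <- blockBackward(B$enc1, ca$e1$caches, gE1, sl)

  g$blocks <- list(enc1 = be1$grads, enc2 = be2$grads, enc3 = be3$grads,
                   btl = bbt$grads, dec3 = bd3$grads, dec2 = bd2$grads,
                   dec1 = bd1$grads)
  g
}

sliceAxis <- function(cfg, spacing) {
  if (cfg@dimensionality == 3L) return(3L)
  which.max(spacing)
}

permToSliceLast <- function(ax) {
  if (ax == 3L) 1:3 else if (ax == 2L) c(1L, 3L, 2L) else c(3L, 2L, 1L)
}

#' Per-voxel class probabilities for a volume
#'
#' Runs the network on a (standardized) volume and returns the raw
#' probability maps of both heads.  For the 2D variant the slice axis (the
#' lowest-resolution axis by spacing) is moved into the per-slice position
#' internally and the outputs are returned in the input orientation.
#'
#' @param net a [MUNet-class].
#' @param v a [VolumeGrid-class], standardized (see [standardizeVolume()]).
#' @return A [Prediction-class].
#' @export
predictProbs <- function(net, v) {
  stopifnot(is(net, "MUNet"), is(v, "VolumeGrid"))
  x <- v@data
  m <- mean(x); vv <- mean((x - m)^2)
  if (abs(m) > 0.1 || vv < 0.5 || vv > 2)
    warning("predictProbs: input does not look standardized (mean ",
            signif(m, 3), ", variance ", signif(vv, 3), ")")
  perm <- permToSliceLast(sliceAxis(net@config, v@spacing))
  xp <- aperm(x, perm)
  fw <- netForward(net, xp, keep = FALSE)
  inv <- order(perm)
  rp <- fw$regionProbs
  rp2 <- array(0, c(dim(x), dim(rp)[4]))
  for (c in seq_len(dim(rp)[4]))
    rp2[, , , c] <- aperm(array(rp[, , , c], dim(xp)), inv)
  bp <- if (!is.null(fw$brainProb)) aperm(fw$brainProb, inv)
        else array(0, dim(x))
  Prediction(rp2, bp)
}

#' Decode a volume into a label map
#'
#' Labels are the per-voxel argmax of the region probabilities (ties go to
#' the lowest class index); the brain mask thresholds the skull-stripping
#' head at 0.5.
#'
#' @param net a [MUNet-class].
#' @param v a standardized [VolumeGrid-class].
#' @return A [LabelMap-class].
#' @export
predictLabels <- function(net, v) {
  pr <- predictProbs(net, v)
  decodePrediction(pr, v@spacing, v@affine)
}

#' Turn a [Prediction-class] into a [LabelMap-class]
#'
#' @param pr a Prediction.
#' @param spacing,affine voxel geometry to attach.
#' @return A [LabelMap-class].
#' @export
decodePrediction <- function(pr, spacing, affine = NULL) {
  d <- dim(pr@regionProbs)
  pm <- matrix(pr@regionProbs, nrow = prod(d[1:3]), ncol = d[4])
  lab <- array(max.col(pm, ties.method = "first") - 1L, d[1:3])
  brain <- array(as.integer(pr@brainProb >= 0.5), d[1:3])
  LabelMap(lab, brain, spacing, affine)
}
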