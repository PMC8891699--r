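#' One-hot encode a label array
#'
#' @param labels 3D integer array with codes `0 .. nClasses - 1`.
#' @param nClasses number of classes.
#' @return 4D 0/1 array (x, y, z, class).
#' @export
oneHotLabels <- function(labels, nClasses = 3L) {
  d <- dim(labels)
  out <- array(0, c(d, nClasses))
  for (c in seq_len(nClasses))
    out[, , , c] <- as.numeric(labels == (c - 1L))
  out
}

# Generalized Dice loss on arrays, with analytic gradient w.r.t. the
# probabilities.  Class weights default to the inverse squared ground-truth
# class volumes (the form in the generalized-Dice literature); the
# `prediction` switch reproduces the variant where the weights are computed
# from the prediction instead (weights are treated as constants in the
# gradient in both cases).
gdlCore <- function(probs, onehot, weightsFrom = c("truth", "prediction"),
                    eps = 1e-5, wantGrad = FALSE) {
  weightsFrom <- match.arg(weightsFrom)
  nc <- dim(probs)[4]
  if (prod(dim(onehot)[1:3]) == 0 || sum(onehot) == 0)
    stop("generalized Dice loss: empty ground truth")
  ysum <- psum <- inter <- numeric(nc)
  for (c in seq_len(nc)) {
    yc <- onehot[, , , c]; pc <- probs[, , , c]
    ysum[c] <- sum(yc); psum[c] <- sum(pc); inter[c] <- sum(yc * pc)
  }
  base <- if (weightsFrom == "truth") ysum else psum
  w <- 1 / (base^2 + eps)
  num <- sum(w * inter)
  # the denominator guard only needs to prevent 0/0; it must not perturb
  # the perfect-overlap limit (contract: loss 0 within 1e-6)
  den <- sum(w * (ysum + psum)) + 1e-12
  L <- 1 - 2 * num / den
  grad <- NULL
  if (wantGrad) {
    grad <- array(0, dim(probs))
    for (c in seq_len(nc))
      grad[, , , c] <- -2 * (w[c] * onehot[, , , c] * den - num * w[c]) / den^2
  }
  list(value = L, weights = w, grad = grad)
}

# Brain-mask Dice term, exactly as specified: -sum(y p) / sum(y + p).
# Its minimum at perfect overlap is -1/2 (no factor 2 in the numerator).
brainCore <- function(prob, mask, wantGrad = FALSE) {
  if (sum(mask) == 0) stop("brain Dice loss: empty brain mask")
  I <- sum(mask * prob)
  S <- sum(mask) + sum(prob)
  L <- -I / S
  grad <- NULL
  if (wantGrad) grad <- -(mask * S - I) / S^2
  list(value = L, grad = grad)
}

#' Generalized Dice loss for the hippocampus task
#'
#' `1 - 2 * sum_l w_l sum_n y_ln p_ln / sum_l w_l sum_n (y_ln + p_ln)` with
#' class weights `w_l = (sum_n y_ln)^-2` (stabilised by a small epsilon in the weight denominators; the loss denominator carries only a 1e-12 guard against 0/0).
#' Setting `weightsFrom = "prediction"` computes the weights from the
#' predicted class volumes instead.
#'
#' @param pred a [Prediction-class].
#' @param truth a [LabelMap-class] (one-hot encoded internally).
#' @param weightsFrom `"truth"` (default) or `"prediction"`.
#' @return The loss value in [0, 1], with the class weights attached as
#'   attribute `"weights"`.
#' @export
generalizedDiceLoss <- function(pred, truth,
                                weightsFrom = c("truth", "prediction")) {
  stopifnot(is(pred, "Prediction"), is(truth, "LabelMap"))
  nc <- dim(pred@regionProbs)[4]
  res <- gdlCore(pred@regionProbs, oneHotLabels(truth@labels, nc), weightsFrom)
  structure(res$value, weights = res$weights)
}

#' Brain-mask Dice loss for the skull-stripping task
#'
#' `-sum_n y_n p_n / sum_n (y_n + p_n)`; attains -0.5 at perfect overlap
#' and 0 at zero overlap.
#'
#' @param pred a [Prediction-class].
#' @param truth a [LabelMap-class] with a non-empty brain mask.
#' @return The loss value in [-0.5, 0].
#' @export
brainDiceLoss <- function(pred, truth) {
  stopifnot(is(pred, "Prediction"), is(truth, "LabelMap"))
  brainCore(pred@brainProb, truth@brain)$value
}

#' Composite training loss
#'
#' Sum of the generalized Dice hippocampus term and the brain-mask Dice
#' term, with the breakdown retained for logging.
#'
#' @inheritParams generalizedDiceLoss
#' @return A `LossBreakdown` list with elements `L`, `L_HC`, `L_Brain` and
#'   `weights`; `L = L_HC + L_Brain` exactly.
#' @export
totalLoss <- function(pred, truth, weightsFrom = c("truth", "prediction")) {
  hc <- generalizedDiceLoss(pred, truth, weightsFrom)
  br <- brainDiceLoss(pred, truth)
  structure(list(L = as.numeric(hc) + br, L_HC = as.numeric(hc),
                 L_Brain = br, weights = attr(hc, "weights")),
            class = "LossBreakdown")
}
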