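#' Animal-level cross-validation folds
#'
#' Partitions animal ids into `k` folds of equal size, deterministically
#' given the seed.  All scans of one animal always share a fold.
#'
#' @param animals character vector of animal ids.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @return A `FoldPlan`: list(folds = list of id vectors, k, seed).
#' @export
makeFolds <- function(animals, k = 6L, seed = 1L) {
  n <- length(animals)
  if (n %% k != 0L)
    stop("makeFolds: ", n, " animals cannot be split into ", k,
         " folds of equal size")
  sz <- n %/% k
  sh <- withSeed(seed, sample(animals))
  folds <- split(sh, rep(seq_len(k), each = sz))
  structure(list(folds = unname(folds), k = as.integer(k),
                 seed = as.integer(seed)), class = "FoldPlan")
}

# near-equal random partition used for the nested validation folds
nestedPartition <- function(animals, k, seed) {
  sh <- withSeed(seed, sample(animals))
  unname(split(sh, rep(seq_len(k), length.out = length(sh))))
}

#' Ensemble of trained networks
#'
#' @slot members list of [MUNet-class] networks, one per nested fold.
#' @slot histories per-member training histories.
#' @slot manifests per-member lists of train/validation animal ids.
#' @slot testAnimals animals excluded from all training and validation.
#' @export
setClass("MUNetEnsemble",
  representation(members = "list", histories = "list", manifests = "list",
                 testAnimals = "character"))

setMethod("show", "MUNetEnsemble", function(object) {
  cat(sprintf("MUNetEnsemble with %d members; held-out animals: %s\n",
              length(object@members),
              paste(object@testAnimals, collapse = ", ")))
})

#' Train a majority-vote ensemble with nested validation folds
#'
#' The scans of the held-out test animals are excluded from every training
#' and validation set.  The remaining animals are randomly divided into
#' `k` nested folds; one network per nested fold is trained on the other
#' `k - 1` folds with that fold as its early-stopping validation set.
#'
#' @param samples list of cohort samples (elements `volume`, `labels`,
#'   `animal`, ...), e.g. from [generateCohort()].
#' @param testAnimals ids of the outer test fold.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()]; member j trains with seed
#'   `trainCfg$seed + j`.
#' @param k number of nested folds (= ensemble size).
#' @return A [MUNetEnsemble-class].
#' @export
trainEnsemble <- function(samples, testAnimals, modelCfg = modelConfig(),
                          trainCfg = trainConfig(), k = 6L) {
  pool <- samples[!vapply(samples, function(s) s$animal %in% testAnimals, TRUE)]
  poolAnimals <- unique(vapply(pool, `[[`, "", "animal"))
  if (length(poolAnimals) < k)
    stop("trainEnsemble: need at least ", k, " training animals")
  folds <- nestedPartition(poolAnimals, k, trainCfg$seed)
  members <- histories <- manifests <- vector("list", k)
  for (j in seq_len(k)) {
    valAnimals <- folds[[j]]
    isVal <- vapply(pool, function(s) s$animal %in% valAnimals, TRUE)
    cfg <- trainCfg; cfg$seed <- trainCfg$seed + j
    net <- buildNetwork(modelCfg, seed = cfg$seed)
    res <- trainSingle(net, pool[!isVal], pool[isVal], cfg)
    members[[j]] <- res$net
    histories[[j]] <- res$history
    manifests[[j]] <- list(train = setdiff(poolAnimals, valAnimals),
                           val = valAnimals)
  }
  new("MUNetEnsemble", members = members, histories = histories,
      manifests = manifests, testAnimals = as.character(testAnimals))
}

#' Majority-vote label fusion
#'
#' Per-voxel modal label across candidate segmentations (registered
#' atlases or ensemble members).  Ties are broken by the mean class
#' probability when probability maps are supplied, otherwise by the lowest
#' class index.  The brain mask is fused the same way (a tie falls back to
#' mean brain probability, else to background).
#'
#' @param labelMaps list of [LabelMap-class] objects with identical shape.
#' @param predictions optional list of [Prediction-class] objects matching
#'   `labelMaps`, used only for tie-breaking.
#' @return The fused [LabelMap-class].
#' @export
fuseMajority <- function(labelMaps, predictions = NULL) {
  stopifnot(length(labelMaps) >= 1)
  d <- dim(labelMaps[[1]]@labels)
  for (l in labelMaps)
    if (!identical(dim(l@labels), d))
      stop("fuseMajority: label maps differ in shape")
  n <- prod(d); nc <- 3L
  cnt <- matrix(0L, n, nc)
  for (l in labelMaps) {
    lab <- as.integer(l@labels)
    for (c in seq_len(nc) - 1L)
      cnt[, c + 1L] <- cnt[, c + 1L] + (lab == c)
  }
  win <- max.col(cnt, ties.method = "first")   # lowest index on ties
  if (!is.null(predictions)) {
    mx <- do.call(pmax, lapply(seq_len(nc), function(c) cnt[, c]))
    tied <- rowSums(cnt == mx) > 1L
    if (any(tied)) {
      mp <- matrix(0, n, nc)
      for (p in predictions)
        mp <- mp + matrix(p@regionProbs, n, nc)
      mp[cnt < mx] <- -Inf
      win[tied] <- max.col(mp, ties.method = "first")[tied]
    }
  }
  labels <- array(win - 1L, d)
  nb <- length(labelMaps)
  bvotes <- Reduce(`+`, lapply(labelMaps, function(l) as.integer(l@brain)))
  brain <- as.integer(bvotes * 2L > nb)
  if (nb %% 2L == 0L) {
    tieB <- bvotes * 2L == nb
    if (any(tieB) && !is.null(predictions)) {
      mb <- Reduce(`+`, lapply(predictions, function(p) p@brainProb)) / nb
      brain[tieB] <- as.integer(mb[tieB] >= 0.5)
    }
  }
  LabelMap(labels, array(brain, d), labelMaps[[1]]@spacing,
           labelMaps[[1]]@affine)
}

#' Segment a volume with a network or ensemble
#'
#' Standardizes the volume, runs every member, fuses member label maps by
#' majority voting (mean probabilities break ties) and optionally applies
#' the morphological post-processing.
#'
#' @param model a [MUNet-class] or [MUNetEnsemble-class].
#' @param v a [VolumeGrid-class] (raw intensities; standardized internally).
#' @param postprocess apply [postprocessSegmentation()] to the result.
#' @return A [LabelMap-class].
#' @export
segmentVolume <- function(model, v, postprocess = TRUE) {
  sv <- standardizeVolume(v)
  out <- if (is(model, "MUNet")) {
    decodePrediction(predictProbs(model, sv), v@spacing, v@affine)
  } else if (is(model, "MUNetEnsemble")) {
    preds <- lapply(model@members, predictProbs, v = sv)
    maps <- lapply(preds, decodePrediction, spacing = v@spacing,
                   affine = v@affine)
    fuseMajority(maps, preds)
  } else stop("segmentVolume: model must be a MUNet or MUNetEnsemble")
  if (postprocess) postprocessSegmentation(out) else out
}

#' Cohort plan for the registration experiment
#'
#' @param animals character vector of animal ids.
#' @param foldSize animals per fold (2 for the 12-animal isotropic-style
#'   design, 1 for the 6-animal anisotropic-style design).
#' @param timepoints imaging days.
#' @param missing optional data.frame (`animal`, `timepoint`) of scans
#'   without annotation.
#' @param seed fold-assignment seed.
#' @return A `CohortPlan` list.
#' @export
registrationCohortPlan <- function(animals, foldSize, timepoints,
                                   missing = NULL, seed = 1L) {
  k <- length(animals) %/% foldSize
  fp <- makeFolds(animals, k, seed)
  structure(list(animals = animals, folds = fp$folds,
                 timepoints = as.integer(timepoints), missing = missing),
            class = "CohortPlan")
}

#' Enumerate within-timepoint atlas-to-target registrations
#'
#' For each timepoint and each annotated, available target scan, one
#' registration per annotated available atlas animal outside the target's
#' fold (the whole fold is excluded, not just the target itself).
#'
#' @param plan a [registrationCohortPlan()].
#' @return list(pairs = data.frame(atlas, target, timepoint),
#'   count = nrow(pairs)).
#' @export
planRegistrations <- function(plan) {
  stopifnot(inherits(plan, "CohortPlan"))
  foldOf <- function(a)
    which(vapply(plan$folds, function(f) a %in% f, TRUE))
  avail <- function(a, t) {
    is.null(plan$missing) ||
      !any(plan$missing$animal == a & plan$missing$timepoint == t)
  }
  rows <- list()
  for (t in plan$timepoints) {
    present <- plan$animals[vapply(plan$animals, avail, TRUE, t = t)]
    for (target in present) {
      fold <- plan$folds[[foldOf(target)]]
      atlases <- setdiff(present, fold)
      if (length(atlases))
        rows[[length(rows) + 1L]] <-
          data.frame(atlas = atlases, target = target, timepoint = t,
                     stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(atlas = character(), target = character(),
                           timepoint = integer())
  list(pairs = pairs, count = nrow(pairs))
}
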