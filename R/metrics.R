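asMask <- function(x) {
  if (is(x, "LabelMap")) stop("pass a binary array, not a LabelMap")
  x > 0
}

#' Dice overlap score
#'
#' `2 |Y n Yt| / (|Y| + |Yt|)`: 1 at perfect overlap, 0 at none.
#'
#' @param y predicted binary mask (3D array).
#' @param yt ground-truth binary mask; must be non-empty.
#' @return Dice score in [0, 1].
#' @export
diceScore <- function(y, yt) {
  y <- asMask(y); yt <- asMask(yt)
  stopifnot(identical(dim(y), dim(yt)))
  if (!any(yt)) stop("diceScore: empty ground truth")
  2 * sum(y & yt) / (sum(y) + sum(yt))
}

#' 95th-percentile Hausdorff distance in millimetres
#'
#' Surface voxels are mask voxels with an exposed face (6-neighbourhood,
#' array borders count as exposure).  Distances between surfaces are
#' measured in mm through the voxel spacing, so anisotropy is respected;
#' the reported value is the maximum of the two directed 95th percentiles
#' (linear-interpolation quantiles).
#'
#' @param y,yt non-empty binary masks.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return HD95 in mm (0 for identical masks).
#' @export
hd95 <- function(y, yt, spacing) {
  y <- asMask(y); yt <- asMask(yt)
  stopifnot(identical(dim(y), dim(yt)), length(spacing) == 3L)
  if (!any(y) || !any(yt)) stop("hd95: empty mask")
  d1 <- surface_dists(y, yt, dim(y), as.numeric(spacing))
  d2 <- surface_dists(yt, y, dim(y), as.numeric(spacing))
  max(quantile(d1, 0.95, names = FALSE, type = 7),
      quantile(d2, 0.95, names = FALSE, type = 7))
}

#' Volume similarity
#'
#' `1 - ||Yt| - |Y|| / (|Yt| + |Y|)`: depends only on the two volumes,
#' not on their overlap.
#'
#' @param y,yt binary masks, not both empty.
#' @return Volume similarity in [0, 1].
#' @export
volumeSimilarity <- function(y, yt) {
  y <- asMask(y); yt <- asMask(yt)
  ny <- sum(y); nt <- sum(yt)
  if (ny + nt == 0) stop("volumeSimilarity: both masks empty")
  1 - abs(nt - ny) / (nt + ny)
}

# exposed-face surface area in mm^2 (deterministic voxel-set measure)
surfaceAreaMM <- function(m, spacing) {
  d <- dim(m)
  vox <- prod(spacing)
  shift <- function(mask, ax, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by > 0) { src[[ax]] <- seq_len(d[ax] - by); dst[[ax]] <- seq_len(d[ax] - by) + by }
    else { src[[ax]] <- seq_len(d[ax] + by) - by; dst[[ax]] <- seq_len(d[ax] + by) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    out
  }
  area <- 0
  for (ax in 1:3) {
    faceArea <- vox / spacing[ax]
    area <- area + faceArea * (sum(m & !shift(m, ax, 1)) +
                               sum(m & !shift(m, ax, -1)))
  }
  area
}

#' Compactness score
#'
#' Compactness of a voxel set is `area^1.5 / volume` with the surface area
#' from exposed-face counting (per-face mm^2 areas) and the volume in
#' mm^3.  The score compares prediction and truth:
#' `CS = 1 - 2 |C - C_GT| / (C + C_GT)`, equal to 1 exactly when the two
#' compactness values agree.
#'
#' @param y,yt non-empty binary masks.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return Compactness score (<= 1).
#' @export
compactnessScore <- function(y, yt, spacing) {
  y <- asMask(y); yt <- asMask(yt)
  if (!any(y) || !any(yt)) stop("compactnessScore: empty mask")
  vox <- prod(spacing)
  C <- surfaceAreaMM(y, spacing)^1.5 / (sum(y) * vox)
  Cg <- surfaceAreaMM(yt, spacing)^1.5 / (sum(yt) * vox)
  1 - 2 * abs(C - Cg) / (C + Cg)
}

#' Precision and recall
#'
#' Precision is the fraction of predicted voxels that are true positives;
#' recall the fraction of ground-truth voxels recovered.
#'
#' @param y,yt binary masks; `y` must be non-empty for precision, `yt` for
#'   recall.
#' @return Named numeric: `precision`, `recall`.
#' @export
precisionRecall <- function(y, yt) {
  y <- asMask(y); yt <- asMask(yt)
  if (!any(y)) stop("precisionRecall: empty prediction (precision undefined)")
  if (!any(yt)) stop("precisionRecall: empty ground truth (recall undefined)")
  tp <- sum(y & yt)
  c(precision = tp / sum(y), recall = tp / sum(yt))
}

#' Six-metric evaluation of a segmentation against ground truth
#'
#' Computes Dice, HD95 (mm), volume similarity, compactness score,
#' precision and recall per hippocampus, plus predicted and true region
#' volumes in mm^3.  Metrics whose preconditions fail (e.g. an empty
#' predicted region) are recorded as `NA` with the reason in the
#' `"notes"` attribute.
#'
#' @param pred predicted [LabelMap-class].
#' @param truth ground-truth [LabelMap-class], aligned with `pred`.
#' @return A `MetricsReport` data.frame with one row per ROI
#'   (`ipsi`, `contra`).
#' @export
evaluatePair <- function(pred, truth) {
  stopifnot(is(pred, "LabelMap"), is(truth, "LabelMap"))
  if (!identical(dim(pred@labels), dim(truth@labels)))
    stop("evaluatePair: label maps are not aligned")
  sp <- truth@spacing
  vox <- prod(sp)
  notes <- character()
  tryMetric <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, paste0(what, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  rows <- lapply(c(ipsi = 1L, contra = 2L), function(code) {
    y <- pred@labels == code
    yt <- truth@labels == code
    roi <- if (code == 1L) "ipsi" else "contra"
    prec <- tryMetric(paste0(roi, "/precision"), {
      if (!any(y)) stop("empty prediction (precision undefined)")
      sum(y & yt) / sum(y)
    })
    rec <- tryMetric(paste0(roi, "/recall"), {
      if (!any(yt)) stop("empty ground truth (recall undefined)")
      sum(y & yt) / sum(yt)
    })
    data.frame(
      roi = roi,
      dice = tryMetric(paste0(roi, "/dice"), diceScore(y, yt)),
      hd95 = tryMetric(paste0(roi, "/hd95"), hd95(y, yt, sp)),
      vs = tryMetric(paste0(roi, "/vs"), volumeSimilarity(y, yt)),
      cs = tryMetric(paste0(roi, "/cs"), compactnessScore(y, yt, sp)),
      precision = prec,
      recall = rec,
      volume_pred = sum(y) * vox,
      volume_truth = sum(yt) * vox,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("MetricsReport", "data.frame")
  attr(out, "notes") <- notes
  out
}
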