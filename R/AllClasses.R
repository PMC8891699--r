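#' VolumeGrid: a single-channel 3D image with voxel geometry
#'
#' Container for one MR volume: a 3D numeric array of intensities together
#' with the voxel spacing in millimetres and a 4x4 affine orientation
#' matrix.  All downstream operations (training, evaluation, volumetry)
#' interpret distances through the spacing, so anisotropic acquisitions
#' (e.g. 0.15 x 0.15 mm in-plane with 0.5 mm slices) are handled without
#' resampling.
#'
#' @slot data 3D numeric array, arbitrary intensity units.
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @slot affine 4x4 orientation matrix mapping voxel indices to world mm.
#' @export
setClass("VolumeGrid",
  representation(data = "array", spacing = "numeric", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array")
    if (any(dim(object@data) < 1L))
      return("all dimensions must be >= 1")
    if (anyNA(object@data) || !all(is.finite(object@data)))
      return("data contains non-finite values")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three strictly positive numbers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be a 4x4 matrix")
    TRUE
  })

#' Construct a VolumeGrid
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param affine optional 4x4 orientation matrix; defaults to a diagonal
#'   scaling by the spacing.
#' @return A [VolumeGrid-class] object.
#' @examples
#' v <- VolumeGrid(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(0.16, 0.16, 0.16))
#' voxelSpacing(v)
#' @export
VolumeGrid <- function(data, spacing, affine = NULL) {
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("VolumeGrid", data = data, spacing = as.numeric(spacing),
      affine = affine)
}

#' LabelMap: hippocampus labels plus a brain mask
#'
#' Integer-coded segmentation aligned with a [VolumeGrid-class]: label 0 is
#' background, label 1 the hippocampus ipsilateral to the (left-hemisphere)
#' injury and label 2 the contralateral hippocampus.  The binary brain mask
#' produced by the skull-stripping task is carried separately so that the
#' two outputs of the network stay independent.
#'
#' @slot labels 3D integer array with values in {0, 1, 2}.
#' @slot brain 3D binary (0/1) array of the brain mask.
#' @slot spacing,affine voxel geometry as in [VolumeGrid-class].
#' @export
setClass("LabelMap",
  representation(labels = "array", brain = "array", spacing = "numeric",
                 affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L || length(dim(object@brain)) != 3L)
      return("labels and brain must be 3D arrays")
    if (!identical(dim(object@labels), dim(object@brain)))
      return("labels and brain must share a shape")
    if (!all(object@labels %in% 0:2))
      return("labels must take values in {0, 1, 2}")
    if (!all(object@brain %in% 0:1))
      return("brain must be binary")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three strictly positive numbers")
    TRUE
  })

#' Construct a LabelMap
#'
#' @param labels 3D array with integer codes 0 (background), 1 (ipsilateral
#'   hippocampus), 2 (contralateral hippocampus).
#' @param brain 3D binary array (brain mask); defaults to all-zero.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param affine optional 4x4 orientation matrix.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(labels, brain = NULL, spacing, affine = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(brain)) brain <- array(0L, dim(labels))
  storage.mode(brain) <- "integer"
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("LabelMap", labels = labels, brain = brain,
      spacing = as.numeric(spacing), affine = affine)
}

#' Prediction: per-voxel class probabilities from the two network heads
#'
#' Holds the 3-class softmax output of the region head (background,
#' ipsilateral hippocampus, contralateral hippocampus) and the sigmoid
#' output of the brain-mask head, both at the spatial resolution of the
#' input volume.
#'
#' @slot regionProbs 4D array (x, y, z, class) of probabilities summing to
#'   one over the class axis.
#' @slot brainProb 3D array of brain-mask probabilities in [0, 1].
#' @export
setClass("Prediction",
  representation(regionProbs = "array", brainProb = "array"),
  validity = function(object) {
    d <- dim(object@regionProbs)
    if (length(d) != 4L) return("regionProbs must be a 4D array")
    if (!identical(d[1:3], dim(object@brainProb)))
      return("regionProbs and brainProb must share spatial shape")
    pm <- matrix(object@regionProbs, prod(d[1:3]), d[4])
    if (max(abs(rowSums(pm) - 1)) > 1e-5)
      return("regionProbs must sum to 1 per voxel (tolerance 1e-5)")
    if (min(object@brainProb) < 0 || max(object@brainProb) > 1)
      return("brainProb must lie in [0, 1]")
    TRUE
  })

#' @rdname Prediction-class
#' @param regionProbs 4D probability array (x, y, z, class).
#' @param brainProb 3D probability array.
#' @export
Prediction <- function(regionProbs, brainProb) {
  new("Prediction", regionProbs = regionProbs, brainProb = brainProb)
}

# ---- accessors -------------------------------------------------------------

#' @title Accessors for image containers
#' @description `volumeData` returns the intensity array of a
#'   [VolumeGrid-class]; `voxelSpacing` the mm spacing of a volume or label
#'   map; `labelArray` and `brainMask` the two arrays of a
#'   [LabelMap-class]; `voxelVolume` the volume of one voxel in cubic mm.
#' @param x a VolumeGrid or LabelMap.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setMethod("volumeData", "VolumeGrid", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setMethod("labelArray", "LabelMap", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setMethod("brainMask", "LabelMap", function(x) x@brain)

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setMethod("voxelVolume", "VolumeGrid", function(x) prod(x@spacing))
#' @rdname accessors
#' @export
setMethod("voxelVolume", "LabelMap", function(x) prod(x@spacing))

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  n1 <- sum(object@labels == 1L); n2 <- sum(object@labels == 2L)
  cat(sprintf("LabelMap %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  ipsilateral HC %d vox, contralateral HC %d vox, brain %d vox\n",
              n1, n2, sum(object@brain == 1L)))
})
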