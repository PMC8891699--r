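#' Read a NIfTI volume
#'
#' Loads a NIfTI-1 image (.nii or .nii.gz) into a [VolumeGrid-class].  Voxel
#' spacing is taken from the header `pixdim`; trailing singleton dimensions
#' (e.g. a 4D file with one frame) are squeezed.
#'
#' @param path path to an existing NIfTI file.
#' @return A [VolumeGrid-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("readVolume: file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # strip image classes
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L)
    stop("readVolume: expected a 3D payload, got dimensions ",
         paste(dim(as.array(img)), collapse = " x "))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("readVolume: header has zero or negative voxel spacing")
  sp <- signif(sp, 7)   # undo float32 header storage noise
  if (anyNA(arr) || !all(is.finite(arr)))
    stop("readVolume: volume contains non-finite values")
  aff <- tryCatch(unclass(RNifti::xform(img))[1:4, 1:4],
                  error = function(e) diag(c(sp, 1)))
  VolumeGrid(arr, sp, structure(aff, dimnames = NULL))
}

#' Write a volume as NIfTI
#'
#' @param v a [VolumeGrid-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "VolumeGrid"))
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map (and optional brain mask) from NIfTI
#'
#' Labels are stored as a uint8 NIfTI with codes 0/1/2; the brain mask, if
#' present, is a second 0/1 NIfTI next to it.
#'
#' @param path path to the label NIfTI.
#' @param brainPath optional path to the brain-mask NIfTI.
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path, brainPath = NULL) {
  v <- readVolume(path)
  lab <- round(v@data)
  if (!all(lab %in% 0:2))
    stop("readLabelMap: label codes outside {0, 1, 2}")
  brain <- NULL
  if (!is.null(brainPath)) {
    b <- readVolume(brainPath)
    if (!identical(dim(b@data), dim(lab)))
      stop("readLabelMap: brain mask shape differs from labels")
    brain <- array(as.integer(b@data > 0.5), dim(lab))
  }
  LabelMap(lab, brain, v@spacing, v@affine)
}

#' Write a label map (and its brain mask) as NIfTI
#'
#' @param l a [LabelMap-class].
#' @param path output path for the labels.
#' @param brainPath optional output path for the brain mask.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(l, path, brainPath = NULL) {
  stopifnot(is(l, "LabelMap"))
  img <- RNifti::asNifti(l@labels + 0)
  RNifti::pixdim(img) <- l@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  if (!is.null(brainPath)) {
    bimg <- RNifti::asNifti(l@brain + 0)
    RNifti::pixdim(bimg) <- l@spacing
    RNifti::writeNifti(bimg, brainPath, datatype = "uint8")
  }
  invisible(path)
}

#' Standardize a volume to zero mean and unit variance
#'
#' Intensity normalisation applied to every volume before it enters the
#' network, matching the online per-sample normalisation used during
#' training.
#'
#' @param v a [VolumeGrid-class] with non-zero intensity variance.
#' @return A [VolumeGrid-class] whose intensities have mean 0 and variance 1.
#' @export
standardizeVolume <- function(v) {
  stopifnot(is(v, "VolumeGrid"))
  x <- v@data
  m <- mean(x)
  # population SD: the contract is variance over all voxels
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s < 1e-12)
    stop("standardizeVolume: constant volume (zero intensity variance)")
  VolumeGrid((x - m) / s, v@spacing, v@affine)
}

# Restore the caller's RNG state after running `expr` under `seed`.
# Keeps every stochastic operation a pure function of its recorded seed.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
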