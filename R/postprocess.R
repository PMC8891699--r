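#' Keep the largest connected component and fill its cavities
#'
#' Components use 26-connectivity by default; cavities are background
#' regions not 6-connected to the array border.  When several components
#' tie for the largest size, the one containing the first voxel in array
#' storage order is kept (a documented, deterministic rule).  An empty
#' input returns an empty mask with a warning.
#'
#' @param mask 3D binary array.
#' @param connectivity 26 (default) or 6.
#' @return 3D logical array.
#' @export
largestComponentFill <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L)
  m <- mask > 0
  if (!any(m)) {
    warning("largestComponentFill: empty mask")
    return(m)
  }
  lab <- cc_label(m, dim(m), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)   # first maximum = earliest component in scan order
  comp <- lab == keep
  fill_holes(comp, dim(comp))
}

#' Morphological cleanup of a decoded segmentation
#'
#' Applies [largestComponentFill()] independently to the brain mask and to
#' each hippocampus class.  Should hole filling make the two hippocampus
#' regions overlap, the contested voxels are assigned to the smaller
#' region (ties favour the ipsilateral class).
#'
#' @param l a [LabelMap-class].
#' @return The cleaned [LabelMap-class].
#' @export
postprocessSegmentation <- function(l) {
  stopifnot(is(l, "LabelMap"))
  d <- dim(l@labels)
  clean <- function(m, what) {
    if (!any(m)) {
      warning("postprocessSegmentation: ", what, " entirely absent")
      return(m > 0)
    }
    largestComponentFill(m)
  }
  b <- clean(l@brain > 0, "brain mask")
  h1 <- clean(l@labels == 1L, "ipsilateral hippocampus")
  h2 <- clean(l@labels == 2L, "contralateral hippocampus")
  both <- h1 & h2
  if (any(both)) {
    if (sum(h1) <= sum(h2)) h2[both] <- FALSE else h1[both] <- FALSE
  }
  labels <- array(0L, d)
  labels[h1] <- 1L; labels[h2] <- 2L
  LabelMap(labels, array(as.integer(b), d), l@spacing, l@affine)
}

#' Structuring element bridging sparse sagittal annotation
#'
#' A line of half-length `lineHalf` along the sparsely annotated axis,
#' dilated by a cubic 26-neighbourhood ball of radius `ballRadius`: the
#' Minkowski sum spans `2 * (lineHalf + ballRadius) + 1` voxels along the
#' sparse axis, enough to bridge single missing slices while touching the
#' remaining surface only gently.
#'
#' @param axis sparse (sagittal) axis, 1-3.
#' @param lineHalf half-length of the line component.
#' @param ballRadius radius of the cubic ball component.
#' @return Integer offset matrix (n x 3), symmetric about the origin.
#' @export
makeStructuringElement <- function(axis = 1L, lineHalf = 1L, ballRadius = 1L) {
  stopifnot(axis %in% 1:3, lineHalf >= 0, ballRadius >= 0)
  ball <- as.matrix(expand.grid(dx = -ballRadius:ballRadius,
                                dy = -ballRadius:ballRadius,
                                dz = -ballRadius:ballRadius))
  offs <- do.call(rbind, lapply(-lineHalf:lineHalf, function(s) {
    o <- ball; o[, axis] <- o[, axis] + s; o
  }))
  offs <- unique(offs)
  storage.mode(offs) <- "integer"
  dimnames(offs) <- NULL
  offs
}

#' Complete a sparsely annotated brain mask
#'
#' Binary closing with the structuring element followed by volumetric hole
#' filling, reconstructing a full mask from one annotated in every second
#' sagittal slice.
#'
#' @param sparse 3D binary array with alternating annotated/empty sagittal
#'   slices (see [sparseAnnotate()]).
#' @param element offset matrix from [makeStructuringElement()]; defaults
#'   to the sagittal-axis element.
#' @return 3D logical array.
#' @export
completeBrainMask <- function(sparse, element = makeStructuringElement(1L)) {
  stopifnot(length(dim(sparse)) == 3L)
  m <- sparse > 0
  if (!any(m)) stop("completeBrainMask: empty mask")
  nSlices <- sum(apply(m, 1, any))
  if (nSlices < 2L) {
    warning("completeBrainMask: only one annotated slice; returning input")
    return(m)
  }
  d <- dim(m)
  closed <- erode3(dilate3(m, d, element), d, element)
  fill_holes(closed, d)
}
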