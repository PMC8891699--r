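#' Specification of one synthetic rat-brain phantom
#'
#' The phantom emulates the geometry and injury phenotypes relevant to
#' hippocampus segmentation after lateral fluid-percussion injury: an
#' ellipsoidal brain with a cortical shell, two mirrored banana-shaped
#' (torus-sector) hippocampi bent around the midline axis, paired
#' ventricles, and for TBI animals a left dorsolateral cortical cavity with
#' hippocampal atrophy and displacement that grow with the post-injury
#' timepoint, plus a smooth multiplicative bias field and additive Gaussian
#' noise.  It is a geometric test-bed, not an anatomical atlas.
#'
#' @param shape integer(3) grid size; default 64 x 64 x 48.
#' @param spacing numeric(3) voxel spacing in mm; default isotropic 0.16.
#' @param injury `"sham"` or `"TBI"`.
#' @param timepointDays non-negative integer, days since injury.
#' @param lesionSeverity lesion size/intensity factor in [0, 1]; must be 0
#'   for sham.
#' @param atrophyFraction fraction of ipsilateral hippocampus volume lost,
#'   in [0, 0.5]; must be 0 for sham.
#' @param ventricleEnlargement relative ventricular dilation, >= 0.
#' @param noiseSd additive Gaussian noise SD (intensity units).
#' @param biasAmplitude amplitude of the multiplicative bias field.
#' @param seed integer seed making the phantom fully deterministic.
#' @return A `PhantomSpec` list.
#' @export
phantomSpec <- function(shape = c(64L, 64L, 48L),
                        spacing = c(0.16, 0.16, 0.16),
                        injury = c("sham", "TBI"),
                        timepointDays = 0L,
                        lesionSeverity = if (injury[1] == "TBI") 0.6 else 0,
                        atrophyFraction = 0,
                        ventricleEnlargement = 0,
                        noiseSd = 0.05,
                        biasAmplitude = 0.1,
                        seed = 1L) {
  injury <- match.arg(injury)
  if (injury == "sham" && (lesionSeverity != 0 || atrophyFraction != 0))
    stop("phantomSpec: sham animals must have zero lesion severity and atrophy")
  if (lesionSeverity < 0 || lesionSeverity > 1)
    stop("phantomSpec: lesionSeverity must lie in [0, 1]")
  if (atrophyFraction < 0 || atrophyFraction > 0.5)
    stop("phantomSpec: atrophyFraction must lie in [0, 0.5]")
  if (ventricleEnlargement < 0 || noiseSd < 0 || biasAmplitude < 0)
    stop("phantomSpec: ventricleEnlargement, noiseSd, biasAmplitude must be >= 0")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 injury = injury, timepointDays = as.integer(timepointDays),
                 lesionSeverity = lesionSeverity,
                 atrophyFraction = atrophyFraction,
                 ventricleEnlargement = ventricleEnlargement,
                 noiseSd = noiseSd, biasAmplitude = biasAmplitude,
                 seed = as.integer(seed), sizeFactor = 1),
            class = "PhantomSpec")
}

# mm coordinate grids centred on the volume, one array per axis
phantomCoords <- function(shape, spacing) {
  cx <- (shape + 1) / 2
  px <- (seq_len(shape[1]) - cx[1]) * spacing[1]
  py <- (seq_len(shape[2]) - cx[2]) * spacing[2]
  pz <- (seq_len(shape[3]) - cx[3]) * spacing[3]
  list(x = array(rep(px, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(py, each = shape[1]), times = shape[3]), shape),
       z = array(rep(pz, each = shape[1] * shape[2]), shape))
}

# Torus-sector hippocampus: ring of radius R around the vertical (y) axis
# through the midline, tube radius r, restricted to a lateral angular
# sector.  `side` +1 = right, -1 = left; centre/scale shifts implement
# atrophy displacement.
hcMask <- function(co, side, R, r, centreY, centreZ, theta1, theta2,
                   shiftX = 0, shiftY = 0) {
  px <- side * (co$x - shiftX)          # mirror for the left side
  py <- co$y - centreY - shiftY
  pz <- co$z - centreZ
  s <- sqrt(px^2 + pz^2)
  theta <- atan2(px, pz)                # 0 rostral, +pi/2 lateral
  (s - R)^2 + py^2 <= r^2 & theta >= theta1 & theta <= theta2
}

#' Generate one synthetic phantom
#'
#' Fully deterministic given the spec (including its seed): the same spec
#' yields bit-identical volume and labels.
#'
#' @param spec a [phantomSpec()].
#' @return A list with elements `volume` ([VolumeGrid-class]) and `labels`
#'   ([LabelMap-class]); label 1 is the left (ipsilateral) hippocampus.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withSeed(spec$seed, {
    shape <- spec$shape; sp <- spec$spacing
    co <- phantomCoords(shape, sp)
    ext <- shape * sp                     # field of view in mm
    sf <- spec$sizeFactor

    # brain: ellipsoid with a cortical shell
    A <- c(0.40, 0.36, 0.44) * ext * sf
    rho2 <- (co$x / A[1])^2 + (co$y / A[2])^2 + (co$z / A[3])^2
    brain <- rho2 <= 1
    cortex <- brain & rho2 > 0.62

    # hippocampi: mirrored torus sectors, dorsal third of the brain
    R <- 0.21 * min(ext[1], ext[3]) * sf
    r <- 0.085 * min(ext[1], ext[3]) * sf
    hcY <- 0.08 * ext[2]; hcZ <- -0.05 * ext[3]
    th <- c(25, 125) * pi / 180
    hcR <- hcMask(co, +1, R, r, hcY, hcZ, th[1], th[2])
    atr <- spec$atrophyFraction
    rL <- r * sqrt(1 - atr)               # volume scales with r^2
    shX <- -1.1 * atr * min(ext[1], ext[3]) / 10   # pushed toward the cavity
    shY <- 0.6 * atr * min(ext[1], ext[3]) / 10
    hcL <- hcMask(co, -1, R, rL, hcY, hcZ, th[1], th[2],
                  shiftX = shX, shiftY = shY)
    hcL <- hcL & brain; hcR <- hcR & brain
    if (!any(hcL) || !any(hcR))
      stop("generatePhantom: lesion/atrophy parameters erased a hippocampus")

    # paired ventricles near the midline, dorsal of the hippocampi
    vs <- c(0.045, 0.09, 0.13) * min(ext) * (1 + spec$ventricleEnlargement)
    vx <- 0.07 * ext[1]; vy <- 0.16 * ext[2]; vz <- 0.02 * ext[3]
    vent <- ((abs(co$x) - vx)^2 / vs[1]^2 + (co$y - vy)^2 / vs[2]^2 +
             (co$z - vz)^2 / vs[3]^2) <= 1
    vent <- vent & brain & !hcL & !hcR

    # left dorsolateral cortical cavity, adjacent to but never overlapping
    # the left hippocampus
    cavity <- array(FALSE, shape)
    if (spec$injury == "TBI" && spec$lesionSeverity > 0) {
      sev <- spec$lesionSeverity
      ls <- (c(0.05, 0.05, 0.07) + c(0.11, 0.09, 0.13) * sev) * min(ext)
      lc <- c(-0.62 * A[1], 0.40 * A[2], hcZ)
      cavity <- ((co$x - lc[1])^2 / ls[1]^2 + (co$y - lc[2])^2 / ls[2]^2 +
                 (co$z - lc[3])^2 / ls[3]^2) <= 1
      cavity <- cavity & brain & !hcL & !hcR
    }

    img <- array(0.05, shape)
    img[brain] <- 1.0
    img[cortex] <- 0.92
    img[hcL | hcR] <- 1.30
    img[vent] <- 0.35
    img[cavity] <- 0.22

    # smooth multiplicative bias: Gaussian bump at a random in-brain point
    bc <- c(runif(1, -0.3, 0.3) * ext[1], runif(1, -0.3, 0.3) * ext[2],
            runif(1, -0.3, 0.3) * ext[3])
    sig <- 0.5 * min(ext)
    bias <- 1 + spec$biasAmplitude *
      exp(-((co$x - bc[1])^2 + (co$y - bc[2])^2 + (co$z - bc[3])^2) /
            (2 * sig^2))
    img <- img * bias
    if (spec$noiseSd > 0)
      img <- img + array(rnorm(prod(shape), 0, spec$noiseSd), shape)

    labels <- array(0L, shape)
    labels[hcL] <- 1L; labels[hcR] <- 2L
    list(volume = VolumeGrid(img, sp),
         labels = LabelMap(labels, array(as.integer(brain), shape), sp))
  })
}

#' Specification of a synthetic cohort
#'
#' @param nTBI,nSham numbers of injured and sham animals.
#' @param timepoints integer vector of imaging days.
#' @param dialect `"isotropic3D"` (0.16 mm isotropic) or `"anisotropic2D"`
#'   (0.15 x 0.15 mm in-plane, 0.5 mm slices).
#' @param missing optional data.frame with columns `animal`, `timepoint`
#'   listing scans that were never annotated/acquired.
#' @param shape optional grid override.
#' @return A `CohortSpec` list; animal ids are `T01..` and `S01..`.
#' @export
cohortSpec <- function(nTBI, nSham, timepoints,
                       dialect = c("isotropic3D", "anisotropic2D"),
                       missing = NULL, shape = NULL) {
  dialect <- match.arg(dialect)
  if (nTBI < 0 || nSham < 0 || nTBI + nSham < 1)
    stop("cohortSpec: need at least one animal")
  animals <- c(if (nTBI > 0) sprintf("T%02d", seq_len(nTBI)),
               if (nSham > 0) sprintf("S%02d", seq_len(nSham)))
  group <- c(rep("TBI", nTBI), rep("sham", nSham))
  if (is.null(shape))
    shape <- if (dialect == "isotropic3D") c(64L, 64L, 48L) else c(64L, 64L, 24L)
  spacing <- if (dialect == "isotropic3D") c(0.16, 0.16, 0.16)
             else c(0.15, 0.15, 0.5)
  if (!is.null(missing)) {
    if (!all(missing$animal %in% animals))
      stop("cohortSpec: missing entries refer to unknown animals")
    if (!all(missing$timepoint %in% timepoints))
      stop("cohortSpec: missing entries refer to unknown timepoints")
  }
  structure(list(animals = animals, group = setNames(group, animals),
                 timepoints = sort(as.integer(timepoints)), dialect = dialect,
                 missing = missing, shape = as.integer(shape),
                 spacing = spacing),
            class = "CohortSpec")
}

#' Generate a synthetic cohort
#'
#' One phantom per non-missing (animal, timepoint) pair.  Per-animal random
#' effects (brain size, lesion severity) are drawn once and held constant
#' across timepoints; the atrophy fraction and ventricular enlargement of
#' TBI animals increase monotonically with the post-injury day.  Generation
#' is a pure function of (cohort, seed).
#'
#' @param cohort a [cohortSpec()].
#' @param seed integer master seed.
#' @param outDir optional directory; when given, volumes/labels/brain masks
#'   are written as NIfTI and a `manifest.csv` is created.
#' @param force overwrite an existing non-empty `outDir`.
#' @return A list with `manifest` (data.frame: animal, group,
#'   timepoint_days, volume_path, label_path, brain_path) and `samples`
#'   (in-memory list with elements volume, labels, animal, group,
#'   timepoint).
#' @export
generateCohort <- function(cohort, seed = 1L, outDir = NULL, force = FALSE) {
  stopifnot(inherits(cohort, "CohortSpec"))
  if (!is.null(outDir)) {
    if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !force)
      stop("generateCohort: output directory not empty (use force = TRUE)")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  }
  effects <- withSeed(seed, {
    lapply(setNames(nm = cohort$animals), function(a) {
      list(size = runif(1, 0.95, 1.05),
           severity = if (cohort$group[[a]] == "TBI") runif(1, 0.45, 0.85) else 0)
    })
  })
  isMissing <- function(a, t) {
    !is.null(cohort$missing) &&
      any(cohort$missing$animal == a & cohort$missing$timepoint == t)
  }
  samples <- list(); rows <- list()
  for (a in cohort$animals) {
    eff <- effects[[a]]
    for (t in cohort$timepoints) {
      if (isMissing(a, t)) next
      tbi <- cohort$group[[a]] == "TBI"
      atrophy <- if (tbi) round(0.40 * eff$severity * t / (t + 25), 4) else 0
      vent <- if (tbi) 0.8 * eff$severity * t / (t + 30) else 0
      scanSeed <- as.integer((as.numeric(seed) * 1009 +
                              match(a, cohort$animals) * 131 +
                              as.numeric(t)) %% .Machine$integer.max)
      spec <- phantomSpec(shape = cohort$shape, spacing = cohort$spacing,
                          injury = if (tbi) "TBI" else "sham",
                          timepointDays = t,
                          lesionSeverity = if (tbi) eff$severity else 0,
                          atrophyFraction = atrophy,
                          ventricleEnlargement = vent,
                          seed = scanSeed)
      spec$sizeFactor <- eff$size
      ph <- generatePhantom(spec)
      vp <- lp <- bp <- NA_character_
      if (!is.null(outDir)) {
        vp <- file.path(outDir, sprintf("%s_d%03d_vol.nii.gz", a, t))
        lp <- file.path(outDir, sprintf("%s_d%03d_lab.nii.gz", a, t))
        bp <- file.path(outDir, sprintf("%s_d%03d_brain.nii.gz", a, t))
        writeVolume(ph$volume, vp)
        writeLabelMap(ph$labels, lp, bp)
      }
      samples[[length(samples) + 1L]] <-
        list(volume = ph$volume, labels = ph$labels, animal = a,
             group = unname(cohort$group[[a]]), timepoint = t)
      rows[[length(rows) + 1L]] <-
        data.frame(animal = a, group = unname(cohort$group[[a]]),
                   timepoint_days = t, volume_path = vp, label_path = lp,
                   brain_path = bp, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir))
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, samples = samples)
}

#' Remove every second sagittal slice from a mask
#'
#' Reproduces the sparse manual annotation protocol in which only every
#' second sagittal slice of the brain mask was outlined; the result is the
#' natural input fixture for [completeBrainMask()].
#'
#' @param mask 3D binary array (full brain mask); the sagittal axis is the
#'   first array axis.
#' @return The mask with even-indexed sagittal slices zeroed.
#' @export
sparseAnnotate <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  out <- mask
  even <- seq(2L, dim(mask)[1], by = 2L)
  out[even, , ] <- 0L
  out
}
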