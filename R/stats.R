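#' Paired permutation test for a mean difference
#'
#' Two-sided test of zero mean paired difference by random sign flips.
#' When the full sign-flip group is no larger than `iterations`
#' (`2^n <= iterations`) the exact enumeration is used automatically;
#' otherwise `iterations` random sign patterns are drawn and the
#' add-one-smoothed Monte-Carlo estimate is returned.
#'
#' @param x numeric vector: first method's values, or the paired
#'   differences when `y` is `NULL`.
#' @param y optional second method's values (paired with `x`).
#' @param iterations Monte-Carlo iterations (and enumeration cutoff).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return Two-sided p-value.
#' @export
pairedPermutationTest <- function(x, y = NULL, iterations = 10000L,
                                  seed = 1L) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  if (n < 2L) stop("pairedPermutationTest: need at least 2 pairs")
  if (all(d == 0)) return(1.0)
  tObs <- abs(mean(d))
  tol <- 1e-12 * max(1, tObs)
  if (2^n <= iterations) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tPerm <- abs(as.vector(signs %*% d)) / n
    return(mean(tPerm >= tObs - tol))
  }
  hits <- withSeed(seed, {
    sum(vapply(seq_len(iterations), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      abs(mean(s * d)) >= tObs - tol
    }, TRUE))
  })
  (hits + 1) / (iterations + 1)
}

#' Bonferroni correction
#'
#' @param p vector of p-values.
#' @param m number of comparisons (defaults to `length(p)`; must be at
#'   least that).
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("bonferroniAdjust: m must be >= number of p-values")
  pmin(1, m * p)
}

#' Inter-hemispheric metric differences with bootstrap CIs
#'
#' For each evaluation metric, the per-scan difference between the
#' ipsilateral and contralateral hippocampus (ipsi - contra) is averaged
#' across scans, with a percentile bootstrap confidence interval for the
#' mean.  Scans missing either ROI for a metric are excluded pairwise and
#' the retained count reported.
#'
#' @param reports list of `MetricsReport` objects from [evaluatePair()].
#' @param nBoot bootstrap resamples (>= 2000 recommended).
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return data.frame: metric, mean_diff, ci_lo, ci_hi, n.
#' @export
interhemisphericDifferences <- function(reports, nBoot = 2000L,
                                        level = 0.95, seed = 1L) {
  if (length(reports) < 2L)
    stop("interhemisphericDifferences: need at least 2 reports")
  metrics <- c("dice", "hd95", "vs", "cs", "precision", "recall")
  alpha <- (1 - level) / 2
  withSeed(seed, {
    rows <- lapply(metrics, function(mt) {
      d <- vapply(reports, function(r) {
        r[r$roi == "ipsi", mt] - r[r$roi == "contra", mt]
      }, 0)
      d <- d[!is.na(d)]
      if (length(d) < 2L)
        return(data.frame(metric = mt, mean_diff = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          n = length(d)))
      bm <- vapply(seq_len(nBoot), function(i)
        mean(sample(d, replace = TRUE)), 0)
      data.frame(metric = mt, mean_diff = mean(d),
                 ci_lo = quantile(bm, alpha, names = FALSE),
                 ci_hi = quantile(bm, 1 - alpha, names = FALSE),
                 n = length(d))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Hippocampal volumes of a label map
#'
#' @param labels a [LabelMap-class].
#' @return Named numeric, mm^3: `ipsi` (label 1), `contra` (label 2).
#' @export
computeVolumes <- function(labels) {
  stopifnot(is(labels, "LabelMap"))
  vox <- prod(labels@spacing)
  c(ipsi = sum(labels@labels == 1L) * vox,
    contra = sum(labels@labels == 2L) * vox)
}

#' Heteroscedastic repeated-measures model of hippocampal volume
#'
#' Fits `V = alpha + bt*t + bR*R + bB*B + btR*tR + btB*tB + bRB*RB + E`
#' where `t` is the timepoint in days (continuous), `R = 1` for the
#' ipsilateral hippocampus, `B = 1` for TBI animals, and the error term
#' has a separate variance per timepoint (diagonal covariance).  The fit
#' is feasible generalized least squares iterated to convergence: OLS
#' residuals estimate the per-timepoint variances, the model is refit by
#' weighted least squares, and the two steps alternate until the variances
#' stabilise.  Wald z-tests are reported per coefficient.
#'
#' @param tab data.frame with columns `volume` (mm^3), `t` (days), `R`
#'   (0/1), `B` (0/1); typically one row per animal x timepoint x ROI.
#' @param maxIter,tol FGLS iteration controls.
#' @return A `VolumeModelFit` list: `coefficients` (term, estimate, se, z,
#'   p), `sigma2` (per-timepoint error variances), `fitted`, `residuals`,
#'   `iterations`.
#' @export
fitVolumeModel <- function(tab, maxIter = 50L, tol = 1e-8) {
  need <- c("volume", "t", "R", "B")
  if (!all(need %in% names(tab)))
    stop("fitVolumeModel: table must have columns ", paste(need, collapse = ", "))
  if (length(unique(tab$B)) < 2L || length(unique(tab$t)) < 2L ||
      length(unique(tab$R)) < 2L)
    stop("fitVolumeModel: need both groups, both ROIs and >= 2 timepoints")
  X <- stats::model.matrix(~ t + R + B + t:R + t:B + R:B, data = tab)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fitVolumeModel: rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  yv <- tab$volume
  tg <- factor(tab$t)
  w <- rep(1, nrow(X))
  sig2 <- tapply(rep(1, nrow(X)), tg, mean)   # placeholder
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- stats::lm.wfit(X, yv, w)
    res <- yv - X %*% fit$coefficients
    newSig2 <- tapply(as.vector(res)^2, tg, mean)
    w <- as.vector(1 / newSig2[as.character(tg)])
    if (iter >= maxIter ||
        max(abs(newSig2 - sig2) / pmax(newSig2, 1e-12)) < tol) {
      sig2 <- newSig2
      break
    }
    sig2 <- newSig2
  }
  beta <- fit$coefficients
  XtWX <- crossprod(X * sqrt(w))
  vcov <- solve(XtWX)
  se <- sqrt(diag(vcov))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  fitted <- as.vector(X %*% beta)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = unname(se), z = unname(z), p = unname(p),
                              stringsAsFactors = FALSE),
    sigma2 = sig2, fitted = fitted, residuals = yv - fitted,
    iterations = iter), class = "VolumeModelFit")
}

#' @export
print.VolumeModelFit <- function(x, ...) {
  cat("Heteroscedastic (per-timepoint) FGLS fit of hippocampal volume\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("Per-timepoint error variances:\n")
  print(round(x$sigma2, 4))
  invisible(x)
}

#' Build a volume table from cohort labels
#'
#' Converts per-scan label maps into the long-format table expected by
#' [fitVolumeModel()]: one row per scan and hemisphere.
#'
#' @param samples cohort samples (elements `labels`, `animal`, `group`,
#'   `timepoint`) or a list of such.
#' @param labelMaps optional list of predicted [LabelMap-class]s replacing
#'   the ground-truth labels of `samples` (same order).
#' @return data.frame: animal, B, t, R, volume.
#' @export
volumeTable <- function(samples, labelMaps = NULL) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    lm0 <- if (is.null(labelMaps)) s$labels else labelMaps[[i]]
    v <- computeVolumes(lm0)
    data.frame(animal = s$animal, B = as.integer(s$group == "TBI"),
               t = s$timepoint, R = c(1L, 0L),
               volume = c(v[["ipsi"]], v[["contra"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
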