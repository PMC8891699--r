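# Independent brute-force reference implementations used to validate the
# package's metric code.  These deliberately share no code with R/metrics.R:
# distances are accumulated with explicit loops over surface voxel pairs.

surfaceVoxelsOracle <- function(m) {
  d <- dim(m)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    exposed <- FALSE
    for (r in seq_len(6)) {
      q <- nb[r, ]
      if (any(q < 1) || any(q > d)) { exposed <- TRUE; break }
      if (!m[q[1], q[2], q[3]]) { exposed <- TRUE; break }
    }
    if (exposed) out <- rbind(out, c(i, j, k))
  }
  out
}

hd95Oracle <- function(y, yt, spacing) {
  A <- surfaceVoxelsOracle(y)
  B <- surfaceVoxelsOracle(yt)
  Amm <- A %*% diag(spacing)
  Bmm <- B %*% diag(spacing)
  directed <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(r)
      min(sqrt(rowSums(sweep(Q, 2, P[r, ])^2))), 0)
  }
  d1 <- directed(Amm, Bmm)
  d2 <- directed(Bmm, Amm)
  max(quantile(d1, 0.95, names = FALSE), quantile(d2, 0.95, names = FALSE))
}

diceOracle <- function(y, yt) {
  inter <- 0; ny <- 0; nt <- 0
  for (i in seq_along(y)) {
    inter <- inter + (y[i] && yt[i])
    ny <- ny + y[i]; nt <- nt + yt[i]
  }
  2 * inter / (ny + nt)
}

surfaceAreaOracle <- function(m, spacing) {
  d <- dim(m)
  area <- 0
  faces <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j, k]) next
    for (r in seq_len(6)) {
      q <- c(i, j, k) + faces[r, ]
      outside <- any(q < 1) || any(q > d) || !m[q[1], q[2], q[3]]
      if (outside) {
        ax <- which(faces[r, ] != 0)
        area <- area + prod(spacing) / spacing[ax]
      }
    }
  }
  area
}

csOracle <- function(y, yt, spacing) {
  vox <- prod(spacing)
  C <- surfaceAreaOracle(y, spacing)^1.5 / (sum(y) * vox)
  Cg <- surfaceAreaOracle(yt, spacing)^1.5 / (sum(yt) * vox)
  1 - 2 * abs(C - Cg) / (C + Cg)
}

# random blob mask (union of a filled ellipsoid and salt voxels)
randomMask <- function(d = c(12, 12, 12), pSalt = 0.01) {
  ctr <- runif(3, 3, d - 2)
  ax <- runif(3, 1.5, 4)
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  m <- array(((co$x - ctr[1]) / ax[1])^2 + ((co$y - ctr[2]) / ax[2])^2 +
             ((co$z - ctr[3]) / ax[3])^2 <= 1, d)
  salt <- array(runif(prod(d)) < pSalt, d)
  out <- m | salt
  if (!any(out)) out[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  out
}

# independent registration-pair enumerator: loop over all ordered pairs
registrationOracle <- function(folds, timepoints, missing = NULL) {
  animals <- unlist(folds)
  foldId <- rep(seq_along(folds), lengths(folds))
  names(foldId) <- animals
  ok <- function(a, t) is.null(missing) ||
    !any(missing$animal == a & missing$timepoint == t)
  n <- 0L
  for (t in timepoints)
    for (target in animals)
      for (atlas in animals) {
        if (atlas == target) next
        if (foldId[[atlas]] == foldId[[target]]) next
        if (!ok(target, t) || !ok(atlas, t)) next
        n <- n + 1L
      }
  n
}
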