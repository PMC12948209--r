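# 3D reconstruction: per-pixel RMS normalization, landmark-driven rigid
# registration of consecutive sections, volume assembly, and inter-slice
# correlation QC.
#
# Registration maximizes normalized cross-correlation (NCC) of the fixed
# image against the rigidly transformed moving image over the fixed
# foreground, with a 3-level multi-resolution pyramid. Each level runs a
# coarse rotation/translation sweep around the current estimate followed by
# regular-step gradient ascent (at most max_iters steps per level). The
# similarity metric and optimizer are package choices: NCC is appropriate
# for mono-modal ion images and is deterministic.

#' Compose two rigid transforms (apply \code{b} first, then \code{a})
#'
#' @param a,b \linkS4class{RigidTransform2D} objects sharing a rotation
#'   center.
#' @return the composed \linkS4class{RigidTransform2D}.
#' @export
composeRigid <- function(a, b) {
  th <- a@thetaDeg * pi / 180
  RigidTransform2D(a@thetaDeg + b@thetaDeg,
                   a@txPx + cos(th) * b@txPx - sin(th) * b@tyPx,
                   a@tyPx + sin(th) * b@txPx + cos(th) * b@tyPx)
}

#' Invert a rigid transform
#'
#' @param t a \linkS4class{RigidTransform2D}.
#' @return the inverse transform.
#' @export
invertRigid <- function(t) {
  th <- -t@thetaDeg * pi / 180
  RigidTransform2D(-t@thetaDeg,
                   -(cos(th) * t@txPx - sin(th) * t@tyPx),
                   -(sin(th) * t@txPx + cos(th) * t@tyPx))
}

#' Apply a rigid transform to a 2D image
#'
#' Resamples the image into the frame defined by the transform (rotation
#' about the image center, then translation). Out-of-frame samples are 0.
#'
#' @param img numeric matrix.
#' @param transform a \linkS4class{RigidTransform2D}.
#' @param interpolation "linear" for intensities, "nearest" for masks and
#'   label images.
#' @return transformed matrix of the same shape.
#' @export
applyRigid <- function(img, transform, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  storage.mode(img) <- "double"
  .cpp_resample_rigid(img, transform@thetaDeg, transform@txPx,
                      transform@tyPx, as.integer(interpolation == "linear"))
}

#' RMS-normalize a section
#'
#' Divides every foreground pixel's intensity vector by the root mean
#' square of its intensities across all features, the spectrum-wise
#' normalization conventional in MSI. Background pixels are untouched.
#' Foreground pixels with all-zero spectra are left unscaled and reported
#' in the \code{"qcZeroPixels"} attribute.
#'
#' @param section a \linkS4class{SectionImage}.
#' @return the normalized \linkS4class{SectionImage}.
#' @export
rmsNormalize <- function(section) {
  inten <- section@intensities
  d <- dim(inten)
  fg <- which(section@mask)
  if (!length(fg)) stop("section has no foreground pixels")
  m <- matrix(inten, d[1] * d[2], d[3])
  rms <- sqrt(rowMeans(m[fg, , drop = FALSE]^2))
  zero <- rms == 0
  scale <- ifelse(zero, 1, 1 / rms)
  m[fg, ] <- m[fg, , drop = FALSE] * scale
  out <- section
  out@intensities <- array(m, d)
  attr(out, "qcZeroPixels") <- fg[zero]
  out
}

#' Extract one feature's ion image from a section
#'
#' @param section a \linkS4class{SectionImage}.
#' @param axis the dataset \linkS4class{FeatureAxis}.
#' @param mz query m/z; must match an axis entry within \code{tolPpm}.
#' @param tolPpm match tolerance (defaults to the axis tolerance).
#' @return numeric matrix of that feature's intensities (background 0).
#' @export
extractIonImage <- function(section, axis, mz, tolPpm = tolerancePpm(axis)) {
  idx <- .resolveFeature(axis, mz, tolPpm)
  img <- section@intensities[, , idx]
  img[!section@mask] <- 0
  img
}

.resolveFeature <- function(axis, mz, tolPpm = tolerancePpm(axis)) {
  qaxis <- FeatureAxis(axis@mz, tolPpm)
  idx <- matchFeatures(qaxis, mz)
  if (is.na(idx)) {
    near <- axis@mz[order(abs(axis@mz - mz))][seq_len(min(3, length(axis@mz)))]
    stop("unknown feature: m/z ", mz, " matches no axis entry within ",
         tolPpm, " ppm; nearest entries: ", paste(near, collapse = ", "))
  }
  idx
}

# block-mean downsampling by an integer factor; masks are downsampled by any()
.shrinkImage <- function(img, f) {
  if (f == 1L) return(img)
  h <- nrow(img) %/% f * f
  w <- ncol(img) %/% f * f
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  a <- array(img, c(f, h %/% f, f, w %/% f))
  apply(a, c(2, 4), mean)
}

.shrinkMask <- function(mask, f) {
  if (f == 1L) return(mask)
  h <- nrow(mask) %/% f * f
  w <- ncol(mask) %/% f * f
  mask <- mask[seq_len(h), seq_len(w), drop = FALSE]
  a <- array(mask, c(f, h %/% f, f, w %/% f))
  apply(a, c(2, 4), any)
}

.nccAt <- function(fixed, moving, fmask, mmask, p) {
  v <- .cpp_ncc_rigid(fixed, moving, fmask, mmask, p[1], p[2], p[3])
  if (is.na(v)) -Inf else v
}

#' Register a moving 2D image to a fixed one by rigid transform
#'
#' Finds the rotation + translation maximizing normalized cross-correlation
#' of the fixed image with the transformed moving image over the fixed
#' foreground. Uses a 3-level multi-resolution pyramid; at each level a
#' coarse parameter sweep seeds regular-step gradient ascent limited to
#' \code{maxIters} iterations. Resampling is bilinear with out-of-frame
#' values of 0.
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param maxIters maximum optimizer iterations per pyramid level
#'   (default 400).
#' @param fixedMask,movingMask optional logical foreground masks; default
#'   to the positive pixels of each image. The metric is evaluated over
#'   the overlap of the fixed mask with the transformed moving mask.
#' @param searchTransPx,searchRotDeg half-widths of the coarse search at
#'   the coarsest level, in full-resolution pixels and degrees.
#' @param init starting transform (default identity); the search is
#'   centered on it, so a small search window around a good initialization
#'   restricts registration to a local polish.
#' @return a \linkS4class{RigidTransform2D} mapping moving into the fixed
#'   frame. The attributes \code{"ncc"} and \code{"converged"} report the
#'   final metric and optimizer status; degenerate (constant) inputs return
#'   the identity with a warning.
#' @export
registerPair <- function(fixed, moving, maxIters = 400, fixedMask = NULL,
                         movingMask = NULL,
                         searchTransPx = 8, searchRotDeg = 15,
                         init = RigidTransform2D(0, 0, 0)) {
  stopifnot(identical(dim(fixed), dim(moving)))
  if (is.null(fixedMask)) fixedMask <- fixed > 0
  if (is.null(movingMask)) movingMask <- moving > 0
  if (sum(fixedMask) < 4 || sd(fixed[fixedMask]) == 0 ||
      sd(as.vector(moving)) == 0) {
    warning("degenerate image pair; returning identity transform")
    out <- RigidTransform2D(0, 0, 0)
    attr(out, "converged") <- FALSE
    return(out)
  }
  storage.mode(fixed) <- storage.mode(moving) <- "double"

  p <- c(init@thetaDeg, init@txPx, init@tyPx)  # at full resolution
  converged <- TRUE
  levels <- c(4L, 2L, 1L)
  levels <- levels[levels < min(dim(fixed)) / 4]
  # small foregrounds carry no usable signal at coarse scales
  nfg <- sum(fixedMask)
  levels <- levels[levels^2 < nfg / 25]
  if (!length(levels)) levels <- 1L
  for (f in levels) {
    fx <- .shrinkImage(fixed, f)
    mv <- .shrinkImage(moving, f)
    mk <- .shrinkMask(fixedMask, f)
    mmk <- .shrinkMask(movingMask, f)
    pl <- c(p[1], p[2] / f, p[3] / f)
    # grid sweep: translations searched globally at the coarsest level and
    # locally afterwards; rotation searched over the full window at every
    # level because fine image structure carries most of the rotation signal
    if (f == max(levels)) {
      ts <- seq(-searchTransPx / f, searchTransPx / f,
                by = min(1, searchTransPx / f / 2))
    } else {
      ts <- seq(-1, 1, by = 0.5)
    }
    rs <- seq(-searchRotDeg, searchRotDeg, by = 0.75 * f)
    best <- .nccAt(fx, mv, mk, mmk, pl); bestP <- pl
    for (r in rs) for (dx in ts) for (dy in ts) {
      q <- c(pl[1] + r, pl[2] + dx, pl[3] + dy)
      v <- .nccAt(fx, mv, mk, mmk, q)
      if (v > best) { best <- v; bestP <- q }
    }
    pl <- bestP
    if (!is.finite(best)) {   # metric undefined everywhere at this level
      p <- c(pl[1], pl[2] * f, pl[3] * f)
      next
    }
    # regular-step gradient ascent in a scaled parameter space where one
    # unit of rotation moves mask pixels by about one pixel of arc
    idx <- which(mk, arr.ind = TRUE)
    rad <- sqrt(mean((idx[, 1] - (nrow(mk) + 1) / 2)^2 +
                     (idx[, 2] - (ncol(mk) + 1) / 2)^2))
    sc <- c(max(rad, 1) * pi / 180, 1, 1)
    step <- 1
    fval <- best
    it <- 0L
    while (step > 0.01 && it < maxIters) {
      it <- it + 1L
      g <- numeric(3)
      for (j in 1:3) {
        dp <- numeric(3); dp[j] <- 0.25 / sc[j]
        g[j] <- (.nccAt(fx, mv, mk, mmk, pl + dp) -
                 .nccAt(fx, mv, mk, mmk, pl - dp)) / (2 * dp[j]) / sc[j]
      }
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn < 1e-10) break
      cand <- pl + step * (g / gn) / sc
      vcand <- .nccAt(fx, mv, mk, mmk, cand)
      if (vcand > fval) { pl <- cand; fval <- vcand }
      else step <- step / 2
    }
    if (it >= maxIters) converged <- FALSE
    p <- c(pl[1], pl[2] * f, pl[3] * f)
  }
  out <- RigidTransform2D(p[1], p[2], p[3])
  attr(out, "ncc") <- .nccAt(fixed, moving, fixedMask, movingMask, p)
  attr(out, "converged") <- converged
  if (!converged)
    warning("registration hit the iteration cap; returning best-found transform")
  out
}

# Globally consistent absolute transforms from redundant pairwise rigid
# measurements. Pairs (i, j) with j - i <= span are registered raw-to-raw,
# warm-started from the chained estimates; the absolute transforms M_i
# (anchored at `mid`) are then solved by weighted least squares: rotations
# satisfy theta_j - theta_i = theta_ij (linear), and given the rotations
# the translations satisfy t_j - t_i = R(theta_i) t_ij (linear). Weights
# are the squared pair NCC, so weak pairs (tiny polar-cap sections) barely
# influence the solution.
.graphConsistentTransforms <- function(lmk, masks, chainT, mid, span,
                                       maxIters, searchTransPx = 2,
                                       searchRotDeg = 4) {
  nz <- length(lmk)
  pairs <- list()
  reg <- function(a, b, init) tryCatch(
    suppressWarnings(
      registerPair(lmk[[a]], lmk[[b]], maxIters = maxIters,
                   fixedMask = masks[[a]], movingMask = masks[[b]],
                   init = init, searchTransPx = searchTransPx,
                   searchRotDeg = searchRotDeg)),
    error = function(e) NULL)
  for (d in seq_len(min(span, nz - 1L))) {
    for (i in seq_len(nz - d)) {
      j <- i + d
      init <- composeRigid(invertRigid(chainT[[i]]), chainT[[j]])
      # symmetric measurement: forward and backward registrations are
      # averaged after inversion, cancelling first-order fixed/moving
      # asymmetry bias; their discrepancy feeds the weight
      trF <- reg(i, j, init)
      trB <- reg(j, i, invertRigid(init))
      if (is.null(trF) && is.null(trB)) next
      use <- !vapply(list(trF, trB), is.null, logical(1))
      nccs <- c(if (use[1]) attr(trF, "ncc") else NA,
                if (use[2]) attr(trB, "ncc") else NA)
      nccs[!is.finite(nccs)] <- NA
      if (all(is.na(nccs))) next
      if (use[1] && use[2]) {
        invB <- invertRigid(trB)
        dTheta <- trF@thetaDeg - invB@thetaDeg
        dT <- sqrt((trF@txPx - invB@txPx)^2 + (trF@tyPx - invB@tyPx)^2)
        theta <- (trF@thetaDeg + invB@thetaDeg) / 2
        tx <- (trF@txPx + invB@txPx) / 2
        ty <- (trF@tyPx + invB@tyPx) / 2
        wCons <- 1 / (1 + (dTheta / 0.5)^2 + (dT / 0.3)^2)
      } else {
        one <- if (use[1]) trF else invertRigid(trB)
        theta <- one@thetaDeg; tx <- one@txPx; ty <- one@tyPx
        wCons <- 0.25
      }
      ncc <- mean(nccs, na.rm = TRUE)
      if (ncc <= 0) next
      pairs[[length(pairs) + 1L]] <-
        list(i = i, j = j, theta = theta, tx = tx, ty = ty,
             w = ncc^2 * wCons)
    }
  }
  if (!length(pairs)) return(chainT)

  idx <- setdiff(seq_len(nz), mid)   # anchor: M_mid = identity
  col <- match(seq_len(nz), idx)     # NA for mid
  m <- length(pairs)
  A <- matrix(0, m, nz - 1L)
  bTheta <- numeric(m)
  w <- numeric(m)
  for (k in seq_len(m)) {
    pr <- pairs[[k]]
    if (!is.na(col[pr$j])) A[k, col[pr$j]] <- 1
    if (!is.na(col[pr$i])) A[k, col[pr$i]] <- -1
    bTheta[k] <- pr$theta
    w[k] <- pr$w
  }
  # iteratively reweighted LS (Cauchy weights) so blundered pair
  # measurements -- typically involving the tiny polar-cap sections --
  # cannot corrupt their neighbors' solutions
  irls <- function(b, scale) {
    wk <- w
    x <- NULL
    for (it in 1:4) {
      WA <- A * wk
      x <- tryCatch(solve(crossprod(WA, A), crossprod(WA, b)),
                    error = function(e) NULL)
      if (is.null(x)) return(NULL)
      r <- as.vector(b - A %*% x)
      wk <- w / (1 + (r / scale)^2)
    }
    x
  }
  theta <- irls(bTheta, 0.5)
  if (is.null(theta)) return(chainT)
  thetaAll <- numeric(nz)
  thetaAll[idx] <- theta

  bx <- numeric(m); by <- numeric(m)
  for (k in seq_len(m)) {
    pr <- pairs[[k]]
    th <- thetaAll[pr$i] * pi / 180
    bx[k] <- cos(th) * pr$tx - sin(th) * pr$ty
    by[k] <- sin(th) * pr$tx + cos(th) * pr$ty
  }
  tx <- irls(bx, 0.3)
  ty <- irls(by, 0.3)
  if (is.null(tx) || is.null(ty)) return(chainT)
  txAll <- numeric(nz); tyAll <- numeric(nz)
  txAll[idx] <- tx; tyAll[idx] <- ty

  nccOf <- function(k) {
    hit <- vapply(pairs, function(p) p$i == k - 1L && p$j == k, logical(1))
    if (any(hit)) sqrt(pairs[[which(hit)[1]]]$w) else NA_real_
  }
  lapply(seq_len(nz), function(k) {
    out <- RigidTransform2D(thetaAll[k], txAll[k], tyAll[k])
    attr(out, "ncc") <- nccOf(k)
    out
  })
}

# assemble a (z, y, x, feature) volume from a dataset without registration
#' Stack sections into a volume without registration
#'
#' Used for before-registration QC and as the assembly step of
#' \code{\link{stackDataset}}.
#'
#' @param dataset a \linkS4class{SerialSectionDataset}.
#' @return a \linkS4class{FeatureVolume} with identity transforms.
#' @export
assembleVolume <- function(dataset) {
  secs <- dataset@sections
  d <- dim(secs[[1]]@intensities)
  nz <- length(secs)
  data <- array(0, c(nz, d[1], d[2], d[3]))
  mask <- array(FALSE, c(nz, d[1], d[2]))
  for (i in seq_len(nz)) {
    data[i, , , ] <- secs[[i]]@intensities
    mask[i, , ] <- secs[[i]]@mask
  }
  FeatureVolume(data, voxelUm = c(secs[[1]]@thicknessUm,
                                  secs[[1]]@pixelSizeUm,
                                  secs[[1]]@pixelSizeUm),
                featureAxis = dataset@featureAxis, mask = mask,
                transformsApplied = replicate(nz, RigidTransform2D(0, 0, 0)))
}

#' Register and stack a serial-section dataset into a feature volume
#'
#' Slice 0 is the reference. Each subsequent slice is registered to the
#' already-transformed previous slice on the RMS-normalized landmark ion
#' image (chained reference), and the recovered transform is applied to all
#' feature channels (linear interpolation) and the mask (nearest neighbor).
#'
#' @param dataset a \linkS4class{SerialSectionDataset} with >= 2 sections.
#' @param landmarkMz m/z of the morphology-defining landmark ion.
#' @param maxIters optimizer iteration cap per pyramid level.
#' @param reference "graph" (default) measures pairwise transforms between
#'   slices up to \code{graphSpan} apart and solves a weighted
#'   least-squares consistency problem for the absolute transforms,
#'   anchored at the middle slice -- redundant measurements suppress the
#'   drift a sequential chain accumulates. "previous" chains each slice to
#'   its transformed predecessor; "middle" re-anchors the chain at the
#'   central slice.
#' @param graphSpan largest slice gap measured in graph mode.
#' @return a \linkS4class{FeatureVolume} with \code{transformsApplied}
#'   recording the per-slice transform.
#' @export
stackDataset <- function(dataset, landmarkMz, maxIters = 400,
                         reference = c("graph", "previous", "middle"),
                         graphSpan = 4L) {
  reference <- match.arg(reference)
  secs <- dataset@sections
  if (length(secs) < 2L) stop("stacking needs at least 2 sections")
  axis <- dataset@featureAxis
  li <- .resolveFeature(axis, landmarkMz)
  nz <- length(secs)
  norm <- lapply(secs, rmsNormalize)
  lmk <- lapply(norm, function(s) { g <- s@intensities[, , li]; g[!s@mask] <- 0; g })
  masks <- lapply(secs, function(s) s@mask)

  mid <- (nz + 1L) %/% 2L
  chainOrder <- if (reference == "previous") {
    list(seq(2L, nz))
  } else {
    list(seq(mid + 1L, nz), seq(mid - 1L, 1L))
  }
  transforms <- replicate(nz, RigidTransform2D(0, 0, 0))
  aligned <- lmk
  alignedMask <- masks
  for (chain in chainOrder) {
    prev <- if (reference == "previous") chain[1] - 1L else mid
    for (i in chain) {
      tr <- tryCatch(
        registerPair(aligned[[prev]], lmk[[i]], maxIters = maxIters,
                     fixedMask = alignedMask[[prev]],
                     movingMask = masks[[i]]),
        error = function(e)
          stop("registration failed at z_index ", secs[[i]]@zIndex, ": ",
               conditionMessage(e)))
      transforms[[i]] <- tr
      aligned[[i]] <- applyRigid(lmk[[i]], tr)
      alignedMask[[i]] <- applyRigid(masks[[i]] * 1, tr, "nearest") > 0
      prev <- i
    }
  }

  if (reference == "graph" && nz > 2L)
    transforms <- .graphConsistentTransforms(lmk, masks, transforms, mid,
                                             graphSpan, maxIters)

  vol <- assembleVolume(dataset)
  data <- vol@data
  mask <- vol@mask
  for (i in seq_len(nz)) {
    for (k in seq_len(dim(data)[4]))
      data[i, , , k] <- applyRigid(data[i, , , k], transforms[[i]])
    mask[i, , ] <- applyRigid(secs[[i]]@mask * 1, transforms[[i]],
                              "nearest") > 0
  }
  data[data < 0] <- 0
  FeatureVolume(data, voxelUm = vol@voxelUm, featureAxis = axis,
                mask = mask, transformsApplied = transforms)
}

#' Inter-slice correlation QC for a landmark feature
#'
#' For each pair of adjacent slices, the Pearson correlation of the landmark
#' intensities over the union of the two foreground masks (missing side
#' contributes zeros, so misalignment is penalized). Pairs with fewer than
#' 10 union voxels are skipped and listed in \code{skipped}.
#'
#' @param volume a \linkS4class{FeatureVolume} with >= 2 slices.
#' @param mz landmark m/z.
#' @return list with \code{pairs} (data.frame: z_a, z_b, correlation),
#'   \code{mean}, \code{sd}, and \code{skipped}.
#' @export
intersliceCorrelation <- function(volume, mz) {
  li <- .resolveFeature(volume@featureAxis, mz)
  nz <- dim(volume@data)[1]
  if (nz < 2L) stop("need at least 2 slices")
  res <- data.frame(z_a = integer(), z_b = integer(),
                    correlation = numeric())
  skipped <- integer()
  for (i in seq_len(nz - 1L)) {
    a <- volume@data[i, , , li];  ma <- volume@mask[i, , ]
    b <- volume@data[i + 1L, , , li]; mb <- volume@mask[i + 1L, , ]
    u <- ma | mb
    if (sum(u) < 10L) { skipped <- c(skipped, i); next }
    av <- a[u]; bv <- b[u]
    av[!ma[u]] <- 0; bv[!mb[u]] <- 0
    r <- if (sd(av) == 0 || sd(bv) == 0) NA_real_ else cor(av, bv)
    res <- rbind(res, data.frame(z_a = i - 1L, z_b = i,
                                 correlation = r))
  }
  list(pairs = res, mean = mean(res$correlation, na.rm = TRUE),
       sd = sd(res$correlation, na.rm = TRUE), skipped = skipped)
}
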