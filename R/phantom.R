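# Synthetic serial-section phantoms with full ground truth.
#
# The biculture mode emulates a ~600 um diameter spheroid of cancer cells
# with embedded fibroblast clusters, sectioned exhaustively at 20 um and
# rastered at 20 um; the organoid mode emulates a hollow cystic shell whose
# lumen is enriched in two small-mass channels. Region means, planted fold
# changes, per-voxel noise and per-section rigid perturbations are all
# recorded so registration, segmentation, object picking and statistics can
# each be validated against known truth.

.defaultMarkerSpec <- function(mode) {
  if (mode == "biculture_spheroid") {
    # regionA = cancer, regionB = fibroblast means (a.u.); lfc is the planted
    # log2 fold change of V2-class over V3-class fibroblast clusters
    # cell-type marker channels are strongly exclusive between regions, the
    # way cell-type-specific lipid ion images look in practice
    df <- data.frame(
      mz      = c(87.01, 400.25, 450.30, 500.35, 550.40, 600.30, 650.20,
                  700.10, 778.51, 792.55, 863.57, 885.55),
      regionA = c(2,     30,     20,     40,     25,     2,      2,
                  2,     100,    2,      100,    4),
      regionB = c(60,    30,     20,     40,     25,     30,     40,
                  40,    3,      100,    60,     90),
      lfc     = c(0,     0,      0,      0,      0,      1.5,    -2,
                  2,     0,      0,      0,      0),
      background = c(0,  15,     10,     0,      0,      0,      0,
                  0,     0,      0,      0,      0),
      landmark = FALSE)
    df$landmark[df$mz == 863.57] <- TRUE
  } else {
    # regionA = shell, regionB = lumen; lfc records log2(lumen/shell)
    df <- data.frame(
      mz      = c(300.10, 350.20, 505.99, 521.98, 742.54, 835.54, 861.55,
                  863.57),
      regionA = c(25,     30,     2,      2,      70,     80,     90,
                  100),
      regionB = c(25,     30,     120,    90,     8,      10,     12,
                  80),
      landmark = FALSE)
    df$lfc <- log2(df$regionB / df$regionA)
    df$background <- ifelse(df$mz %in% c(300.10, 350.20), c(12, 8)[match(df$mz, c(300.10, 350.20))], 0)
    df$landmark[df$mz == 863.57] <- TRUE
  }
  df
}

#' Construct a phantom specification
#'
#' See \linkS4class{PhantomSpec} for the meaning and defaults of every
#' field. Defaults describe the reference study conditions: 300 um spheroid
#' radius (~600 um diameter), 20 um sections and raster, independent
#' per-section perturbations up to 5 px and 10 degrees, multiplicative
#' lognormal noise sigma 0.1 with additive sigma 1 a.u.
#'
#' @param mode "biculture_spheroid" or "cystic_organoid".
#' @param spheroidRadiusUm outer radius in um.
#' @param shellThicknessUm organoid shell thickness in um.
#' @param pixelSizeUm,thicknessUm raster and section thickness in um.
#' @param nClusters embedded fibroblast cluster count (spheroid mode).
#' @param clusterRadiusRangeUm ascending pair of cluster radii (um).
#' @param markerSpec per-feature region means and planted fold changes;
#'   defaults to a 12-feature (spheroid) or 8-feature (organoid) panel.
#' @param sigmaM,sigmaA multiplicative lognormal and additive Gaussian
#'   noise sigmas.
#' @param maxTransPx,maxRotDeg per-section rigid perturbation bounds.
#' @param driftMode cumulative drift instead of independent jitter.
#' @param marginPx background margin around the spheroid footprint.
#' @param seed RNG seed; a fixed seed reproduces the phantom bit-exactly.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(mode = c("biculture_spheroid", "cystic_organoid"),
                        spheroidRadiusUm = 300, shellThicknessUm = 60,
                        pixelSizeUm = 20, thicknessUm = 20,
                        nClusters = 14L, clusterRadiusRangeUm = c(25, 72),
                        markerSpec = NULL, sigmaM = 0.1, sigmaA = 1,
                        textureSigma = 0.8, textureLengthPx = 0.8,
                        textureLengthZ = 10,
                        maxTransPx = 5, maxRotDeg = 10, driftMode = FALSE,
                        marginPx = 9L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(markerSpec)) markerSpec <- .defaultMarkerSpec(mode)
  new("PhantomSpec", mode = mode, spheroidRadiusUm = spheroidRadiusUm,
      shellThicknessUm = shellThicknessUm, pixelSizeUm = pixelSizeUm,
      thicknessUm = thicknessUm, nClusters = as.integer(nClusters),
      clusterRadiusRangeUm = clusterRadiusRangeUm, markerSpec = markerSpec,
      sigmaM = sigmaM, sigmaA = sigmaA, textureSigma = textureSigma,
      textureLengthPx = textureLengthPx, textureLengthZ = textureLengthZ,
      maxTransPx = maxTransPx,
      maxRotDeg = maxRotDeg, driftMode = driftMode,
      marginPx = as.integer(marginPx), seed = as.integer(seed))
}

# separable Gaussian smoothing of a 3D array (edge-renormalized), used to
# correlate the texture field over a few voxels in-plane and along z
.smooth3d <- function(arr, lengths) {
  d <- dim(arr)
  for (axis in 1:3) {
    L <- lengths[axis]
    if (L <= 0) next
    half <- max(1L, ceiling(3 * L))
    k <- exp(-((-half):half)^2 / (2 * L^2))
    k <- k / sum(k)
    arr <- .convolveAlong(arr, k, axis)
    ones <- .convolveAlong(array(1, d), k, axis)
    arr <- arr / ones
  }
  arr
}

.convolveAlong <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dm <- dim(x)
  m <- matrix(x, dm[1], dm[2] * dm[3])
  half <- (length(k) - 1L) / 2L
  out <- matrix(0, dm[1], ncol(m))
  for (j in seq_along(k)) {
    off <- j - 1L - half
    src <- seq_len(dm[1]) + off
    ok <- src >= 1L & src <= dm[1]
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, dm), order(perm))
}

#' Landmark m/z of a phantom specification
#' @param spec a \linkS4class{PhantomSpec}.
#' @return the m/z flagged as the morphology landmark.
#' @export
phantomLandmarkMz <- function(spec) spec@markerSpec$mz[spec@markerSpec$landmark][1]

# place nClusters non-overlapping spheres fully inside the spheroid;
# radii are drawn up front and placed largest-first (much less prone to
# jamming), with bounded full restarts before giving up
.placeClusters <- function(spec) {
  R <- spec@spheroidRadiusUm
  p <- spec@pixelSizeUm
  rRange <- spec@clusterRadiusRangeUm
  for (attempt in seq_len(25L)) {
    radiiWanted <- sort(runif(spec@nClusters, rRange[1], rRange[2]),
                        decreasing = TRUE)
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    failed <- FALSE
    for (r in radiiWanted) {
      placed <- FALSE
      rmax <- R - r - p
      if (rmax > 0) for (try in seq_len(200L)) {
        cand <- runif(3, -rmax, rmax)
        if (sqrt(sum(cand^2)) > rmax) next
        if (nrow(centers)) {
          dd <- sqrt(colSums((t(centers) - cand)^2))
          if (any(dd <= radii + r + sqrt(3) * p)) next
        }
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
        placed <- TRUE
        break
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) return(list(centers = centers, radii = radii))
  }
  stop("cluster placement failed after bounded retries; ",
       "use fewer or smaller clusters")
}

#' Generate a synthetic serial-section dataset with ground truth
#'
#' Builds the analytic 3D region model, voxelizes it (a voxel belongs to a
#' region if its center lies inside the analytic solid), draws per-voxel
#' intensities as \code{mean * exp(N(0, sigmaM)) + N(0, sigmaA)} truncated
#' at zero (background voxels carry only the weak matrix-adduct channels
#' plus additive noise), slices into sections, and finally applies an
#' independent random rigid perturbation to every section, recording it in
#' the truth.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{dataset} (a
#'   \linkS4class{SerialSectionDataset}) and \code{truth} (a
#'   \linkS4class{PhantomTruth}).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  R <- spec@spheroidRadiusUm
  p <- spec@pixelSizeUm
  t <- spec@thicknessUm
  ms <- spec@markerSpec[order(spec@markerSpec$mz), , drop = FALSE]
  axis <- FeatureAxis(ms$mz, tolerancePpm = 10)
  nF <- nrow(ms)

  half <- ceiling(R / p)
  HW <- 2L * half + 2L * spec@marginPx
  nPx <- HW * HW
  nz <- round(2 * R / t)
  zc <- -R + (seq_len(nz) - 0.5) * t
  ctr0 <- (HW - 1) / 2   # rotation/world center, 0-based pixel units

  organoid <- spec@mode == "cystic_organoid"
  if (!organoid) {
    cl <- .placeClusters(spec)
  } else {
    cl <- list(centers = matrix(numeric(0), 0, 3), radii = numeric(0))
  }
  lumenR <- R - spec@shellThicknessUm

  # analytic region model, evaluated at arbitrary world coordinates (um):
  # 0 background, 1 cancer/shell, 2 fibroblast/lumen; cid = cluster index
  regionAt <- function(xw, yw, zw) {
    d2 <- xw^2 + yw^2 + zw^2
    reg <- ifelse(d2 <= R^2, 1L, 0L)
    cid <- integer(length(xw))
    if (organoid) {
      reg[d2 <= lumenR^2] <- 2L
      cid[reg == 2L] <- 1L
    } else if (nrow(cl$centers)) {
      for (j in seq_len(nrow(cl$centers))) {
        hit <- (xw - cl$centers[j, 1])^2 + (yw - cl$centers[j, 2])^2 +
          (zw - cl$centers[j, 3])^2 <= cl$radii[j]^2
        reg[hit] <- 2L
        cid[hit] <- j
      }
    }
    list(region = reg, cid = cid)
  }

  # voxel-center grid (0-based pixel coordinates, column-major: row fastest)
  gy0 <- rep(seq_len(HW) - 1L, times = HW)
  gx0 <- rep(seq_len(HW) - 1L, each = HW)

  # ground-truth voxelization at the unperturbed raster (center rule)
  region <- array(0L, c(nz, HW, HW))
  clusterId <- array(0L, c(nz, HW, HW))
  for (k in seq_len(nz)) {
    ra <- regionAt((gx0 - ctr0) * p, (gy0 - ctr0) * p, zc[k])
    region[k, , ] <- matrix(ra$region, HW, HW)
    clusterId[k, , ] <- matrix(ra$cid, HW, HW)
  }

  # per-cluster voxel counts decide the size class the effects attach to
  if (!organoid && nrow(cl$centers)) {
    counts <- tabulate(clusterId[clusterId > 0], nbins = nrow(cl$centers))
    classes <- .sizeClassOf(counts)
  } else {
    counts <- integer(0); classes <- character(0)
  }

  # per-feature mean intensity by region and cluster class; the planted
  # V2-vs-V3 effect scales fibroblast means of V3-class clusters by
  # 2^(-lfc), so the log2 fold change of V2 over V3 objects equals lfc
  bgMeans <- if ("background" %in% names(ms)) ms$background else numeric(nF)
  meanLookup <- function(reg, cid, f) {
    mv <- rep(bgMeans[f], length(reg))
    mv[reg == 1L] <- ms$regionA[f]
    b <- rep(ms$regionB[f], length(reg))
    if (!organoid && length(classes) && ms$lfc[f] != 0) {
      v3 <- which(classes == "V3")
      if (length(v3)) b[cid %in% v3] <- ms$regionB[f] * 2^(-ms$lfc[f])
    }
    mv[reg == 2L] <- b[reg == 2L]
    mv
  }

  # smooth multiplicative texture: spatially correlated molecular
  # heterogeneity, continuous across adjacent sections (what makes real
  # serial sections registrable). Three latent Gaussian-correlated fields
  # with random per-feature loadings give every feature its own spatial
  # pattern, so the texture survives per-pixel RMS normalization. Sections
  # are rasterized by sampling this continuous model at the rigidly
  # perturbed subpixel positions (physical pixel integration), never by
  # resampling an already-rasterized image.
  K <- 3L
  useTexture <- spec@textureSigma > 0
  if (useTexture) {
    fields <- lapply(seq_len(K), function(k) {
      f <- .smooth3d(array(rnorm(nz * nPx), c(nz, HW, HW)),
                     c(spec@textureLengthZ, spec@textureLengthPx,
                       spec@textureLengthPx))
      (f - mean(f)) / sd(f)
    })
    Wload <- matrix(rnorm(nF * K), nF, K)
    Wload <- Wload / sqrt(rowSums(Wload^2))
  }
  sSub <- 2L   # subpixel integration factor

  transforms <- vector("list", nz)
  secs <- vector("list", nz)
  prev <- RigidTransform2D(0, 0, 0)
  for (k in seq_len(nz)) {
    jit <- RigidTransform2D(runif(1, -spec@maxRotDeg, spec@maxRotDeg),
                            runif(1, -spec@maxTransPx, spec@maxTransPx),
                            runif(1, -spec@maxTransPx, spec@maxTransPx))
    tr <- if (spec@driftMode) composeRigid(prev, jit) else jit
    prev <- tr
    transforms[[k]] <- tr

    # inverse-transformed pixel-center positions (0-based pixel units)
    th <- tr@thetaDeg * pi / 180
    qx <- gx0 - ctr0 - tr@txPx
    qy <- gy0 - ctr0 - tr@tyPx
    sx <- cos(th) * qx + sin(th) * qy
    sy <- -sin(th) * qx + cos(th) * qy
    ra <- regionAt(sx * p, sy * p, zc[k])

    meansMat <- vapply(seq_len(nF), function(f)
      meanLookup(ra$region, ra$cid, f), numeric(nPx))

    if (useTexture) {
      subSamples <- lapply(fields, function(fd)
        .cpp_sample_rigid_sub(fd[k, , ], tr@thetaDeg, tr@txPx, tr@tyPx,
                              sSub))
      texMean <- matrix(0, nPx, nF)
      for (sub in seq_len(sSub * sSub)) {
        lat <- vapply(subSamples, function(m) m[, sub], numeric(nPx))
        texMean <- texMean + exp(spec@textureSigma * lat %*% t(Wload))
      }
      texMean <- texMean / (sSub * sSub)
      meansMat <- meansMat * texMean
    }

    noise <- if (spec@sigmaM > 0)
      matrix(exp(rnorm(nPx * nF, 0, spec@sigmaM)), nPx, nF) else 1
    addn <- if (spec@sigmaA > 0)
      matrix(rnorm(nPx * nF, 0, spec@sigmaA), nPx, nF) else 0
    inten <- pmax(meansMat * noise + addn, 0)

    secs[[k]] <- SectionImage(array(inten, c(HW, HW, nF)),
                              matrix(ra$region > 0L, HW, HW),
                              pixelSizeUm = p, thicknessUm = t,
                              zIndex = k - 1L)
  }
  dataset <- SerialSectionDataset(secs, axis, sampleId = spec@mode)

  planted <- data.frame(mz = ms$mz, lfc = ms$lfc)
  clusterInfo <- if (!organoid && nrow(cl$centers))
    data.frame(cluster = seq_along(cl$radii),
               radius_um = cl$radii,
               x_um = cl$centers[, 1], y_um = cl$centers[, 2],
               z_um = cl$centers[, 3],
               voxel_count = counts, size_class = classes)
  else data.frame()

  truth <- new("PhantomTruth", transforms = transforms,
               regionVolume = region,
               regionNames = if (organoid)
                 setNames(c("background", "shell", "lumen"), 0:2)
               else setNames(c("background", "cancer", "fibroblast"), 0:2),
               objectCatalog = data.frame(), plantedEffects = planted,
               clusterInfo = clusterInfo, spec = spec)
  truth@objectCatalog <- catalogTruthObjects(truth)
  list(dataset = dataset, truth = truth)
}

#' Flood-fill 3D connected-component labeling (reference implementation)
#'
#' A deliberately simple breadth-first flood fill, independent of the
#' union-find labeling used by \code{\link{pickObjects}}, kept as the
#' cross-checking oracle. Components are numbered in decreasing voxel
#' count; ties broken by the smallest member linear index.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background).
#' @export
floodFillLabel <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- .neighborOffsets(connectivity)
  labels <- array(0L, d)
  comps <- list()
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    lab <- length(comps) + 1L
    queue <- start
    labels[start] <- lab
    members <- start
    while (length(queue)) {
      coords <- arrayInd(queue, d)
      queue <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(coords, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1, drop = TRUE] +
               d[1] * (nb[ok, 2, drop = TRUE] - 1L) +
               d[1] * d[2] * (nb[ok, 3, drop = TRUE] - 1L)
        lin <- unique(lin[mask[lin] & labels[lin] == 0L])
        if (length(lin)) {
          labels[lin] <- lab
          queue <- c(queue, lin)
          members <- c(members, lin)
        }
      }
    }
    comps[[lab]] <- members
  }
  if (!length(comps)) return(labels)
  sizes <- lengths(comps)
  mins <- vapply(comps, min, numeric(1))
  ord <- order(-sizes, mins)
  relabel <- integer(length(comps))
  relabel[ord] <- seq_along(comps)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  labels
}

#' Catalog the embedded objects of a phantom truth
#'
#' Connected components of the fibroblast/lumen region label, computed by
#' the independent flood fill, with voxel counts and size classes. This is
#' the reference against which \code{\link{pickObjects}} is validated.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param lower,upper size-class bounds in voxels (V1 < lower,
#'   lower <= V2 <= upper, V3 > upper).
#' @param connectivity 6, 18 or 26.
#' @return data.frame with object_id, voxel_count, size_class.
#' @export
catalogTruthObjects <- function(truth, lower = 10, upper = 100,
                                connectivity = 26) {
  lab <- floodFillLabel(truth@regionVolume == 2L, connectivity)
  k <- max(lab)
  if (k == 0L)
    return(data.frame(object_id = integer(), voxel_count = integer(),
                      size_class = character()))
  counts <- tabulate(lab[lab > 0L], nbins = k)
  data.frame(object_id = seq_len(k), voxel_count = counts,
             size_class = .sizeClassOf(counts, lower, upper))
}
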