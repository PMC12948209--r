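#' @useDynLib vox3dmsi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor median p.adjust pt qnorm rnorm runif sd setNames var
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# ---------------------------------------------------------------------------
# FeatureAxis
# ---------------------------------------------------------------------------

#' Feature axis: the common m/z grid of a dataset
#'
#' A \code{FeatureAxis} holds the ascending list of m/z values (Da) shared by
#' all sections of a dataset, together with the ppm tolerance used when
#' assigning centroid peaks to axis entries.
#'
#' @slot mz numeric, strictly ascending m/z values in Da, all positive.
#' @slot tolerancePpm single numeric, peak-matching tolerance in ppm.
#'
#' @examples
#' ax <- FeatureAxis(c(87.01, 778.51, 863.57), tolerancePpm = 10)
#' length(ax)
#' mzValues(ax)
#' @export
setClass("FeatureAxis",
  representation(mz = "numeric", tolerancePpm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tolerancePpm) != 1L || object@tolerancePpm <= 0)
      msg <- c(msg, "tolerancePpm must be a single positive number")
    if (length(object@mz) < 1L)
      msg <- c(msg, "axis must contain at least one m/z value")
    if (any(object@mz <= 0))
      msg <- c(msg, "all m/z values must be positive")
    if (is.unsorted(object@mz, strictly = TRUE))
      msg <- c(msg, "m/z values must be strictly ascending")
    if (length(object@mz) > 1L) {
      rel <- diff(object@mz) / object@mz[-length(object@mz)] * 1e6
      if (any(rel <= object@tolerancePpm))
        msg <- c(msg, "adjacent m/z values lie within the ppm tolerance of each other")
    }
    if (length(msg)) msg else TRUE
  })

#' @param mz numeric vector of m/z values (Da), strictly ascending.
#' @param tolerancePpm matching tolerance in ppm (default 10).
#' @rdname FeatureAxis-class
#' @export
FeatureAxis <- function(mz, tolerancePpm = 10) {
  new("FeatureAxis", mz = as.numeric(mz), tolerancePpm = as.numeric(tolerancePpm))
}

# ---------------------------------------------------------------------------
# SectionImage
# ---------------------------------------------------------------------------

#' One tissue section: pixel grid with per-pixel feature intensities
#'
#' Intensities are stored as a (height, width, feature) array; row/column
#' indices are 0-based externally via imzML I/O but plain R 1-based arrays
#' internally. The foreground mask flags on-tissue pixels; background pixels
#' carry zero intensity.
#'
#' @slot intensities 3D numeric array (height, width, n features), >= 0.
#' @slot mask logical matrix (height, width), TRUE on tissue.
#' @slot pixelSizeUm in-plane raster size in micrometres.
#' @slot thicknessUm section thickness in micrometres.
#' @slot zIndex integer position in cutting order (0-based).
#'
#' @export
setClass("SectionImage",
  representation(intensities = "array", mask = "matrix",
                 pixelSizeUm = "numeric", thicknessUm = "numeric",
                 zIndex = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@intensities)
    if (length(d) != 3L)
      msg <- c(msg, "intensities must be a (height, width, feature) array")
    else if (!identical(dim(object@mask), d[1:2]))
      msg <- c(msg, "mask dimensions must match the intensity grid")
    if (any(object@intensities < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (object@pixelSizeUm <= 0 || object@thicknessUm <= 0)
      msg <- c(msg, "pixelSizeUm and thicknessUm must be positive")
    if (length(msg)) msg else TRUE
  })

#' @param intensities 3D array (height, width, n features).
#' @param mask logical matrix; defaults to pixels with any signal.
#' @param pixelSizeUm,thicknessUm raster size and section thickness (um).
#' @param zIndex integer z order (0-based).
#' @rdname SectionImage-class
#' @export
SectionImage <- function(intensities, mask = NULL, pixelSizeUm = 20,
                         thicknessUm = 20, zIndex = 0L) {
  if (is.null(mask))
    mask <- apply(intensities, c(1, 2), function(v) any(v > 0))
  new("SectionImage", intensities = intensities, mask = mask,
      pixelSizeUm = as.numeric(pixelSizeUm),
      thicknessUm = as.numeric(thicknessUm), zIndex = as.integer(zIndex))
}

# ---------------------------------------------------------------------------
# SerialSectionDataset
# ---------------------------------------------------------------------------

#' A z-ordered stack of serial sections on a common feature axis
#'
#' @slot sections list of \linkS4class{SectionImage}, ordered by zIndex.
#' @slot featureAxis the shared \linkS4class{FeatureAxis}.
#' @slot sampleId sample identifier.
#'
#' @export
setClass("SerialSectionDataset",
  representation(sections = "list", featureAxis = "FeatureAxis",
                 sampleId = "character"),
  validity = function(object) {
    msg <- character()
    secs <- object@sections
    if (length(secs) == 0L)
      return("dataset must contain at least one section")
    if (!all(vapply(secs, is, logical(1), "SectionImage")))
      return("all sections must be SectionImage objects")
    z <- vapply(secs, function(s) s@zIndex, integer(1))
    if (!identical(z, seq_along(secs) - 1L))
      msg <- c(msg, "zIndex values must be consecutive from 0 in list order")
    nf <- vapply(secs, function(s) dim(s@intensities)[3], integer(1))
    if (any(nf != length(object@featureAxis@mz)))
      msg <- c(msg, "every section must carry one channel per axis feature")
    px <- vapply(secs, function(s) s@pixelSizeUm, numeric(1))
    th <- vapply(secs, function(s) s@thicknessUm, numeric(1))
    if (length(unique(px)) != 1L || length(unique(th)) != 1L)
      msg <- c(msg, "all sections must share pixelSizeUm and thicknessUm")
    if (length(msg)) msg else TRUE
  })

#' @param sections list of SectionImage, in cutting order.
#' @param featureAxis shared FeatureAxis.
#' @param sampleId sample identifier string.
#' @rdname SerialSectionDataset-class
#' @export
SerialSectionDataset <- function(sections, featureAxis, sampleId = "sample") {
  new("SerialSectionDataset", sections = sections, featureAxis = featureAxis,
      sampleId = sampleId)
}

# ---------------------------------------------------------------------------
# RigidTransform2D
# ---------------------------------------------------------------------------

#' In-plane rigid transform: rotation about the image center, then translation
#'
#' The transform maps moving-image coordinates p (x right, y down, pixels)
#' to fixed-image coordinates via \code{R(theta) (p - c) + c + t}, where c is
#' the image center. Positive theta rotates counterclockwise in the (x, y)
#' convention used here. Composition and inversion are exact.
#'
#' @slot thetaDeg rotation in degrees.
#' @slot txPx,tyPx translation in pixels, applied after rotation.
#'
#' @examples
#' t1 <- RigidTransform2D(10, 2, -1)
#' composeRigid(t1, invertRigid(t1))  # identity
#' @export
setClass("RigidTransform2D",
  representation(thetaDeg = "numeric", txPx = "numeric", tyPx = "numeric"),
  validity = function(object) {
    if (any(!is.finite(c(object@thetaDeg, object@txPx, object@tyPx))))
      "transform parameters must be finite" else TRUE
  })

#' @param thetaDeg rotation (degrees, counterclockwise).
#' @param txPx,tyPx translation (pixels).
#' @rdname RigidTransform2D-class
#' @export
RigidTransform2D <- function(thetaDeg = 0, txPx = 0, tyPx = 0) {
  new("RigidTransform2D", thetaDeg = as.numeric(thetaDeg),
      txPx = as.numeric(txPx), tyPx = as.numeric(tyPx))
}

# ---------------------------------------------------------------------------
# FeatureVolume
# ---------------------------------------------------------------------------

#' Registered multichannel voxel volume
#'
#' @slot data 4D numeric array (z, y, x, feature).
#' @slot mask logical 3D array (z, y, x), TRUE on tissue voxels.
#' @slot voxelUm numeric(3): voxel edge lengths (dz, dy, dx) in um.
#' @slot featureAxis the \linkS4class{FeatureAxis} of the channel dimension.
#' @slot transformsApplied list of per-slice \linkS4class{RigidTransform2D}.
#'
#' @export
setClass("FeatureVolume",
  representation(data = "array", mask = "array", voxelUm = "numeric",
                 featureAxis = "FeatureAxis", transformsApplied = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 4L)
      return("data must be a 4D (z, y, x, feature) array")
    if (!identical(dim(object@mask), d[1:3]))
      msg <- c(msg, "mask must match the spatial dimensions of data")
    if (length(object@voxelUm) != 3L || any(object@voxelUm <= 0))
      msg <- c(msg, "voxelUm must be three positive edge lengths (dz, dy, dx)")
    if (d[4] != length(object@featureAxis@mz))
      msg <- c(msg, "channel count must equal the feature axis length")
    if (any(object@data < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (length(object@transformsApplied) &&
        length(object@transformsApplied) != d[1])
      msg <- c(msg, "one transform per slice required when transforms are recorded")
    if (length(msg)) msg else TRUE
  })

#' @param data 4D array (z, y, x, feature).
#' @param mask logical 3D array; defaults to voxels with any signal.
#' @param voxelUm numeric(3) voxel edges (dz, dy, dx) in um.
#' @param featureAxis FeatureAxis for the channel dimension.
#' @param transformsApplied optional list of per-slice transforms.
#' @rdname FeatureVolume-class
#' @export
FeatureVolume <- function(data, voxelUm, featureAxis, mask = NULL,
                          transformsApplied = list()) {
  if (is.null(mask)) {
    mask <- apply(data, 1:3, function(v) any(v > 0))
  }
  new("FeatureVolume", data = data, mask = mask,
      voxelUm = as.numeric(voxelUm), featureAxis = featureAxis,
      transformsApplied = transformsApplied)
}

# ---------------------------------------------------------------------------
# LabeledObjects
# ---------------------------------------------------------------------------

#' Labeled 3D voxel objects
#'
#' Connected components of a voxel mask, labeled 1..K in decreasing voxel
#' count. \code{objectStats} carries one row per object (voxel_count and,
#' once computed, volume_um3, surface_area_um2, size_class, centroid).
#'
#' @slot labels 3D integer array, 0 = background.
#' @slot voxelUm numeric(3) voxel edge lengths (dz, dy, dx) in um.
#' @slot stats data.frame of per-object properties.
#'
#' @export
setClass("LabeledObjects",
  representation(labels = "array", voxelUm = "numeric", stats = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      return("labels must be a 3D array")
    k <- max(object@labels)
    if (k > 0 && !setequal(unique(object@labels[object@labels > 0]), seq_len(k)))
      msg <- c(msg, "labels must be consecutive positive integers")
    if (nrow(object@stats) != k)
      msg <- c(msg, "stats must contain one row per object")
    if (length(object@voxelUm) != 3L || any(object@voxelUm <= 0))
      msg <- c(msg, "voxelUm must be three positive edge lengths")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# SegmentationTree
# ---------------------------------------------------------------------------

#' Bisecting k-means segmentation result
#'
#' @slot membership integer leaf id per member (parallel to memberIndex).
#' @slot memberIndex linear index of each member into the source geometry.
#' @slot sourceDim dimensions of the source image/volume.
#' @slot centroids matrix (leaf x feature) of leaf centroid profiles.
#' @slot nodes data.frame describing the binary split tree.
#' @slot seed RNG seed used for the k-means restarts.
#'
#' @export
setClass("SegmentationTree",
  representation(membership = "integer", memberIndex = "integer",
                 sourceDim = "integer", centroids = "matrix",
                 nodes = "data.frame", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@membership) != length(object@memberIndex))
      msg <- c(msg, "membership and memberIndex must be parallel")
    k <- nrow(object@centroids)
    if (length(object@membership) &&
        !all(object@membership %in% seq_len(k)))
      msg <- c(msg, "every member must belong to exactly one leaf")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# PhantomSpec / PhantomTruth
# ---------------------------------------------------------------------------

#' Specification of a synthetic serial-section phantom
#'
#' Defaults emulate a ~600 um diameter biculture spheroid sectioned at 20 um
#' with a 20 um raster: embedded fibroblast clusters inside a cancer-cell
#' sphere, a landmark lipid channel high across all tissue, per-voxel
#' multiplicative lognormal noise plus a small additive detector noise, and
#' an independent random rigid perturbation per section. Organoid mode swaps
#' the geometry for a hollow shell with a lumen enriched in two small-mass
#' channels (structurally mirroring lumenal nucleotide accumulation).
#'
#' @slot mode "biculture_spheroid" or "cystic_organoid".
#' @slot spheroidRadiusUm outer radius (um).
#' @slot shellThicknessUm organoid shell thickness (um; organoid mode only).
#' @slot pixelSizeUm,thicknessUm raster and section thickness (um).
#' @slot nClusters number of embedded fibroblast clusters (spheroid mode).
#' @slot clusterRadiusRangeUm min/max cluster radius (um).
#' @slot markerSpec data.frame: mz, cancer, fibroblast mean intensities and
#'   planted lfc_v3 log2 fold change applied to fibroblast clusters of size
#'   class V3 (spheroid mode) or lumen/shell means with lfc planted between
#'   lumen and shell (organoid mode).
#' @slot sigmaM multiplicative lognormal noise sigma (log scale).
#' @slot sigmaA additive Gaussian noise sigma (a.u.).
#' @slot textureSigma log-sd of the smooth multiplicative texture field
#'   modeling spatially correlated molecular heterogeneity shared between
#'   adjacent sections (what makes real serial sections registrable).
#' @slot textureLengthPx,textureLengthZ Gaussian correlation lengths of the
#'   texture field in-plane (pixels) and along z (sections).
#' @slot maxTransPx,maxRotDeg per-section perturbation bounds.
#' @slot driftMode logical; cumulative drift instead of independent jitter.
#' @slot marginPx background margin around the spheroid footprint (px).
#' @slot seed RNG seed; fixed seed gives bit-identical output.
#'
#' @export
setClass("PhantomSpec",
  representation(mode = "character", spheroidRadiusUm = "numeric",
                 shellThicknessUm = "numeric",
                 pixelSizeUm = "numeric", thicknessUm = "numeric",
                 nClusters = "integer", clusterRadiusRangeUm = "numeric",
                 markerSpec = "data.frame", sigmaM = "numeric",
                 sigmaA = "numeric", textureSigma = "numeric",
                 textureLengthPx = "numeric", textureLengthZ = "numeric",
                 maxTransPx = "numeric",
                 maxRotDeg = "numeric", driftMode = "logical",
                 marginPx = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("biculture_spheroid", "cystic_organoid"))
      msg <- c(msg, "mode must be 'biculture_spheroid' or 'cystic_organoid'")
    if (object@spheroidRadiusUm <= 0 || object@pixelSizeUm <= 0 ||
        object@thicknessUm <= 0)
      msg <- c(msg, "radii and voxel sizes must be positive")
    if (object@sigmaM < 0 || object@sigmaA < 0 || object@textureSigma < 0)
      msg <- c(msg, "noise sigmas must be non-negative")
    if (length(object@clusterRadiusRangeUm) != 2L ||
        any(object@clusterRadiusRangeUm <= 0) ||
        diff(object@clusterRadiusRangeUm) < 0)
      msg <- c(msg, "clusterRadiusRangeUm must be an ascending positive pair")
    need <- c("mz", "regionA", "regionB", "lfc")
    if (!all(need %in% names(object@markerSpec)))
      msg <- c(msg, "markerSpec must have columns mz, regionA, regionB, lfc")
    if (length(msg)) msg else TRUE
  })

#' Ground truth accompanying a generated phantom
#'
#' @slot transforms list of per-section \linkS4class{RigidTransform2D}
#'   actually applied (perturbations).
#' @slot regionVolume 3D integer array (z, y, x): 0 background, 1
#'   cancer/shell, 2 fibroblast/lumen, in the unperturbed frame.
#' @slot regionNames names of the integer region codes.
#' @slot objectCatalog data.frame of embedded objects (object_id,
#'   voxel_count, size_class) from the independent flood-fill.
#' @slot plantedEffects data.frame (mz, lfc) of true log2 fold changes
#'   between the compared groups.
#' @slot clusterInfo data.frame of embedded cluster geometry and class.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#'
#' @export
setClass("PhantomTruth",
  representation(transforms = "list", regionVolume = "array",
                 regionNames = "character", objectCatalog = "data.frame",
                 plantedEffects = "data.frame", clusterInfo = "data.frame",
                 spec = "PhantomSpec"))
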