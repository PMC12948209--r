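# Voxel-object picking: 3D connected components of a region mask, size
# classification (V1/V2/V3), per-object geometry (volume, surface area on
# anisotropic voxels), voxelated reference spheres, and per-object mean
# intensity profiles that serve as the statistical units downstream.

#' Pick 3D objects: connected components of a voxel mask
#'
#' Labels the connected components of a 3D mask under face (6), face+edge
#' (18) or full (26) connectivity, numbering objects 1..K in decreasing
#' voxel count (ties: the object containing the smallest linear voxel
#' index first).
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26, the most permissive).
#' @param voxelUm voxel edge lengths (dz, dy, dx) in um.
#' @return a \linkS4class{LabeledObjects}; an empty mask yields zero
#'   objects with a warning.
#' @export
pickObjects <- function(mask, connectivity = 26, voxelUm = c(20, 20, 20)) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  if (!any(mask)) {
    warning("empty mask: no objects to pick")
    return(new("LabeledObjects", labels = array(0L, d),
               voxelUm = as.numeric(voxelUm),
               stats = data.frame(object_id = integer(),
                                  voxel_count = integer())))
  }
  raw <- .cpp_label3d(as.logical(mask), as.integer(d),
                      as.integer(connectivity))
  labs <- sort(unique(raw[raw > 0L]))
  counts <- tabulate(match(raw[raw > 0L], labs))
  mins <- vapply(labs, function(l) min(which(raw == l)), numeric(1))
  ord <- order(-counts, mins)
  remap <- integer(max(labs))
  remap[labs[ord]] <- seq_along(labs)
  out <- array(0L, d)
  out[raw > 0L] <- remap[raw[raw > 0L]]
  counts <- counts[ord]
  cent <- t(vapply(seq_along(labs), function(l) {
    colMeans(arrayInd(which(out == l), d))
  }, numeric(3)))
  new("LabeledObjects", labels = out, voxelUm = as.numeric(voxelUm),
      stats = data.frame(object_id = seq_along(labs),
                         voxel_count = counts,
                         centroid_z = cent[, 1], centroid_y = cent[, 2],
                         centroid_x = cent[, 3]))
}

#' Classify objects into V1/V2/V3 size classes
#'
#' V1: voxel_count < lower; V2: lower <= voxel_count <= upper; V3:
#' voxel_count > upper. The default bounds of 10 and 100 voxels follow the
#' convention for fibroblast 3D objects; V1 objects are retained but
#' typically treated as below the effective spatial resolution.
#'
#' @param objects a \linkS4class{LabeledObjects}.
#' @param lower,upper class bounds in voxels (lower < upper).
#' @return the \linkS4class{LabeledObjects} with a size_class column added;
#'   class counts are in attribute \code{"classCounts"}.
#' @export
classifySize <- function(objects, lower = 10, upper = 100) {
  st <- objects@stats
  st$size_class <- .sizeClassOf(st$voxel_count, lower, upper)
  objects@stats <- st
  attr(objects, "classCounts") <-
    table(factor(st$size_class, levels = c("V1", "V2", "V3")))
  objects
}

#' Histogram table of object sizes
#'
#' @param objects a \linkS4class{LabeledObjects}.
#' @param breaks histogram breaks in voxels (right-open bins, last bin
#'   catches everything larger).
#' @return data.frame with bin bounds and object counts; bin totals sum to
#'   the object count.
#' @export
sizeHistogram <- function(objects, breaks = c(1, 10, 100, Inf)) {
  counts <- objects@stats$voxel_count
  bins <- cut(counts, breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  data.frame(bin = levels(bins), n_objects = as.integer(table(bins)))
}

#' Per-object volume and surface area on anisotropic voxels
#'
#' Volume is voxel_count times the voxel volume. Surface area counts
#' object-voxel faces adjacent to non-object voxels (or the array border):
#' faces normal to z have area dy*dx; faces normal to y, dz*dx; faces
#' normal to x, dz*dy.
#'
#' @param objects a \linkS4class{LabeledObjects}.
#' @param voxelUm voxel edges (dz, dy, dx) in um; defaults to the object's.
#' @return the \linkS4class{LabeledObjects} with volume_um3 and
#'   surface_area_um2 columns added.
#' @export
objectGeometry <- function(objects, voxelUm = NULL) {
  if (is.null(voxelUm)) voxelUm <- objects@voxelUm
  lab <- objects@labels
  d <- dim(lab)
  k <- nrow(objects@stats)
  if (k == 0L) {
    objects@stats$volume_um3 <- numeric(0)
    objects@stats$surface_area_um2 <- numeric(0)
    return(objects)
  }
  faceArea <- c(voxelUm[2] * voxelUm[3],   # normal to z
                voxelUm[1] * voxelUm[3],   # normal to y
                voxelUm[1] * voxelUm[2])   # normal to x
  surf <- numeric(k)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      shifted <- array(0L, d)
      n <- d[axis]
      idxFrom <- lapply(d, seq_len)
      idxTo <- lapply(d, seq_len)
      if (dir == 1L) { idxFrom[[axis]] <- 1:(n - 1); idxTo[[axis]] <- 2:n }
      else { idxFrom[[axis]] <- 2:n; idxTo[[axis]] <- 1:(n - 1) }
      shifted <- array(0L, d)
      shifted[idxTo[[1]], idxTo[[2]], idxTo[[3]]] <-
        lab[idxFrom[[1]], idxFrom[[2]], idxFrom[[3]]]
      exposed <- lab > 0L & shifted != lab
      if (any(exposed))
        surf <- surf + faceArea[axis] *
          tabulate(lab[exposed], nbins = k)
    }
  }
  st <- objects@stats
  st$volume_um3 <- st$voxel_count * prod(voxelUm)
  st$surface_area_um2 <- surf
  objects@stats <- st
  objects@voxelUm <- as.numeric(voxelUm)
  objects
}

#' Voxelated reference sphere
#'
#' Builds the voxelization of an analytic sphere: voxels whose centers lie
#' within \code{radiusUm} of the sphere center (placed on a voxel center)
#' form a single object. Used to validate shape fidelity: as the radius
#' grows, the voxelated volume and surface-to-volume ratio converge to the
#' analytic sphere's.
#'
#' @param radiusUm sphere radius in um (>= the largest voxel edge).
#' @param voxelUm voxel edges (dz, dy, dx) in um.
#' @return a single-object \linkS4class{LabeledObjects} with geometry
#'   computed; the analytic volume and surface are in attribute
#'   \code{"analytic"}.
#' @export
voxelatedSphere <- function(radiusUm, voxelUm = c(20, 20, 20)) {
  voxelUm <- rep(as.numeric(voxelUm), length.out = 3)
  if (radiusUm < max(voxelUm))
    stop("degenerate sphere: radius ", radiusUm,
         " um is below the voxel size")
  n <- 2L * floor(radiusUm / voxelUm) + 3L
  ax <- lapply(1:3, function(i)
    (seq_len(n[i]) - (n[i] + 1) / 2) * voxelUm[i])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  mask <- d2 <= radiusUm^2
  obj <- pickObjects(mask, connectivity = 26, voxelUm = voxelUm)
  obj <- objectGeometry(obj)
  attr(obj, "analytic") <- c(volume_um3 = 4 / 3 * pi * radiusUm^3,
                             surface_um2 = 4 * pi * radiusUm^2)
  obj
}

#' Mean intensity profiles of labeled objects
#'
#' The per-feature arithmetic mean intensity over each object's member
#' voxels: the statistical unit for voxel-object differential analysis
#' (objects, never voxels, are the replicates).
#'
#' @param objects a \linkS4class{LabeledObjects}.
#' @param volume a \linkS4class{FeatureVolume} aligned with the labels.
#' @return matrix (objects x features) of mean intensities; rownames are
#'   object ids, colnames the axis m/z values.
#' @export
objectProfiles <- function(objects, volume) {
  lab <- objects@labels
  if (!identical(dim(lab), dim(volume@data)[1:3]))
    stop("label volume and feature volume shapes differ")
  k <- nrow(objects@stats)
  nF <- dim(volume@data)[4]
  sel <- which(lab > 0L)
  if (!length(sel) || k == 0L)
    return(matrix(numeric(0), 0, nF,
                  dimnames = list(NULL, volume@featureAxis@mz)))
  labs <- lab[sel]
  flat <- matrix(volume@data, prod(dim(lab)), nF)
  sums <- rowsum(flat[sel, , drop = FALSE], labs)
  counts <- tabulate(labs, nbins = k)
  prof <- sums / counts[as.integer(rownames(sums))]
  rownames(prof) <- rownames(sums)
  colnames(prof) <- volume@featureAxis@mz
  prof[order(as.integer(rownames(prof))), , drop = FALSE]
}
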