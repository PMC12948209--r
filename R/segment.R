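# Feature selection and spatial segmentation: intensity-threshold sliding
# window feature lists, ROC (AUC) discriminating features, weak de-noising,
# and bisecting k-means with correlation distance.

#' Select features by mean-spectrum intensity threshold (sliding window)
#'
#' Computes the mean spectrum over all foreground pixels of the dataset and
#' keeps features that are local maxima of the mean spectrum within a
#' sliding m/z window and whose mean intensity reaches the threshold.
#' Raising the threshold never adds features.
#'
#' @param dataset a \linkS4class{SerialSectionDataset}.
#' @param intensityThreshold minimum mean intensity (a.u.).
#' @param windowDa full width of the sliding m/z window (Da).
#' @return a \linkS4class{FeatureAxis} of the retained features, with the
#'   mean spectrum in attribute \code{"meanSpectrum"}.
#' @export
thresholdFeatureList <- function(dataset, intensityThreshold,
                                 windowDa = 0.1) {
  axis <- dataset@featureAxis
  mz <- axis@mz
  tot <- numeric(length(mz)); n <- 0
  for (s in dataset@sections) {
    d <- dim(s@intensities)
    m <- matrix(s@intensities, d[1] * d[2], d[3])
    fg <- which(s@mask)
    if (!length(fg)) next
    tot <- tot + colSums(m[fg, , drop = FALSE])
    n <- n + length(fg)
  }
  if (n == 0) stop("dataset has no foreground pixels")
  meanSpec <- tot / n
  keep <- logical(length(mz))
  half <- windowDa / 2
  for (i in seq_along(mz)) {
    w <- which(abs(mz - mz[i]) <= half)
    isMax <- meanSpec[i] > max(c(-Inf, meanSpec[setdiff(w, i)])) ||
      (meanSpec[i] == max(meanSpec[w]) && i == w[which.max(meanSpec[w])])
    keep[i] <- isMax && meanSpec[i] >= intensityThreshold
  }
  if (!any(keep))
    stop("no feature passes the intensity threshold of ",
         intensityThreshold, " a.u.; lower the threshold")
  out <- FeatureAxis(mz[keep], axis@tolerancePpm)
  attr(out, "meanSpectrum") <- data.frame(mz = mz, mean_intensity = meanSpec,
                                          selected = keep)
  out
}

#' Midrank AUC of one feature separating two groups
#'
#' Area under the ROC curve for classifying group A versus group B by
#' intensity, computed from midranks (equivalent to counting concordant
#' pairs with half credit for ties). A constant feature scores 0.5.
#'
#' @param a,b intensity values of the two groups.
#' @return AUC in [0, 1] (probability a random A exceeds a random B).
#' @export
rocAuc <- function(a, b) {
  nA <- length(a); nB <- length(b)
  if (nA == 0 || nB == 0) return(NA_real_)
  r <- rank(c(a, b))
  (sum(r[seq_len(nA)]) - nA * (nA + 1) / 2) / (nA * nB)
}

#' Select discriminating features by ROC AUC
#'
#' Per feature, the midrank AUC for separating the two pixel groups;
#' features with \code{max(AUC, 1 - AUC) >= aucThreshold} are retained, the
#' best \code{topN} of them when given.
#'
#' @param intensities matrix (pixels x features) of intensities.
#' @param labels factor or vector with exactly two levels, one per pixel.
#' @param axis the \linkS4class{FeatureAxis} describing the columns.
#' @param aucThreshold minimum discrimination score (default 0.65).
#' @param topN optionally keep only the topN features by score.
#' @return a \linkS4class{FeatureAxis} of the retained features; the full
#'   score table is in attribute \code{"scores"}.
#' @export
rocDiscriminatingFeatures <- function(intensities, labels, axis,
                                      aucThreshold = 0.65, topN = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must define exactly two groups")
  ga <- labels == levels(labels)[1]
  if (sum(ga) < 10L || sum(!ga) < 10L)
    stop("each group needs at least 10 pixels")
  auc <- apply(intensities, 2, function(v) rocAuc(v[ga], v[!ga]))
  score <- pmax(auc, 1 - auc)
  sel <- which(score >= aucThreshold)
  if (!is.null(topN) && length(sel) > topN)
    sel <- sel[order(score[sel], decreasing = TRUE)[seq_len(topN)]]
  sel <- sort(sel)
  if (!length(sel))
    stop("no feature reaches an AUC score of ", aucThreshold)
  out <- FeatureAxis(axis@mz[sel], axis@tolerancePpm)
  attr(out, "scores") <- data.frame(mz = axis@mz, auc = auc, score = score,
                                    selected = seq_along(axis@mz) %in% sel)
  out
}

#' Weak de-noising of an ion image (3x3 median filter)
#'
#' Median filtering over the 3x3 neighborhood restricted to the image
#' (reduced neighborhood at the edges) and, when a mask is supplied, to
#' foreground pixels; background pixels pass through unchanged.
#'
#' @param img numeric matrix.
#' @param mask optional logical matrix of foreground pixels.
#' @return filtered matrix.
#' @export
weakDenoise <- function(img, mask = NULL) {
  h <- nrow(img); w <- ncol(img)
  use <- if (is.null(mask)) matrix(TRUE, h, w) else mask
  padded <- matrix(NA_real_, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- ifelse(use, img, NA_real_)
  stack <- vapply(seq_len(9), function(k) {
    dr <- (k - 1) %% 3; dc <- (k - 1) %/% 3
    as.vector(padded[(1 + dr):(h + dr), (1 + dc):(w + dc)])
  }, numeric(h * w))
  med <- apply(stack, 1, median, na.rm = TRUE)
  out <- matrix(med, h, w)
  out[is.na(out)] <- 0
  if (!is.null(mask)) out[!mask] <- img[!mask]
  out
}

# correlation distance 1 - r between rows of x and a centroid vector;
# zero-variance rows get NA
.corDist <- function(x, centroid) {
  xc <- x - rowMeans(x)
  cc <- centroid - mean(centroid)
  denom <- sqrt(rowSums(xc^2) * sum(cc^2))
  d <- 1 - (xc %*% cc)[, 1] / denom
  d[denom == 0] <- NA_real_
  d
}

# one 2-means split with correlation distance; returns membership (1/2)
.split2means <- function(x, nInit = 10, maxIter = 50) {
  n <- nrow(x)
  best <- NULL; bestCost <- Inf
  for (init in seq_len(nInit)) {
    seeds <- sample.int(n, 2)
    cent <- x[seeds, , drop = FALSE]
    member <- integer(n)
    for (iter in seq_len(maxIter)) {
      d1 <- .corDist(x, cent[1, ]); d2 <- .corDist(x, cent[2, ])
      d1[is.na(d1)] <- 1; d2[is.na(d2)] <- 1
      newMember <- ifelse(d1 <= d2, 1L, 2L)
      if (identical(newMember, member)) break
      member <- newMember
      if (!any(member == 1L) || !any(member == 2L)) break
      cent <- rbind(colMeans(x[member == 1L, , drop = FALSE]),
                    colMeans(x[member == 2L, , drop = FALSE]))
    }
    if (length(unique(member)) < 2L) next
    d1 <- .corDist(x, cent[1, ]); d2 <- .corDist(x, cent[2, ])
    d1[is.na(d1)] <- 1; d2[is.na(d2)] <- 1
    cost <- sum(ifelse(member == 1L, d1, d2))
    if (cost < bestCost) { bestCost <- cost; best <- member }
  }
  best
}

#' Bisecting k-means segmentation with correlation distance
#'
#' Starting from one cluster holding every member, repeatedly splits the
#' leaf with the largest within-cluster summed correlation distance
#' (1 - Pearson correlation to the leaf centroid) into two by k-means with
#' \code{nInit} random restarts, until \code{nLeaves} leaves exist.
#' Deterministic for a fixed seed. Members are expected RMS-normalized;
#' correlation distance makes the result invariant to positive rescaling of
#' any member. Zero-variance members are attached to the nearest leaf at
#' the end and listed in the \code{"flatMembers"} attribute.
#'
#' @param members numeric matrix (members x features).
#' @param nLeaves number of leaves to produce (>= 1).
#' @param seed RNG seed controlling the restarts.
#' @param nInit random restarts per split.
#' @param memberIndex optional linear indices of the members in their
#'   source geometry (stored for \code{\link{assignRegions}}).
#' @param sourceDim optional dim of the source image/volume.
#' @return a \linkS4class{SegmentationTree}.
#' @export
bisectingKmeans <- function(members, nLeaves, seed = 1L, nInit = 10,
                            memberIndex = seq_len(nrow(members)),
                            sourceDim = c(nrow(members), 1L, 1L)) {
  stopifnot(is.matrix(members), nLeaves >= 1)
  n <- nrow(members)
  if (nLeaves > 1 && nrow(unique(members)) < nLeaves)
    stop("fewer distinct members than requested leaves")
  variable <- apply(members, 1, function(v) var(v) > 0)
  flat <- which(!variable)
  # clustering operates on correlation-standardized rows (centered, unit
  # norm) so that membership is exactly invariant to positive rescaling of
  # any member; reported centroids stay on the original scale
  xs <- members - rowMeans(members)
  rsd <- sqrt(rowSums(xs^2))
  xs[variable, ] <- xs[variable, , drop = FALSE] / rsd[variable]

  .withSeed(seed, {
    membership <- rep(1L, n)
    membership[flat] <- NA_integer_
    nodes <- data.frame(node = 1L, parent = 0L, leaf = TRUE,
                        size = sum(variable), within = NA_real_)
    leafWithin <- function(leaf) {
      idx <- which(membership == leaf)
      if (length(idx) < 2L) return(0)
      cent <- colMeans(xs[idx, , drop = FALSE])
      d <- .corDist(xs[idx, , drop = FALSE], cent)
      sum(d, na.rm = TRUE)
    }
    within <- c("1" = leafWithin(1L))
    while (length(within) < nLeaves) {
      splitLeaf <- as.integer(names(within))[which.max(within)]
      idx <- which(membership == splitLeaf)
      if (length(idx) < 2L)
        stop("cannot reach ", nLeaves, " leaves: leaves exhausted")
      part <- .split2means(xs[idx, , drop = FALSE], nInit = nInit)
      if (is.null(part))
        stop("cannot reach ", nLeaves, " leaves: a leaf refused to split")
      newIds <- max(as.integer(names(within))) + 1:2
      membership[idx[part == 1L]] <- newIds[1]
      membership[idx[part == 2L]] <- newIds[2]
      nodes$leaf[nodes$node == splitLeaf] <- FALSE
      nodes <- rbind(nodes,
        data.frame(node = newIds, parent = splitLeaf, leaf = TRUE,
                   size = c(sum(part == 1L), sum(part == 2L)),
                   within = NA_real_))
      within <- within[names(within) != as.character(splitLeaf)]
      within[as.character(newIds)] <- c(leafWithin(newIds[1]),
                                        leafWithin(newIds[2]))
    }
    # renumber leaves 1..nLeaves in node order
    leafIds <- sort(as.integer(names(within)))
    remap <- setNames(seq_along(leafIds), leafIds)
    membership <- as.integer(remap[as.character(membership)])
    centroids <- t(vapply(seq_along(leafIds), function(l)
      colMeans(members[which(membership == l), , drop = FALSE]),
      numeric(ncol(members))))
    # attach zero-variance members to the nearest leaf (correlation distance
    # is undefined for them, so nearest is judged in Euclidean terms)
    if (length(flat)) {
      for (i in flat) {
        d <- rowSums(sweep(centroids, 2, members[i, ])^2)
        membership[i] <- which.min(d)
      }
    }
    nodes$within[nodes$leaf] <- within[as.character(sort(as.integer(names(within))))]
    tree <- new("SegmentationTree", membership = membership,
                memberIndex = as.integer(memberIndex),
                sourceDim = as.integer(sourceDim),
                centroids = centroids, nodes = nodes,
                seed = as.integer(seed))
    attr(tree, "flatMembers") <- flat
    tree
  })
}

#' Map segmentation leaves to named regions
#'
#' Produces an integer label image/volume in the source geometry from a
#' user-supplied leaf-to-region mapping. Mapping several leaves to one
#' region merges them; every leaf must be covered.
#'
#' @param tree a \linkS4class{SegmentationTree}.
#' @param mapping named character vector or list: names are leaf ids,
#'   values are region names.
#' @return integer array shaped like the source, with region names in the
#'   \code{"regionNames"} attribute (0 = unsegmented).
#' @export
assignRegions <- function(tree, mapping) {
  k <- nrow(tree@centroids)
  leaves <- as.character(seq_len(k))
  mapping <- unlist(mapping)
  missing <- setdiff(leaves, names(mapping))
  if (length(missing))
    stop("mapping does not cover leaf id(s): ",
         paste(missing, collapse = ", "))
  regions <- unique(unname(mapping[leaves]))
  regionCode <- setNames(seq_along(regions), regions)
  out <- array(0L, tree@sourceDim)
  out[tree@memberIndex] <-
    as.integer(regionCode[mapping[as.character(tree@membership)]])
  attr(out, "regionNames") <- regionCode
  out
}
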