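# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname FeatureAxis-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))

#' @rdname FeatureAxis-class
#' @export
setGeneric("tolerancePpm", function(object) standardGeneric("tolerancePpm"))

#' @rdname SerialSectionDataset-class
#' @export
setGeneric("sections", function(object) standardGeneric("sections"))

#' @rdname SerialSectionDataset-class
#' @export
setGeneric("featureAxis", function(object) standardGeneric("featureAxis"))

#' @rdname SerialSectionDataset-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname SectionImage-class
#' @export
setGeneric("intensityData", function(object) standardGeneric("intensityData"))

#' @rdname SectionImage-class
#' @export
setGeneric("foregroundMask", function(object) standardGeneric("foregroundMask"))

#' @rdname SectionImage-class
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname SectionImage-class
#' @export
setGeneric("thicknessUm", function(object) standardGeneric("thicknessUm"))

#' @rdname SectionImage-class
#' @export
setGeneric("zIndex", function(object) standardGeneric("zIndex"))

#' @rdname FeatureVolume-class
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))

#' @rdname FeatureVolume-class
#' @export
setGeneric("voxelUm", function(object) standardGeneric("voxelUm"))

#' @rdname FeatureVolume-class
#' @export
setGeneric("transformsApplied",
           function(object) standardGeneric("transformsApplied"))

#' @rdname LabeledObjects-class
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @rdname LabeledObjects-class
#' @export
setGeneric("objectStats", function(object) standardGeneric("objectStats"))

#' @rdname SegmentationTree-class
#' @export
setGeneric("leafLabels", function(object) standardGeneric("leafLabels"))

#' @rdname SegmentationTree-class
#' @export
setGeneric("leafCentroids", function(object) standardGeneric("leafCentroids"))

# ---------------------------------------------------------------------------
# Methods
# ---------------------------------------------------------------------------

#' @rdname FeatureAxis-class
#' @export
setMethod("mzValues", "FeatureAxis", function(object) object@mz)

#' @rdname FeatureAxis-class
#' @export
setMethod("tolerancePpm", "FeatureAxis", function(object) object@tolerancePpm)

#' @rdname FeatureAxis-class
#' @export
setMethod("length", "FeatureAxis", function(x) length(x@mz))

#' @rdname SerialSectionDataset-class
#' @export
setMethod("sections", "SerialSectionDataset", function(object) object@sections)

#' @rdname SerialSectionDataset-class
#' @export
setMethod("featureAxis", "SerialSectionDataset",
          function(object) object@featureAxis)

#' @rdname FeatureVolume-class
#' @export
setMethod("featureAxis", "FeatureVolume", function(object) object@featureAxis)

#' @rdname SerialSectionDataset-class
#' @export
setMethod("sampleId", "SerialSectionDataset", function(object) object@sampleId)

#' @rdname SerialSectionDataset-class
#' @export
setMethod("length", "SerialSectionDataset",
          function(x) length(x@sections))

#' @rdname SerialSectionDataset-class
#' @param i section index (1-based).
#' @export
setMethod("[[", "SerialSectionDataset", function(x, i) x@sections[[i]])

#' @rdname SectionImage-class
#' @export
setMethod("intensityData", "SectionImage", function(object) object@intensities)

#' @rdname SectionImage-class
#' @export
setMethod("foregroundMask", "SectionImage", function(object) object@mask)

#' @rdname FeatureVolume-class
#' @export
setMethod("foregroundMask", "FeatureVolume", function(object) object@mask)

#' @rdname SectionImage-class
#' @export
setMethod("pixelSizeUm", "SectionImage", function(object) object@pixelSizeUm)

#' @rdname SectionImage-class
#' @export
setMethod("thicknessUm", "SectionImage", function(object) object@thicknessUm)

#' @rdname SectionImage-class
#' @export
setMethod("zIndex", "SectionImage", function(object) object@zIndex)

#' @rdname SectionImage-class
#' @export
setMethod("dim", "SectionImage", function(x) dim(x@intensities))

#' @rdname FeatureVolume-class
#' @export
setMethod("volumeData", "FeatureVolume", function(object) object@data)

#' @rdname FeatureVolume-class
#' @export
setMethod("voxelUm", "FeatureVolume", function(object) object@voxelUm)

#' @rdname LabeledObjects-class
#' @export
setMethod("voxelUm", "LabeledObjects", function(object) object@voxelUm)

#' @rdname FeatureVolume-class
#' @export
setMethod("transformsApplied", "FeatureVolume",
          function(object) object@transformsApplied)

#' @rdname FeatureVolume-class
#' @export
setMethod("dim", "FeatureVolume", function(x) dim(x@data))

#' @rdname LabeledObjects-class
#' @export
setMethod("labelArray", "LabeledObjects", function(object) object@labels)

#' @rdname LabeledObjects-class
#' @export
setMethod("objectStats", "LabeledObjects", function(object) object@stats)

#' @rdname LabeledObjects-class
#' @export
setMethod("length", "LabeledObjects", function(x) nrow(x@stats))

#' @rdname SegmentationTree-class
#' @export
setMethod("leafLabels", "SegmentationTree", function(object) object@membership)

#' @rdname SegmentationTree-class
#' @export
setMethod("leafCentroids", "SegmentationTree",
          function(object) object@centroids)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "FeatureAxis", function(object) {
  cat("FeatureAxis with", length(object@mz), "features, m/z",
      format(min(object@mz), digits = 6), "-",
      format(max(object@mz), digits = 6),
      sprintf("(tolerance %.3g ppm)\n", object@tolerancePpm))
})

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("SectionImage z=%d: %d x %d px (%g um raster, %g um thick), %d features, %d foreground px\n",
              object@zIndex, d[2], d[1], object@pixelSizeUm,
              object@thicknessUm, d[3], sum(object@mask)))
})

setMethod("show", "SerialSectionDataset", function(object) {
  cat(sprintf("SerialSectionDataset '%s': %d sections, %d features\n",
              object@sampleId, length(object@sections),
              length(object@featureAxis@mz)))
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: theta = %.4g deg, t = (%.4g, %.4g) px\n",
              object@thetaDeg, object@txPx, object@tyPx))
})

setMethod("show", "FeatureVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("FeatureVolume: %d x %d x %d voxels (z,y,x) x %d features, voxel %g x %g x %g um\n",
              d[1], d[2], d[3], d[4], object@voxelUm[1], object@voxelUm[2],
              object@voxelUm[3]))
})

setMethod("show", "LabeledObjects", function(object) {
  cat(sprintf("LabeledObjects: %d objects over %d voxels\n",
              nrow(object@stats), sum(object@labels > 0)))
  if (nrow(object@stats)) print(head(object@stats, 5))
})

setMethod("show", "SegmentationTree", function(object) {
  cat(sprintf("SegmentationTree: %d members in %d leaves (seed %d)\n",
              length(object@membership), nrow(object@centroids), object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d sections, regions {%s}, %d embedded objects, %d planted effects\n",
              length(object@transforms),
              paste(object@regionNames, collapse = ", "),
              nrow(object@objectCatalog),
              sum(object@plantedEffects$lfc != 0)))
})
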