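# End-to-end orchestration: declarative run configuration, staged execution
# (load/simulate -> reconstruct -> segment -> objects -> stats), structured
# per-stage records, and a QC report. Every intermediate is written to the
# output directory so a run is inspectable and reproducible; rerunning a
# config with the same seeds yields bit-identical tables.

.defaultConfig <- function() {
  list(
    sample = list(manifest = NULL, sample_id = NULL,
                  pixel_size_um = 20, thickness_um = 20),
    simulate = NULL,   # list of phantomSpec() arguments, used when no manifest
    landmark_mz = 863.57,
    registration = list(max_iters = 400, reference = "previous"),
    segmentation = list(n_leaves = 8, seed = 7, denoise = TRUE,
                        region_map = NULL, region_markers = NULL,
                        target_region = "fibroblast"),
    objects = list(connectivity = 26, lower = 10, upper = 100,
                   exclude_classes = "V1"),
    stats = list(group_by = "size_class", group_a = "V2", group_b = "V3",
                 alpha = 0.01, lfc = 1, test = "welch"),
    output_dir = "vox3dmsi_run")
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a single declarative YAML file (or an equivalent
#' named list); unset fields take documented defaults. Validation happens
#' before any computation.
#'
#' @param config path to a YAML file or a named list.
#' @return validated configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a named list")
  def <- .defaultConfig()
  merged <- utils::modifyList(def, config)
  v <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  v(!is.null(merged$sample$manifest) || !is.null(merged$simulate),
    "either sample$manifest or simulate must be given")
  if (!is.null(merged$sample$manifest))
    v(file.exists(merged$sample$manifest),
      paste0("manifest not found: ", merged$sample$manifest))
  v(is.numeric(merged$landmark_mz), "landmark_mz must be numeric")
  v(merged$registration$max_iters >= 1, "max_iters must be >= 1")
  v(merged$registration$reference %in% c("previous", "middle"),
    "registration reference must be 'previous' or 'middle'")
  v(merged$segmentation$n_leaves >= 2, "n_leaves must be >= 2")
  v(merged$objects$connectivity %in% c(6, 18, 26),
    "connectivity must be 6, 18 or 26")
  v(merged$objects$lower < merged$objects$upper,
    "object size bounds must satisfy lower < upper")
  v(merged$stats$alpha > 0 && merged$stats$alpha < 1,
    "alpha must be in (0, 1)")
  v(merged$stats$test %in% c("welch", "student"),
    "test must be 'welch' or 'student'")
  sm <- merged$segmentation$region_map
  if (!is.null(sm)) {
    v(!is.null(names(sm)) && all(nzchar(names(sm))),
      "region_map must be a named leaf -> region mapping")
    v(merged$segmentation$target_region %in% unlist(sm),
      "target_region missing from region_map")
  }
  merged
}

# map leaves to regions from per-region marker m/z values: each leaf's
# mean raw marker intensities are computed, every marker channel is
# normalized by its maximum across leaves, and the leaf joins the region
# whose normalized marker is largest. For markers that are strongly
# enriched in their region this reproduces a majority assignment and is
# robust to leaves that split along intensity texture rather than cell
# type.
.autoRegionMap <- function(tree, axis, regionMarkers, rawMembers) {
  cols <- vapply(regionMarkers, function(m)
    .resolveFeature(axis, as.numeric(m)), integer(1))
  k <- nrow(tree@centroids)
  cent <- t(vapply(seq_len(k), function(l)
    colMeans(rawMembers[tree@membership == l, cols, drop = FALSE]),
    numeric(length(cols))))
  cent <- sweep(cent, 2, apply(cent, 2, max), "/")
  regions <- names(regionMarkers)[max.col(cent, ties.method = "first")]
  setNames(regions, seq_len(k))
}

#' Run the full reconstruction-to-statistics pipeline
#'
#' Executes the stages in order, writing every intermediate (feature volume
#' and label NRRDs, QC and transform tables, object table, volcano table)
#' plus a JSON provenance record into the output directory. Any stage
#' error aborts with the stage name; outputs of completed stages are
#' preserved.
#'
#' @param config a config path or list, see \code{\link{readRunConfig}}.
#' @return the run record: stage outputs, file paths and provenance,
#'   invisibly.
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  outDir <- config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  record <- list(config = config, files = character(0), timings = list(),
                 package_version = as.character(utils::packageVersion("vox3dmsi")))
  stamp <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    record$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  emit <- function(obj, name) {
    path <- file.path(outDir, name)
    if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    record$files <<- c(record$files, path)
    path
  }

  # --- load or simulate -----------------------------------------------------
  truth <- NULL
  dataset <- stamp("load", {
    if (!is.null(config$sample$manifest)) {
      axis <- FeatureAxis(config$feature_mz %||% stop(
        "config$feature_mz (the feature axis) is required with a manifest"))
      readDataset(config$sample$manifest, axis,
                  sampleId = config$sample$sample_id,
                  pixelSizeUm = config$sample$pixel_size_um,
                  thicknessUm = config$sample$thickness_um)
    } else {
      spec <- do.call(phantomSpec, config$simulate)
      ph <- generatePhantom(spec)
      truth <- ph$truth
      ph$dataset
    }
  })

  # --- reconstruct ----------------------------------------------------------
  recon <- stamp("reconstruct", {
    before <- intersliceCorrelation(assembleVolume(dataset),
                                    config$landmark_mz)
    vol <- stackDataset(dataset, config$landmark_mz,
                        maxIters = config$registration$max_iters,
                        reference = config$registration$reference)
    after <- intersliceCorrelation(vol, config$landmark_mz)
    list(volume = vol, qc_before = before, qc_after = after)
  })
  writeVolumeNrrd(recon$volume, file.path(outDir, "volume.nrrd"))
  record$files <- c(record$files, file.path(outDir, "volume.nrrd"))
  tr <- recon$volume@transformsApplied
  emit(data.frame(z_index = seq_along(tr) - 1L,
                  theta_deg = vapply(tr, function(t) t@thetaDeg, 1),
                  tx_px = vapply(tr, function(t) t@txPx, 1),
                  ty_px = vapply(tr, function(t) t@tyPx, 1)),
       "transforms.tsv")
  qc <- rbind(cbind(stage = "before", recon$qc_before$pairs),
              cbind(stage = "after", recon$qc_after$pairs))
  emit(qc, "qc_correlation.tsv")

  # --- segment --------------------------------------------------------------
  seg <- stamp("segment", {
    vol <- recon$volume
    idx <- which(vol@mask)
    dat <- vol@data
    if (isTRUE(config$segmentation$denoise)) {
      for (z in seq_len(dim(dat)[1])) {
        mk <- vol@mask[z, , ]
        if (!any(mk)) next
        for (f in seq_len(dim(dat)[4]))
          dat[z, , , f] <- weakDenoise(dat[z, , , f], mk)
      }
    }
    flat <- matrix(dat, prod(dim(vol@mask)), dim(dat)[4])
    rawMembers <- flat[idx, , drop = FALSE]
    members <- rawMembers
    rms <- sqrt(rowMeans(members^2))
    members[rms > 0, ] <- members[rms > 0, , drop = FALSE] / rms[rms > 0]
    tree <- bisectingKmeans(members, config$segmentation$n_leaves,
                            seed = config$segmentation$seed,
                            memberIndex = idx, sourceDim = dim(vol@mask))
    map <- config$segmentation$region_map
    if (is.null(map)) {
      if (is.null(config$segmentation$region_markers))
        stop("segmentation needs region_map or region_markers")
      map <- .autoRegionMap(tree, vol@featureAxis,
                            config$segmentation$region_markers, rawMembers)
    }
    labels <- assignRegions(tree, map)
    list(tree = tree, map = map, labels = labels)
  })
  writeVolumeNrrd(seg$labels, file.path(outDir, "regions.nrrd"),
                  voxelUm = recon$volume@voxelUm)
  record$files <- c(record$files, file.path(outDir, "regions.nrrd"))
  emit(data.frame(leaf = seq_len(nrow(seg$tree@centroids)),
                  region = unname(unlist(seg$map)[as.character(
                    seq_len(nrow(seg$tree@centroids)))]),
                  size = tabulate(seg$tree@membership,
                                  nbins = nrow(seg$tree@centroids))),
       "leaves.tsv")

  # --- objects --------------------------------------------------------------
  obj <- stamp("objects", {
    codes <- attr(seg$labels, "regionNames")
    target <- config$segmentation$target_region
    if (!target %in% names(codes))
      stop("target region '", target, "' not present in the region map")
    mask <- seg$labels == codes[[target]]
    o <- pickObjects(mask, connectivity = config$objects$connectivity,
                     voxelUm = recon$volume@voxelUm)
    o <- classifySize(o, lower = config$objects$lower,
                      upper = config$objects$upper)
    objectGeometry(o)
  })
  writeVolumeNrrd(obj, file.path(outDir, "objects.nrrd"))
  record$files <- c(record$files, file.path(outDir, "objects.nrrd"))
  emit(objectStats(obj), "objects.tsv")

  # --- stats ----------------------------------------------------------------
  stats <- stamp("stats", {
    prof <- objectProfiles(obj, recon$volume)
    st <- objectStats(obj)
    keep <- !(st$size_class %in% config$objects$exclude_classes)
    groups <- st$size_class[keep]
    prof <- prof[keep, , drop = FALSE]
    ga <- groups == config$stats$group_a
    gb <- groups == config$stats$group_b
    if (sum(ga) < 2 || sum(gb) < 2)
      stop("need >= 2 objects in each compared group (have ",
           sum(ga), " ", config$stats$group_a, ", ", sum(gb), " ",
           config$stats$group_b, ")")
    res <- differentialTest(prof[ga, , drop = FALSE],
                            prof[gb, , drop = FALSE],
                            mz = mzValues(featureAxis(recon$volume)),
                            alpha = config$stats$alpha,
                            lfcThreshold = config$stats$lfc,
                            test = config$stats$test)
    list(profiles = prof, groups = groups, result = res,
         volcano = volcanoTable(res))
  })
  emit(stats$volcano, "volcano.tsv")
  profTab <- data.frame(object_id = rownames(stats$profiles),
                        group = stats$groups,
                        stats$profiles, check.names = FALSE)
  emit(profTab, "object_profiles.tsv")

  record$dataset <- dataset
  record$truth <- truth
  record$reconstruct <- recon
  record$segment <- seg
  record$objects <- obj
  record$stats <- stats

  prov <- list(package_version = record$package_version,
               config = config, timings = record$timings,
               files = record$files,
               seeds = list(segmentation = config$segmentation$seed,
                            simulate = config$simulate$seed))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  record$files <- c(record$files, file.path(outDir, "provenance.json"))
  invisible(record)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quality-control report for a pipeline run
#'
#' Summarizes inter-slice landmark correlation before and after
#' registration, per-slice transform magnitudes, segmentation leaf sizes,
#' and the object size histogram; optionally written as a markdown report.
#'
#' @param record a run record from \code{\link{runPipeline}}.
#' @param path optional path for a markdown report file.
#' @return list with the report tables.
#' @export
qcReport <- function(record, path = NULL) {
  if (is.null(record$reconstruct))
    stop("run record lacks a completed reconstruction stage")
  before <- record$reconstruct$qc_before
  after <- record$reconstruct$qc_after
  corr <- data.frame(pair = paste(before$pairs$z_a, before$pairs$z_b,
                                  sep = "-"),
                     before = before$pairs$correlation,
                     after = after$pairs$correlation)
  tr <- record$reconstruct$volume@transformsApplied
  transforms <- data.frame(
    z_index = seq_along(tr) - 1L,
    theta_deg = vapply(tr, function(t) t@thetaDeg, 1),
    translation_px = vapply(tr, function(t) sqrt(t@txPx^2 + t@tyPx^2), 1))
  leaves <- if (!is.null(record$segment))
    data.frame(leaf = seq_len(nrow(record$segment$tree@centroids)),
               size = tabulate(record$segment$tree@membership,
                               nbins = nrow(record$segment$tree@centroids)))
  hist <- if (!is.null(record$objects)) sizeHistogram(record$objects)
  rep <- list(correlation = corr,
              correlation_summary = data.frame(
                stage = c("before", "after"),
                mean = c(before$mean, after$mean),
                sd = c(before$sd, after$sd)),
              transforms = transforms, leaves = leaves,
              size_histogram = hist)
  if (!is.null(path)) {
    lines <- c("# Run QC report", "",
               sprintf("Inter-slice landmark correlation: %.3f +/- %.3f before, %.3f +/- %.3f after registration.",
                       before$mean, before$sd, after$mean, after$sd), "",
               "## Correlation per adjacent pair", "",
               paste(utils::capture.output(print(corr)), collapse = "\n"),
               "", "## Transform magnitude per slice", "",
               paste(utils::capture.output(print(transforms)), collapse = "\n"))
    if (!is.null(leaves))
      lines <- c(lines, "", "## Segmentation leaves", "",
                 paste(utils::capture.output(print(leaves)), collapse = "\n"))
    if (!is.null(hist))
      lines <- c(lines, "", "## Object size histogram", "",
                 paste(utils::capture.output(print(hist)), collapse = "\n"))
    writeLines(lines, path)
  }
  rep
}
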