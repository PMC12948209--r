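test_that("default biculture geometry slices into 30 sections of 20 um", {
  ph <- cachedPhantom("geom", phantomSpec(seed = 2L))
  expect_equal(length(ph$dataset), 30L)   # 600 um / 20 um
  expect_equal(thicknessUm(ph$dataset[[1]]), 20)
  expect_equal(pixelSizeUm(ph$dataset[[1]]), 20)
  expect_equal(dim(ph$truth@regionVolume)[1], 30L)
  expect_equal(length(ph$truth@transforms), 30L)
  # every embedded cluster appears in the catalog
  expect_equal(nrow(ph$truth@objectCatalog) >=
                 sum(ph$truth@clusterInfo$voxel_count > 0), TRUE)
})

test_that("a fixed seed reproduces the phantom bit-exactly", {
  a <- generatePhantom(smallPhantomSpec(seed = 11L))
  b <- generatePhantom(smallPhantomSpec(seed = 11L))
  expect_identical(intensityData(a$dataset[[5]]), intensityData(b$dataset[[5]]))
  expect_identical(a$truth@regionVolume, b$truth@regionVolume)
  expect_equal(a$truth@transforms[[7]]@thetaDeg, b$truth@transforms[[7]]@thetaDeg)
  c <- generatePhantom(smallPhantomSpec(seed = 12L))
  expect_false(isTRUE(all.equal(a$truth@transforms[[7]]@thetaDeg,
                                c$truth@transforms[[7]]@thetaDeg)))
})

test_that("noise-free, unperturbed tissue voxels equal their region means", {
  spec <- smallPhantomSpec(seed = 4L, sigmaM = 0, sigmaA = 0,
                           textureSigma = 0, maxTransPx = 0, maxRotDeg = 0)
  ph <- generatePhantom(spec)
  ms <- spec@markerSpec[order(spec@markerSpec$mz), ]
  vol <- assembleVolume(ph$dataset)
  reg <- ph$truth@regionVolume
  cid <- floodFillLabel(reg == 2L, 26)
  classes <- ph$truth@objectCatalog$size_class
  dat <- volumeData(vol)
  for (f in seq_len(nrow(ms))) {
    plane <- dat[, , , f]
    cancer <- plane[reg == 1L]
    expect_true(all(cancer == ms$regionA[f]))
    v2 <- plane[reg == 2L & array(cid %in% which(classes != "V3"), dim(reg))]
    if (length(v2)) expect_true(all(v2 == ms$regionB[f]))
  }
})

test_that("planted V2-vs-V3 fold changes scale V3-cluster means", {
  spec <- smallPhantomSpec(seed = 2L, sigmaM = 0, sigmaA = 0,
                           textureSigma = 0, maxTransPx = 0, maxRotDeg = 0,
                           spheroidRadiusUm = 220,
                           clusterRadiusRangeUm = c(40, 70))
  ph <- generatePhantom(spec)
  cat <- ph$truth@objectCatalog
  expect_true(any(cat$size_class == "V3"))
  ms <- spec@markerSpec[order(spec@markerSpec$mz), ]
  vol <- volumeData(assembleVolume(ph$dataset))
  reg <- ph$truth@regionVolume
  cid <- floodFillLabel(reg == 2L, 26)
  v3vox <- array(cid %in% which(cat$size_class == "V3"), dim(reg)) & reg == 2L
  for (f in which(ms$lfc != 0)) {
    expect_equal(unique(vol[, , , f][v3vox]),
                 ms$regionB[f] * 2^(-ms$lfc[f]))
  }
})

test_that("truth catalog comes from an independent flood fill", {
  # a single embedded sphere of one-voxel radius voxelizes to 7 voxels (V1)
  mask <- array(FALSE, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    mask[3 + d[1], 3 + d[2], 3 + d[3]] <- TRUE
  lab <- floodFillLabel(mask, 6)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), 7L)

  # two disjoint clusters give two catalog entries
  truth <- new("PhantomTruth",
               transforms = list(), regionVolume = {
                 r <- array(0L, c(4, 6, 6)); r[2, 2, 2] <- 2L; r[2, 5, 5] <- 2L; r
               },
               regionNames = setNames(c("background", "cancer", "fibroblast"), 0:2),
               objectCatalog = data.frame(), plantedEffects = data.frame(),
               clusterInfo = data.frame(), spec = smallPhantomSpec())
  cat2 <- catalogTruthObjects(truth)
  expect_equal(nrow(cat2), 2L)
  expect_equal(cat2$size_class, c("V1", "V1"))
})

test_that("impossible cluster packing raises a placement error", {
  spec <- smallPhantomSpec(seed = 1L, nClusters = 60L,
                           clusterRadiusRangeUm = c(60, 80))
  expect_error(generatePhantom(spec), "placement")
})

test_that("unperturbed stacks correlate at least as well as perturbed ones", {
  still <- generatePhantom(smallPhantomSpec(seed = 6L, maxTransPx = 0,
                                            maxRotDeg = 0))
  moved <- generatePhantom(smallPhantomSpec(seed = 6L))
  mz <- phantomLandmarkMz(still$truth@spec)
  cStill <- intersliceCorrelation(assembleVolume(still$dataset), mz)$mean
  cMoved <- intersliceCorrelation(assembleVolume(moved$dataset), mz)$mean
  expect_gte(cStill, cMoved)
})

test_that("organoid mode plants lumen-enriched small-mass channels", {
  ph <- cachedPhantom("organoid",
                      phantomSpec(mode = "cystic_organoid", seed = 5L,
                                  spheroidRadiusUm = 200,
                                  shellThicknessUm = 60, marginPx = 8L))
  truth <- ph$truth
  expect_setequal(unname(truth@regionNames), c("background", "shell", "lumen"))
  expect_gt(sum(truth@regionVolume == 2L), 0)
  eff <- truth@plantedEffects
  # the nucleotide-like channels are lumen-enriched (positive lumen/shell lfc)
  expect_true(all(eff$lfc[eff$mz %in% c(505.99, 521.98)] > 2))
  # shell lipid channels are shell-enriched
  expect_true(all(eff$lfc[eff$mz %in% c(742.54, 835.54, 861.55)] < -1))
})
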