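test_that("feature axis validity and peak matching behave", {
  ax <- FeatureAxis(c(87.01, 778.51, 863.57), tolerancePpm = 10)
  expect_equal(length(ax), 3L)
  expect_error(FeatureAxis(c(2, 1)), "ascending")
  expect_error(FeatureAxis(c(-1, 2)), "positive")
  expect_error(FeatureAxis(c(500, 500.001), tolerancePpm = 10), "tolerance")

  # 863.5701 Da vs axis entry 863.57 is ~0.12 ppm: matched
  expect_equal(matchFeatures(ax, 863.5701), 3L)
  # 900 Da matches nothing at 10 ppm
  expect_true(is.na(matchFeatures(ax, 900)))
  # order independence of matching
  q <- c(87.0101, 863.5699, 778.51)
  expect_equal(matchFeatures(ax, q), c(1L, 3L, 2L))
})

test_that("imzML round trip is the identity on mask and foreground intensities", {
  ph <- cachedPhantom()
  ax <- featureAxis(ph$dataset)
  dir <- withr::local_tempdir()
  for (i in c(4L, 8L)) {
    sec <- ph$dataset[[i]]
    path <- file.path(dir, sprintf("s%d.imzML", i))
    writeSectionImzML(sec, ax, path)
    back <- readSectionImzML(path, ax, zIndex = zIndex(sec))
    expect_identical(foregroundMask(back), foregroundMask(sec))
    expect_identical(pixelSizeUm(back), pixelSizeUm(sec))
    # sparse centroid files carry foreground pixels only; off-tissue
    # intensities are zero on read
    mk <- foregroundMask(sec)
    a <- intensityData(sec); b <- intensityData(back)
    for (f in seq_len(dim(a)[3])) {
      expect_identical(a[, , f][mk], b[, , f][mk])
      expect_true(all(b[, , f][!mk] == 0))
    }
  }
})

test_that("randomized sections survive the imzML round trip", {
  ax <- FeatureAxis(c(100.1, 200.2, 300.3, 400.4), tolerancePpm = 10)
  dir <- withr::local_tempdir()
  set.seed(42)
  for (rep in 1:20) {
    h <- sample(3:9, 1); w <- sample(3:9, 1)
    inten <- array(round(rexp(h * w * 4), 4), c(h, w, 4))
    mask <- matrix(runif(h * w) < 0.6, h, w)
    if (!any(mask)) mask[1, 1] <- TRUE
    inten[array(!mask, c(h, w, 4))] <- 0
    sec <- SectionImage(inten, mask, zIndex = 0L)
    p <- file.path(dir, sprintf("r%d.imzML", rep))
    writeSectionImzML(sec, ax, p)
    back <- readSectionImzML(p, ax)
    expect_identical(intensityData(back), intensityData(sec))
    expect_identical(foregroundMask(back), foregroundMask(sec))
  }
})

test_that("peak binning is order-independent and sums collisions", {
  ax <- FeatureAxis(c(500, 600), tolerancePpm = 20)
  sec <- SectionImage(array(c(3, 7), c(1, 1, 2)), matrix(TRUE, 1, 1))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "one.imzML")
  writeSectionImzML(sec, ax, p)
  # swap the two peaks inside the ibd (mz and intensity arrays separately):
  # binning must not depend on peak order within a spectrum
  ibd <- sub("imzML$", "ibd", p)
  raw <- readBin(ibd, "raw", file.size(ibd))
  mz <- readBin(raw[17:32], "double", 2, endian = "little")
  it <- readBin(raw[33:48], "double", 2, endian = "little")
  raw[17:32] <- writeBin(rev(mz), raw(), endian = "little")
  raw[33:48] <- writeBin(rev(it), raw(), endian = "little")
  writeBin(raw, ibd)
  back <- readSectionImzML(p, ax)
  expect_identical(intensityData(back), intensityData(sec))

  # collision: two peaks near one axis entry are summed (ion conservation)
  ax1 <- FeatureAxis(500, tolerancePpm = 50)
  raw[17:32] <- writeBin(c(500.001, 500.002), raw(), endian = "little")
  writeBin(raw, ibd)
  back2 <- readSectionImzML(p, ax1)
  expect_equal(as.vector(intensityData(back2)), 10)
})

test_that("degenerate imzML inputs raise informative errors", {
  ax <- FeatureAxis(863.57, tolerancePpm = 10)
  dir <- withr::local_tempdir()
  # a section whose only peak is far off-axis: empty-section error
  secFar <- SectionImage(array(5, c(1, 1, 1)), matrix(TRUE, 1, 1))
  p <- file.path(dir, "far.imzML")
  writeSectionImzML(secFar, FeatureAxis(900), p)
  expect_error(readSectionImzML(p, ax), "empty section")
  # all-background section cannot be written
  bg <- SectionImage(array(0, c(2, 2, 1)), matrix(FALSE, 2, 2))
  expect_error(writeSectionImzML(bg, ax, file.path(dir, "bg.imzML")),
               "no foreground")
  # malformed XML names the file
  writeLines("<mzML><oops></mzML>", file.path(dir, "bad.imzML"))
  expect_error(readSectionImzML(file.path(dir, "bad.imzML"), ax),
               "parse error")
})

test_that("NRRD round trip preserves doubles and integer labels exactly", {
  dir <- withr::local_tempdir()
  set.seed(7)
  vol <- array(rexp(3 * 4 * 5), c(3, 4, 5))
  p <- file.path(dir, "v.nrrd")
  writeVolumeNrrd(vol, p, voxelUm = c(20, 20, 20))
  hdr <- readLines(p, n = 9, warn = FALSE)
  expect_true(any(grepl("^sizes: 3 4 5$", hdr)))
  expect_true(any(grepl("^spacings: 20 20 20$", hdr)))
  back <- readVolumeNrrd(p)
  expect_identical(back$data, vol)
  expect_equal(back$voxelUm, c(20, 20, 20))

  labs <- array(sample.int(5L, 60, replace = TRUE) - 1L, c(3, 4, 5))
  writeVolumeNrrd(labs, p, voxelUm = c(20, 10, 10))
  back2 <- readVolumeNrrd(p)
  expect_identical(back2$data, labs)

  expect_error(writeVolumeNrrd(array(0, c(0, 2, 2)), p, voxelUm = c(1, 1, 1)),
               "non-empty")
})

test_that("datasets round trip through per-section imzML plus manifest", {
  ph <- cachedPhantom()
  dir <- withr::local_tempdir()
  manifest <- writeDataset(ph$dataset, dir)
  back <- readDataset(manifest, featureAxis(ph$dataset),
                      pixelSizeUm = 20, thicknessUm = 20)
  expect_equal(length(back), length(ph$dataset))
  expect_identical(foregroundMask(back[[3]]), foregroundMask(ph$dataset[[3]]))
  # z order comes from the manifest, not the file listing: shuffle rows
  man <- read.delim(manifest)
  man <- man[rev(seq_len(nrow(man))), ]
  write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- readDataset(manifest, featureAxis(ph$dataset))
  expect_identical(vapply(sections(back2), zIndex, integer(1)),
                   seq_len(length(back2)) - 1L)
})
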