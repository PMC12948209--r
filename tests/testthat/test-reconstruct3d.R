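test_that("rigid transform algebra composes and inverts exactly", {
  t1 <- RigidTransform2D(10, 2, -1)
  t2 <- RigidTransform2D(-25, 0.5, 3)
  id <- composeRigid(t1, invertRigid(t1))
  expect_equal(id@thetaDeg, 0)
  expect_equal(id@txPx, 0, tolerance = 1e-12)
  expect_equal(id@tyPx, 0, tolerance = 1e-12)
  # associativity
  a <- composeRigid(composeRigid(t1, t2), invertRigid(t2))
  expect_equal(a@thetaDeg, t1@thetaDeg)
  expect_equal(a@txPx, t1@txPx, tolerance = 1e-12)
  # applying a transform then its inverse restores a smooth image interior
  set.seed(1)
  img <- matrix(0, 31, 31)
  img[8:24, 8:24] <- outer(sin(1:17 / 2), cos(1:17 / 3)) + 2
  fwd <- applyRigid(img, t1)
  back <- applyRigid(fwd, invertRigid(t1))
  expect_lt(max(abs(back[12:20, 12:20] - img[12:20, 12:20])), 0.15)
})

test_that("RMS normalization rescales foreground spectra to unit RMS", {
  inten <- array(0, c(1, 2, 3))
  inten[1, 1, ] <- c(2, 2, 2)
  inten[1, 2, ] <- c(3, 4, 0)
  sec <- SectionImage(inten, matrix(TRUE, 1, 2))
  out <- rmsNormalize(sec)
  expect_equal(intensityData(out)[1, 1, ], c(1, 1, 1))
  # (3, 4, 0): RMS = sqrt(25/3)
  expect_equal(intensityData(out)[1, 2, ], c(3, 4, 0) / sqrt(25 / 3))
  # post-normalization RMS is 1 for every clean foreground pixel
  m <- matrix(intensityData(out), 2, 3)
  expect_equal(sqrt(rowMeans(m^2)), c(1, 1))
  # all-zero foreground pixels are left alone and flagged
  inten[1, 2, ] <- 0
  sec2 <- SectionImage(inten, matrix(TRUE, 1, 2))
  out2 <- rmsNormalize(sec2)
  expect_equal(attr(out2, "qcZeroPixels"), 2L)
  expect_equal(intensityData(out2)[1, 2, ], c(0, 0, 0))
})

test_that("ion image extraction selects the matching channel or errors", {
  ax <- FeatureAxis(c(863.57, 885.55))
  inten <- array(1:8, c(2, 2, 2))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  sec <- SectionImage(inten, mask)
  img <- extractIonImage(sec, ax, 863.57)
  expect_equal(img[1, 1], 1)
  expect_equal(img[2, 2], 0)   # background zeroed
  expect_error(extractIonImage(sec, ax, 500), "unknown feature")
})

test_that("registerPair recovers known transforms on phantom slices", {
  ph <- cachedPhantom()
  ax <- featureAxis(ph$dataset)
  mid <- (length(ph$dataset) + 1) %/% 2
  sec <- rmsNormalize(ph$dataset[[mid]])
  img <- extractIonImage(sec, ax, 863.57)
  # self-registration is the identity
  self <- registerPair(img, img)
  expect_lt(abs(self@thetaDeg), 0.1)
  expect_lt(abs(self@txPx), 0.1)
  expect_lt(abs(self@tyPx), 0.1)
  # pure translation by (+3, -2) px recovered as its inverse within 0.5 px
  mov <- applyRigid(img, RigidTransform2D(0, 3, -2))
  tr <- registerPair(img, mov)
  expect_lt(abs(tr@txPx - (-3)), 0.5)
  expect_lt(abs(tr@tyPx - 2), 0.5)
  # added 8 degree rotation recovered within 1 degree
  mov2 <- applyRigid(img, RigidTransform2D(8, 3, -2))
  tr2 <- registerPair(img, mov2)
  expect_lt(abs(tr2@thetaDeg - (-8)), 1)
  # registering the pair both ways yields mutually inverse transforms
  fwd <- registerPair(img, mov2)
  bwd <- registerPair(mov2, img, fixedMask = mov2 > 0)
  round <- composeRigid(fwd, bwd)
  expect_lt(abs(round@thetaDeg), 0.5)
  expect_lt(sqrt(round@txPx^2 + round@tyPx^2), 0.5)
})

test_that("degenerate registration inputs return identity with a warning", {
  flat <- matrix(1, 16, 16)
  expect_warning(tr <- registerPair(flat, flat), "degenerate")
  expect_equal(tr@thetaDeg, 0)
})

test_that("stacking produces a volume of the expected shape and transforms", {
  ph <- cachedPhantom()
  vol <- stackDataset(ph$dataset, 863.57)
  d <- dim(ph$dataset[[1]])
  expect_equal(dim(vol), c(length(ph$dataset), d[1], d[2], d[3]))
  expect_equal(length(transformsApplied(vol)), length(ph$dataset))
  expect_equal(voxelUm(vol), c(20, 20, 20))
  expect_error(stackDataset(ph$dataset, 999), "unknown feature")
})

test_that("stacking leaves integer-translated slices nearly unchanged in total signal", {
  # pure integer translations are exact under bilinear interpolation
  ph <- cachedPhantom()
  sec <- ph$dataset[[8]]
  img <- intensityData(sec)[, , 11]
  shifted <- applyRigid(img, RigidTransform2D(0, 3, -2))
  expect_lt(abs(sum(shifted) - sum(img)) / sum(img), 0.01)
})

test_that("transform recovery on an unperturbed phantom is near-identity", {
  still <- generatePhantom(phantomSpec(seed = 8L, maxTransPx = 0,
                                       maxRotDeg = 0))
  vol <- stackDataset(still$dataset, 863.57)
  rr <- transformRecovery(vol, still$truth)
  inner <- 3:(nrow(rr) - 2)
  expect_lt(max(rr$residual_trans_px[inner]), 0.25)
  expect_lt(median(abs(rr$residual_theta_deg)), 0.5)
})

test_that("noise-free recovery keeps interior translations within a quarter pixel", {
  # stochastic intensity terms off; perturbations and texture structure on
  ph <- generatePhantom(phantomSpec(seed = 9L, sigmaM = 0, sigmaA = 0))
  vol <- stackDataset(ph$dataset, 863.57)
  rr <- transformRecovery(vol, ph$truth)
  inner <- 3:(nrow(rr) - 2)
  expect_lt(max(rr$residual_trans_px[inner]), 0.25)
  expect_lt(median(abs(rr$residual_theta_deg)), 0.5)
})

test_that("inter-slice correlation QC matches closed forms", {
  ax <- FeatureAxis(c(100, 200))
  set.seed(3)
  base <- matrix(rexp(36) + 1, 6, 6)
  mkSec <- function(img, z) {
    a <- array(0, c(6, 6, 2)); a[, , 1] <- img; a[, , 2] <- 1
    SectionImage(a, matrix(TRUE, 6, 6), zIndex = z)
  }
  # duplicated slices correlate perfectly
  ds <- SerialSectionDataset(list(mkSec(base, 0L), mkSec(base, 1L),
                                  mkSec(base, 2L)), ax)
  qc <- intersliceCorrelation(assembleVolume(ds), 100)
  expect_equal(qc$pairs$correlation, c(1, 1))
  expect_equal(nrow(qc$pairs), length(ds) - 1L)
  # anti-correlated checkerboard pair scores -1
  chk <- matrix(rep(c(1, 2), 18), 6, 6)
  ds2 <- SerialSectionDataset(list(mkSec(chk, 0L), mkSec(3 - chk, 1L)), ax)
  qc2 <- intersliceCorrelation(assembleVolume(ds2), 100)
  expect_equal(qc2$pairs$correlation, -1)
  # pairs with under 10 union voxels are skipped and logged
  tiny <- array(0, c(2, 2, 2)); tiny[1, 1, ] <- 1
  s1 <- SectionImage(tiny, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), zIndex = 0L)
  s2 <- SectionImage(tiny, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), zIndex = 1L)
  qc3 <- intersliceCorrelation(assembleVolume(SerialSectionDataset(list(s1, s2),
                                                                   FeatureAxis(c(100, 200)))), 100)
  expect_equal(qc3$skipped, 1L)
  expect_equal(nrow(qc3$pairs), 0L)
})

test_that("registration improves inter-slice correlation on perturbed phantoms", {
  ph <- cachedPhantom()
  mz <- phantomLandmarkMz(ph$truth@spec)
  before <- intersliceCorrelation(assembleVolume(ph$dataset), mz)$mean
  after <- intersliceCorrelation(stackDataset(ph$dataset, mz), mz)$mean
  expect_gt(after, before)
})
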