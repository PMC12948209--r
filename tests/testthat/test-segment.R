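test_that("intensity-threshold feature selection keeps thresholded local maxima", {
  ax <- FeatureAxis(c(100, 101, 150, 200), tolerancePpm = 10)
  inten <- array(0, c(1, 2, 4))
  inten[1, 1, ] <- c(50000, 20000, 40000, 10000)
  inten[1, 2, ] <- c(50000, 20000, 40000, 10000)
  ds <- SerialSectionDataset(list(SectionImage(inten, matrix(TRUE, 1, 2))), ax)
  # peaks 1 Da apart within a 2 Da window: only the larger survives
  sel <- thresholdFeatureList(ds, 30000, windowDa = 2)
  expect_equal(mzValues(sel), c(100, 150))
  # threshold 0 keeps all local maxima
  sel0 <- thresholdFeatureList(ds, 0, windowDa = 2)
  expect_equal(mzValues(sel0), c(100, 150, 200))
  expect_error(thresholdFeatureList(ds, 1e9), "lower the threshold")
})

test_that("feature count is non-increasing in the intensity threshold", {
  set.seed(10)
  for (rep in 1:5) {
    nF <- 20
    mz <- sort(runif(nF, 100, 1000))
    mz <- mz[c(TRUE, diff(mz) / mz[-nF] * 1e6 > 30)]
    ax <- FeatureAxis(mz, tolerancePpm = 10)
    inten <- array(rexp(length(mz) * 9, 1 / 1000), c(3, 3, length(mz)))
    ds <- SerialSectionDataset(list(SectionImage(inten, matrix(TRUE, 3, 3))), ax)
    counts <- vapply(c(0, 200, 500, 1500), function(th) {
      sel <- tryCatch(thresholdFeatureList(ds, th, windowDa = 20),
                      error = function(e) NULL)
      if (is.null(sel)) 0L else length(sel)
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("ROC AUC equals brute-force pair counting and handles edge cases", {
  set.seed(11)
  for (rep in 1:20) {
    a <- round(rexp(sample(3:8, 1)), 2)
    b <- round(rexp(sample(3:8, 1)), 2)
    expect_equal(rocAuc(a, b), aucOracle(a, b))
  }
  # perfect separation scores 1
  expect_equal(rocAuc(c(5, 6, 7), c(1, 2, 3)), 1)
  # constant feature scores 0.5
  expect_equal(rocAuc(rep(2, 5), rep(2, 7)), 0.5)
})

test_that("ROC feature selection keeps discriminating features only", {
  set.seed(12)
  n <- 1000
  labels <- rep(c("a", "b"), each = n)
  ax <- FeatureAxis(c(100, 200, 300))
  x <- cbind(c(rnorm(n, 3), rnorm(n, 0)),   # strongly discriminating
             c(rnorm(n, 0), rnorm(n, 1)),   # weakly discriminating
             rnorm(2 * n))                  # null: AUC ~ 0.5, dropped
  sel <- rocDiscriminatingFeatures(x, labels, ax, aucThreshold = 0.65)
  expect_equal(mzValues(sel), c(100, 200))
  scores <- attr(sel, "scores")
  expect_lt(abs(scores$score[3] - 0.5), 0.05)
  # topN trims to the best-scoring features
  sel1 <- rocDiscriminatingFeatures(x, labels, ax, aucThreshold = 0.6,
                                    topN = 1)
  expect_equal(mzValues(sel1), 100)
  # raising the threshold never adds features
  selHi <- rocDiscriminatingFeatures(x, labels, ax, aucThreshold = 0.9)
  expect_true(all(mzValues(selHi) %in% mzValues(sel)))
  expect_error(rocDiscriminatingFeatures(x[1:15, ], labels[c(1:5, n + 1:10)],
                                         ax), "at least 10")
})

test_that("weak de-noising is a masked 3x3 median filter", {
  const <- matrix(4, 6, 6)
  expect_equal(weakDenoise(const), const)
  # an isolated spike in a flat field is removed
  spike <- const; spike[3, 3] <- 100
  expect_equal(weakDenoise(spike), const)
  # salt-and-pepper corruption: filtering reduces error vs the clean image
  set.seed(13)
  clean <- outer(1:12, 1:12, function(i, j) 10 + sin(i / 2) + cos(j / 3))
  noisy <- clean
  hit <- sample(length(noisy), 20)
  noisy[hit] <- sample(c(0, 50), 20, replace = TRUE)
  den <- weakDenoise(noisy)
  expect_lt(mean(abs(den - clean)), mean(abs(noisy - clean)))
  # background pixels pass through untouched when masked
  mask <- matrix(TRUE, 6, 6); mask[1, ] <- FALSE
  img <- const; img[1, ] <- 77
  out <- weakDenoise(img, mask)
  expect_equal(out[1, ], rep(77, 6))
})

test_that("bisecting k-means recovers separated profiles and partitions members", {
  set.seed(14)
  centers <- rbind(c(10, 1, 1, 5), c(1, 10, 1, 5), c(1, 1, 10, 5))
  truth <- rep(1:3, each = 40)
  x <- centers[truth, ] * matrix(exp(rnorm(120 * 4, 0, 0.05)), 120, 4)
  x <- x / sqrt(rowMeans(x^2))
  tree <- bisectingKmeans(x, 3, seed = 21)
  expect_equal(adjustedRand(leafLabels(tree), truth), 1)
  # leaves partition the members exactly
  expect_true(all(leafLabels(tree) %in% 1:3))
  expect_equal(length(leafLabels(tree)), nrow(x))
  # determinism under a fixed seed
  tree2 <- bisectingKmeans(x, 3, seed = 21)
  expect_identical(leafLabels(tree), leafLabels(tree2))
  # positive rescaling of a member never changes its leaf
  x2 <- x; x2[17, ] <- x2[17, ] * 50
  tree3 <- bisectingKmeans(x2, 3, seed = 21)
  expect_equal(leafLabels(tree3)[17], leafLabels(tree)[17])
  # single leaf holds everything
  t1 <- bisectingKmeans(x, 1, seed = 1)
  expect_true(all(leafLabels(t1) == 1L))
  # more leaves than distinct members is an error
  expect_error(bisectingKmeans(matrix(1:4, 2, 2)[c(1, 1, 2, 2), ], 3,
                               seed = 1), "distinct members")
})

test_that("region assignment merges mapped leaves and rejects gaps", {
  set.seed(15)
  x <- rbind(matrix(rnorm(40, 5), 10, 4), matrix(rnorm(40, -5), 10, 4),
             matrix(rep(c(9, -9, 9, -9), each = 10), 10, 4))
  tree <- bisectingKmeans(x, 3, seed = 2, memberIndex = 1:30,
                          sourceDim = c(30L, 1L, 1L))
  lab <- assignRegions(tree, c("1" = "tissue", "2" = "tissue",
                               "3" = "background"))
  expect_equal(length(unique(lab[lab > 0])), 2L)
  expect_error(assignRegions(tree, c("1" = "tissue")), "leaf id")
})

test_that("phantom tissue regions and background are recovered by segmentation", {
  ph <- generatePhantom(smallPhantomSpec(seed = 5L, nClusters = 4L,
                                         maxTransPx = 0, maxRotDeg = 0))
  vol <- assembleVolume(ph$dataset)
  dat <- volumeData(vol)
  nF <- dim(dat)[4]
  for (z in seq_len(dim(dat)[1])) {
    mk <- foregroundMask(vol)[z, , ]
    for (f in seq_len(nF)) dat[z, , , f] <- weakDenoise(dat[z, , , f], mk)
  }
  flat <- matrix(dat, prod(dim(foregroundMask(vol))), nF)
  truthReg <- as.vector(ph$truth@regionVolume)
  set.seed(16)
  idx <- c(which(truthReg > 0L), sample(which(truthReg == 0L), 2000))
  members <- flat[idx, ]
  rms <- sqrt(rowMeans(members^2))
  members[rms > 0, ] <- members[rms > 0, ] / rms[rms > 0]
  tree <- bisectingKmeans(members, 6, seed = 3, memberIndex = idx,
                          sourceDim = dim(foregroundMask(vol)))
  mem <- leafLabels(tree)
  # majority mapping of leaves to truth regions (the scripted stand-in for
  # the manual sub-cluster selection)
  leafRegion <- vapply(1:6, function(l)
    as.integer(names(which.max(table(truthReg[idx][mem == l])))), integer(1))
  pred <- leafRegion[mem]
  # background vs tissue separation
  expect_gt(mean((pred == 0L) == (truthReg[idx] == 0L)), 0.99)
  # three-region recovery over tissue voxels
  tissue <- truthReg[idx] > 0L
  expect_gt(mean(pred[tissue] == truthReg[idx][tissue]), 0.95)
})
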