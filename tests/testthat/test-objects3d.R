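test_that("connectivity definitions follow voxel adjacency", {
  # two voxels sharing only a corner: one object at 26, two at 6
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(length(pickObjects(m, 26)), 1L)
  expect_equal(length(pickObjects(m, 6)), 2L)
  # an edge-sharing pair joins at 18 but not at 6
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[1, 2, 2] <- TRUE
  expect_equal(length(pickObjects(m2, 18)), 1L)
  expect_equal(length(pickObjects(m2, 6)), 2L)
  # a full cube is one object of 27 voxels
  cube <- array(TRUE, c(3, 3, 3))
  o <- pickObjects(cube, 26)
  expect_equal(objectStats(o)$voxel_count, 27L)
  # empty mask: zero objects, warned
  expect_warning(o0 <- pickObjects(array(FALSE, c(2, 2, 2))), "empty mask")
  expect_equal(length(o0), 0L)
})

test_that("union-find labeling agrees with the flood-fill oracle", {
  set.seed(20)
  for (rep in 1:25) {
    m <- array(runif(12^3) < 0.2, c(12, 12, 12))
    for (conn in c(6, 18, 26)) {
      a <- labelArray(pickObjects(m, conn))
      b <- floodFillLabel(m, conn)
      expect_identical(a, b)
    }
  }
})

test_that("object count is monotone in connectivity", {
  set.seed(21)
  for (rep in 1:10) {
    m <- array(runif(10^3) < 0.25, c(10, 10, 10))
    n6 <- length(pickObjects(m, 6))
    n18 <- length(pickObjects(m, 18))
    n26 <- length(pickObjects(m, 26))
    expect_true(n6 >= n18 && n18 >= n26)
    # conservation: per-object counts sum to the mask total
    expect_equal(sum(objectStats(pickObjects(m, 26))$voxel_count), sum(m))
  }
})

test_that("size classes follow the V1/V2/V3 boundary convention", {
  lab <- array(0L, c(1, 500, 4))
  lab[1, 1:5, 1] <- 1L
  lab[1, 1:10, 2] <- 2L
  lab[1, 1:100, 3] <- 3L
  lab[1, 1:250, 4] <- 4L
  o <- new("LabeledObjects", labels = lab, voxelUm = c(20, 20, 20),
           stats = data.frame(object_id = 1:4,
                              voxel_count = c(5L, 10L, 100L, 250L)))
  o <- classifySize(o)
  expect_equal(objectStats(o)$size_class, c("V1", "V2", "V2", "V3"))
  expect_equal(as.integer(attr(o, "classCounts")), c(1L, 2L, 1L))
  expect_error(classifySize(o, lower = 100, upper = 10), "lower < upper")
  # histogram totals conserve the object count
  h <- sizeHistogram(o)
  expect_equal(sum(h$n_objects), 4L)
})

test_that("object geometry matches hand counts and the face-scan oracle", {
  # one 20 um voxel: 8000 um3 volume, 2400 um2 surface
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  o1 <- objectGeometry(pickObjects(m1, 26, voxelUm = c(20, 20, 20)))
  expect_equal(objectStats(o1)$volume_um3, 8000)
  expect_equal(objectStats(o1)$surface_area_um2, 2400)
  # a 1x1x2 bar: 16000 um3, 4000 um2 (10 exposed faces)
  m2 <- array(FALSE, c(3, 3, 4)); m2[2, 2, 2:3] <- TRUE
  o2 <- objectGeometry(pickObjects(m2, 26, voxelUm = c(20, 20, 20)))
  expect_equal(objectStats(o2)$volume_um3, 16000)
  expect_equal(objectStats(o2)$surface_area_um2, 4000)
  # anisotropic voxels (organoid raster): areas follow the edge lengths
  o3 <- objectGeometry(pickObjects(m1, 26, voxelUm = c(20, 10, 10)))
  expect_equal(objectStats(o3)$volume_um3, 2000)
  expect_equal(objectStats(o3)$surface_area_um2, 2 * 100 + 4 * 200)
  # face counts equal a brute-force neighbor scan on random masks
  set.seed(22)
  for (rep in 1:5) {
    m <- array(runif(7^3) < 0.3, c(7, 7, 7))
    if (!any(m)) next
    o <- objectGeometry(pickObjects(m, 26, voxelUm = c(20, 10, 10)))
    expect_equal(sum(objectStats(o)$surface_area_um2),
                 surfaceOracle(m, c(20, 10, 10)))
  }
})

test_that("voxelated spheres converge to the analytic sphere", {
  # radius = voxel size, centered on a voxel: center plus 6 face neighbors
  o <- voxelatedSphere(20, c(20, 20, 20))
  expect_equal(objectStats(o)$voxel_count, 7L)
  # 300 um radius at 20 um voxels: volume within 5% of (4/3) pi r^3
  o300 <- voxelatedSphere(300, c(20, 20, 20))
  vol <- objectStats(o300)$volume_um3
  expect_lt(abs(vol - 4 / 3 * pi * 300^3) / (4 / 3 * pi * 300^3), 0.05)
  # relative volume error shrinks monotonically with radius
  errs <- vapply(c(5, 10, 15, 30) * 20, function(r) {
    v <- objectStats(voxelatedSphere(r, c(20, 20, 20)))$volume_um3
    abs(v - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # surface-to-volume ratio error also shrinks with radius
  svErr <- vapply(c(5, 15, 30) * 20, function(r) {
    st <- objectStats(voxelatedSphere(r, c(20, 20, 20)))
    abs(st$surface_area_um2 / st$volume_um3 - 3 / r) / (3 / r)
  }, numeric(1))
  expect_true(all(diff(svErr) < 0))
  expect_error(voxelatedSphere(10, c(20, 20, 20)), "degenerate")
})

test_that("object profiles average member voxels per feature", {
  lab <- array(0L, c(2, 2, 2))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L; lab[1, 2, 2] <- 2L
  dat <- array(0, c(2, 2, 2, 2))
  dat[1, 1, 1, 1] <- 1; dat[2, 1, 1, 1] <- 3
  dat[1, 2, 2, 2] <- 7
  vol <- FeatureVolume(dat, c(20, 20, 20), FeatureAxis(c(100, 200)))
  o <- new("LabeledObjects", labels = lab, voxelUm = c(20, 20, 20),
           stats = data.frame(object_id = 1:2, voxel_count = c(2L, 1L)))
  prof <- objectProfiles(o, vol)
  expect_equal(unname(prof[1, ]), c(2, 0))    # mean of 1 and 3
  expect_equal(unname(prof[2, ]), c(0, 7))    # single-voxel object
  badVol <- FeatureVolume(array(0, c(1, 2, 2, 2)), c(20, 20, 20),
                          FeatureAxis(c(100, 200)))
  expect_error(objectProfiles(o, badVol), "shapes differ")
})

test_that("phantom object profiles recover the planted region means", {
  ph <- generatePhantom(smallPhantomSpec(seed = 7L, maxTransPx = 0,
                                         maxRotDeg = 0))
  vol <- assembleVolume(ph$dataset)
  o <- classifySize(pickObjects(ph$truth@regionVolume == 2L, 26, voxelUm(vol)))
  expect_equal(objectStats(o)$voxel_count,
               ph$truth@objectCatalog$voxel_count)
  expect_equal(objectStats(o)$size_class, ph$truth@objectCatalog$size_class)
  prof <- objectProfiles(o, vol)
  spec <- ph$truth@spec
  ms <- spec@markerSpec[order(spec@markerSpec$mz), ]
  # the fibroblast marker mean is recovered within 3 sd of the object mean
  f <- which(ms$mz == 792.55)
  mean792 <- ms$regionB[f] * exp(spec@textureSigma^2 / 2)  # lognormal mean
  big <- objectStats(o)$voxel_count >= 10
  relErr <- abs(prof[big, f] - mean792) / mean792
  # object-level spread is dominated by the coherent texture field
  expect_lt(median(relErr), 0.6)
  expect_true(all(relErr < 2))
})
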