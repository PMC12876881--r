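# segmentation: preprocessing, thresholding, labelling, watershed, records.

test_that("preprocessing is invariant under positive rescaling", {
  sph <- makeSphereVolume(radius_um = 20, seed = 2)
  v1 <- preprocessVolume(sph$vol)
  v2 <- preprocessVolume(Volume3D(voxels(sph$vol) * 37.5,
                                  voxelSpacing(sph$vol), "OCM", 3L))
  expect_equal(voxels(v1), voxels(v2), tolerance = 1e-12)
  expect_gte(min(voxels(v1)), 0)
  expect_lte(max(voxels(v1)), 1)
  flat <- Volume3D(array(0.7, c(4, 4, 4)), c(1, 1, 1))
  expect_warning(z <- preprocessVolume(flat), "constant")
  expect_true(all(voxels(z) == 0))
})

test_that("a single speckled sphere is segmented with high Dice", {
  sph <- makeSphereVolume(radius_um = 25, seed = 3)
  seg <- segmentOrganoids(preprocessVolume(sph$vol))
  expect_identical(nLabels(seg), 1L)
  expect_gt(diceBest(sph$truth, labelData(seg), 1L), 0.95)
})

test_that("the watershed separates two touching spheres", {
  spacing <- c(2, 2, 2)
  dims <- c(40, 60, 40)
  field <- dims * spacing
  a <- array(0.02, dims)
  truth <- array(0L, dims)
  ctrs <- list(c(40, 36, 40), c(40, 82, 40)) # centres 46 um apart
  r <- 25
  for (i in 1:2) {
    zz <- (seq_len(dims[1]) - 1) * spacing[1]
    yy <- (seq_len(dims[2]) - 1) * spacing[2]
    xx <- (seq_len(dims[3]) - 1) * spacing[3]
    inside <- outer(outer((zz - ctrs[[i]][1])^2, (yy - ctrs[[i]][2])^2, "+"),
                    (xx - ctrs[[i]][3])^2, "+") <= r^2
    a[inside] <- 0.6
    truth[inside & truth == 0L] <- i
  }
  v <- Volume3D(a, spacing, "OCM", 3L)
  seg <- segmentOrganoids(preprocessVolume(v))
  expect_identical(nLabels(seg), 2L)
  expect_gt(diceBest(truth, labelData(seg), 1L), 0.85)
  expect_gt(diceBest(truth, labelData(seg), 2L), 0.85)
})

test_that("filterComponents removes small objects and renumbers by size", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:3, 1:3, 1:3] <- 2L   # 27 voxels
  lab[5, 5, 5:6] <- 1L       # 2 voxels
  m <- LabelMask(lab, c(3, 3, 3), 1L) # voxel volume 27 um3
  f <- filterComponents(m, min_volume_um3 = 100)
  expect_identical(nLabels(f), 1L)
  expect_true(all(labelData(f)[1:3, 1:3, 1:3] == 1L)) # largest renumbered to 1
  expect_identical(sum(labelData(f) == 1L), 27L)
})

test_that("summarizeMask computes volumes, centroids and half-open bboxes", {
  lab <- array(0L, c(5, 6, 7))
  lab[2:3, 3:5, 4:6] <- 1L
  m <- LabelMask(lab, c(2, 3, 4), 9L)
  rec <- summarizeMask(m)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$day, 9L)
  expect_equal(rec$n_voxels, 2L * 3L * 3L)
  expect_equal(rec$volume_um3, 18 * prod(c(2, 3, 4)))
  # centroid of 0-based indices 1..2, 2..4, 3..5 times spacing
  expect_equal(rec$cz, 1.5 * 2)
  expect_equal(rec$cy, 3 * 3)
  expect_equal(rec$cx, 4 * 4)
  expect_equal(c(rec$bbox_z0, rec$bbox_z1), c(1, 3))
  expect_equal(c(rec$bbox_y0, rec$bbox_y1), c(2, 5))
  expect_equal(c(rec$bbox_x0, rec$bbox_x1), c(3, 6))
  empty <- summarizeMask(LabelMask(array(0L, c(2, 2, 2)), c(1, 1, 1)))
  expect_equal(nrow(empty), 0L)
})

test_that("the external-mask backend validates and relabels", {
  sph <- makeSphereVolume(radius_um = 20, seed = 4)
  ext <- array(0L, dim(sph$truth))
  ext[sph$truth == 1L] <- 5L # arbitrary external label id
  seg <- segmentOrganoids(preprocessVolume(sph$vol), backend = "external-mask",
                          mask = ext)
  expect_identical(nLabels(seg), 1L)
  expect_identical(sort(setdiff(unique(as.vector(labelData(seg))), 0L)), 1L)
  expect_error(segmentOrganoids(preprocessVolume(sph$vol),
                                backend = "external-mask"),
               "requires a mask")
  expect_error(segmentOrganoids(preprocessVolume(sph$vol),
                                backend = "external-mask",
                                mask = array(0L, c(2, 2, 2))),
               "shape")
})

test_that("a field with no organoid yields an empty mask", {
  v <- Volume3D(array(abs(rnorm(8000, 0, 1e-4)) + 0.5, c(20, 20, 20)),
                c(1, 1, 1))
  # nearly-constant: Otsu threshold sits inside the noise; after the
  # min-volume filter no component of 500 um3 survives at 1 um3 voxels
  seg <- segmentOrganoids(preprocessVolume(v),
                          params = list(min_volume_um3 = 8000))
  expect_identical(nLabels(seg), 0L)
})

test_that("26-connectivity labelling matches a known configuration", {
  fg <- array(FALSE, c(3, 3, 3))
  fg[1, 1, 1] <- TRUE
  fg[2, 2, 2] <- TRUE  # diagonal neighbour: same component under 26-conn
  fg[3, 3, 3] <- TRUE
  lab <- array(ocpam:::cpp_label26(as.logical(fg), c(3L, 3L, 3L)), c(3, 3, 3))
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 1L)
  fg2 <- array(FALSE, c(1, 3, 3))
  fg2[1, 1, 1] <- TRUE
  fg2[1, 3, 3] <- TRUE # gap of one voxel: two components
  lab2 <- array(ocpam:::cpp_label26(as.logical(fg2), c(1L, 3L, 3L)),
                c(1, 3, 3))
  expect_equal(length(setdiff(unique(as.vector(lab2)), 0L)), 2L)
})

test_that("the squared EDT matches brute force on a random mask", {
  set.seed(12)
  dims <- c(7, 8, 6)
  fg <- array(runif(prod(dims)) < 0.4, dims)
  sp <- c(2, 1, 1.5)
  got <- array(ocpam:::cpp_sqedt(as.logical(fg), as.integer(dims), sp), dims)
  idx_bg <- which(!fg, arr.ind = TRUE)
  if (nrow(idx_bg) && any(fg)) {
    idx_fg <- which(fg, arr.ind = TRUE)
    pos_bg <- t(t(idx_bg - 1) * sp)
    pos_fg <- t(t(idx_fg - 1) * sp)
    for (r in seq_len(nrow(idx_fg))) {
      d2 <- min(colSums((t(pos_bg) - pos_fg[r, ])^2))
      expect_equal(got[idx_fg[r, , drop = FALSE]], d2, tolerance = 1e-9)
    }
    expect_true(all(got[!fg] == 0))
  }
})
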