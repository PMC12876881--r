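# synthetic_data: reproducibility, truth consistency, generator contracts.

test_that("classTrajectory respects class shapes and contracts", {
  expect_equal(classTrajectory("RAPID", 1)[1], 10)
  expect_length(classTrajectory("MEDIUM", 5), 5L)
  expect_length(classTrajectory("WEAK", 8), 8L)
  expect_true(all(classTrajectory("WEAK", 8) > 0))
  # WEAK stays under one decade, MEDIUM in [1, 2), RAPID >= 2 decades
  expect_lt(log10(prod(classTrajectory("WEAK", 5))), 1)
  lmed <- log10(prod(classTrajectory("MEDIUM", 5)))
  expect_gte(lmed, 1)
  expect_lt(lmed, 2)
  expect_gte(log10(prod(classTrajectory("RAPID", 5))), 2)
  expect_error(classTrajectory("DTP", 3), "at least 4 intervals")
  dtp <- classTrajectory("DTP", 7)
  expect_length(dtp, 7L)
  expect_true(any(dtp <= 1.25))    # plateau present
  expect_gt(max(dtp), 5)           # explosive regrowth present
})

test_that("generateOrganoidTimeseries is seed-reproducible", {
  args <- list(n_organoids = 2, days = c(3, 5),
               class_mix = c(RAPID = 0, MEDIUM = 0.5, WEAK = 0.5, DTP = 0),
               field_um = c(100, 260, 260), semiaxes_um = c(8, 11))
  a <- do.call(generateOrganoidTimeseries, c(args, seed = 10))
  b <- do.call(generateOrganoidTimeseries, c(args, seed = 10))
  c3 <- do.call(generateOrganoidTimeseries, c(args, seed = 11))
  expect_identical(voxels(a$volumes[[1]]), voxels(b$volumes[[1]]))
  expect_identical(labelData(a$masks[[2]]), labelData(b$masks[[2]]))
  expect_false(identical(voxels(a$volumes[[1]]), voxels(c3$volumes[[1]])))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateOrganoidTimeseries(
    n_organoids = 1, days = c(3, 5),
    class_mix = c(RAPID = 0, MEDIUM = 1, WEAK = 0, DTP = 0),
    field_um = c(90, 200, 200), semiaxes_um = c(8, 10), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("scene truth is consistent with the rendered masks", {
  sim <- generateOrganoidTimeseries(
    n_organoids = 3, days = c(3, 5, 7),
    class_mix = c(RAPID = 0, MEDIUM = 0.5, WEAK = 0.5, DTP = 0),
    field_um = c(110, 320, 320), semiaxes_um = c(8, 11), seed = 21)
  expect_length(sim$volumes, 3L)
  expect_length(sim$masks, 3L)
  expect_equal(nrow(sim$truth$organoids), 3L)
  expect_true(all(sim$truth$organoids$growth_class %in% c("MEDIUM", "WEAK")))
  expect_equal(dim(sim$truth$relative_volume), c(3L, 3L))
  expect_equal(unname(sim$truth$relative_volume[, 1]), rep(1, 3))
  for (t in 1:3) {
    lab <- labelData(sim$masks[[t]])
    expect_identical(sort(setdiff(unique(as.vector(lab)), 0L)), 1:3)
    # mask voxel volume tracks the truth ellipsoid volume within voxelization
    e <- sim$truth$ellipsoids[sim$truth$ellipsoids$day == sim$truth$days[t], ]
    for (i in 1:3) {
      v_mask <- sum(lab == i) * prod(sim$truth$spacing_um)
      v_true <- 4 / 3 * pi * prod(unlist(e[e$id == i, c("az", "ay", "ax")]))
      expect_lt(abs(v_mask - v_true) / v_true, 0.25)
    }
    # organoid voxels are brighter than the background on average
    a <- voxels(sim$volumes[[t]])
    expect_gt(mean(a[lab > 0]), 5 * mean(a[lab == 0]))
  }
  # relative volumes grow monotonically for these classes
  expect_true(all(diff(t(sim$truth$relative_volume)) > 0))
})

test_that("infeasible scenes and bad mixes error clearly", {
  expect_error(generateOrganoidTimeseries(
    n_organoids = 40, days = c(3, 5),
    class_mix = c(RAPID = 1, MEDIUM = 0, WEAK = 0, DTP = 0),
    field_um = c(60, 100, 100), seed = 1), "field too small")
  expect_error(generateOrganoidTimeseries(
    n_organoids = 1, days = c(3, 5),
    class_mix = c(RAPID = 0.5, MEDIUM = 0.1, WEAK = 0.1, DTP = 0.1),
    field_um = c(100, 200, 200), seed = 1), "sum to 1")
})

test_that("FLM pair renders disjoint live/dead channels matching the truth", {
  sim <- generateOrganoidTimeseries(
    n_organoids = 2, days = c(3, 5),
    class_mix = c(RAPID = 0, MEDIUM = 1, WEAK = 0, DTP = 0),
    field_um = c(100, 260, 260), semiaxes_um = c(9, 12),
    viability_mix = 0.5, seed = 33)
  flm <- generateFlmPair(sim$masks[[1]], sim$truth, seed = 34)
  expect_identical(modality(flm$live), "FLM_LIVE")
  expect_identical(modality(flm$dead), "FLM_DEAD")
  expect_identical(dim(flm$live), dim(sim$masks[[1]]))
  lv <- voxels(flm$live)
  dv <- voxels(flm$dead)
  # per-voxel disjoint: no voxel carries strong signal in both channels
  expect_equal(sum(lv > 0.5 & dv > 0.5), 0L)
  # reproducible
  flm2 <- generateFlmPair(sim$masks[[1]], sim$truth, seed = 34)
  expect_identical(lv, voxels(flm2$live))
  empty <- LabelMask(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(generateFlmPair(empty, seed = 1), "mask is empty")
  expect_error(generateFlmPair(sim$masks[[1]], sim$truth,
                               live_fraction_by_class = c(HIGH = 1.2,
                                                          LOW = 0.1)),
               "live fractions")
})

test_that("spheroid PAM truth matches requested mixing fraction", {
  sp <- generateSpheroidPam(n_cells = 150, melanin_fraction = 0.1, seed = 8)
  expect_identical(modality(sp$ocm), "OCM")
  expect_identical(modality(sp$pam), "PAM")
  expect_identical(dim(sp$ocm), dim(sp$pam))
  expect_equal(nrow(sp$truth$melanin), round(0.1 * nrow(sp$truth$cells)))
  # cells respect the minimum separation of the dart-throwing packing
  d <- as.matrix(dist(sp$truth$cells))
  diag(d) <- Inf
  expect_gte(min(d), 1.6 * 5 - 1e-9)
  # melanin-positive sites carry the brightest PAM signal
  pam <- voxels(sp$pam)
  sp0 <- generateSpheroidPam(n_cells = 150, melanin_fraction = 0, seed = 8)
  expect_gt(max(pam), 10 * max(voxels(sp0$pam)))
  expect_error(generateSpheroidPam(n_cells = 10, melanin_fraction = 2),
               "melanin_fraction")
})

test_that("phantom pair stores its truth and differs across grids", {
  ph <- generatePhantomPair(true_offset_um = c(2, -5, 7),
                            true_scale = c(1, 1.05, 0.95), seed = 3)
  expect_identical(modality(ph$ocm), "PHANTOM")
  expect_identical(modality(ph$pam), "PHANTOM")
  expect_equal(ph$truth$offset_um, c(2, -5, 7))
  expect_equal(ph$truth$scale, c(1, 1.05, 0.95))
  expect_false(identical(voxels(ph$ocm), voxels(ph$pam)))
})

test_that("interferogram obeys the Nyquist depth limit and is reproducible", {
  sf <- generateInterferogram(reflector_depths_um = 80, reflectivities = 1,
                              n_samples = 512, seed = 2)
  expect_length(sf$wavelength_nm, 512L)
  expect_true(all(diff(sf$wavelength_nm) > 0))
  sf2 <- generateInterferogram(reflector_depths_um = 80, reflectivities = 1,
                               n_samples = 512, seed = 2)
  expect_identical(sf$fringes, sf2$fringes)
  expect_error(generateInterferogram(reflector_depths_um = 1e5,
                                     reflectivities = 1, n_samples = 256),
               "Nyquist")
  expect_error(generateInterferogram(reflector_depths_um = c(10, 20),
                                     reflectivities = 1), "length")
})

test_that("texture cohort emits 32 named features per organoid", {
  coh <- generateTextureCohort(n_per_class = 4, seed = 6)
  expect_equal(dim(coh$features), c(8L, 32L))
  expect_identical(colnames(coh$features), featureNames())
  expect_identical(levels(coh$labels), c("LOW", "HIGH"))
  expect_equal(as.vector(table(coh$labels)), c(4L, 4L))
  coh2 <- generateTextureCohort(n_per_class = 4, seed = 6)
  expect_identical(coh$features, coh2$features)
})
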