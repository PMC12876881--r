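# tracking: pair scoring, optimal assignment, chaining, merges.

test_that("scorePair kernels behave as documented", {
  rec <- data.frame(label = 1L, day = 3L, volume_um3 = 1000,
                    cz = 50, cy = 50, cx = 50,
                    bbox_z0 = 18, bbox_z1 = 22, bbox_y0 = 18, bbox_y1 = 22,
                    bbox_x0 = 18, bbox_x1 = 22, n_voxels = 64L)
  s <- scorePair(rec, rec, spacing = c(2.52, 2.52, 2.52))
  expect_equal(s$spatial, 1)
  expect_equal(s$volume, 1)
  expect_equal(s$bbox, 1)
  expect_equal(s$combined, 1)
  far <- rec
  far$cx <- rec$cx + 300
  far$bbox_x0 <- rec$bbox_x0 + 150
  far$bbox_x1 <- rec$bbox_x1 + 150
  s2 <- scorePair(rec, far, spacing = c(2.52, 2.52, 2.52))
  expect_lt(s2$spatial, 1e-6)
  expect_equal(s2$bbox, 0)
  expect_equal(s2$volume, 1)
  # spatial kernel value at distance sigma_d
  near <- rec
  near$cz <- rec$cz + 30
  s3 <- scorePair(rec, near, sigma_d_um = 30, spacing = c(2.52, 2.52, 2.52))
  expect_equal(s3$spatial, exp(-0.5))
  bad <- rec
  bad$volume_um3 <- 0
  expect_error(scorePair(rec, bad), "zero volume")
})

test_that("the Hungarian solver matches brute-force enumeration", {
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n, n)
    got <- ocpam:::.assign_lsap(cost)
    want <- oracleAssign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost,
                 tolerance = 1e-12)
  }
})

test_that("matchDayPair forbids sub-threshold pairs and stays one-to-one", {
  mk <- function(label, cz, vol) data.frame(
    label = label, day = 1L, volume_um3 = vol, cz = cz, cy = 0, cx = 0,
    bbox_z0 = cz - 5, bbox_z1 = cz + 5, bbox_y0 = -5, bbox_y1 = 5,
    bbox_x0 = -5, bbox_x1 = 5, n_voxels = 1L)
  a <- rbind(mk(1L, 0, 1000), mk(2L, 100, 1000))
  b <- rbind(mk(1L, 2, 1100), mk(2L, 102, 1050), mk(3L, 500, 1000))
  m <- matchDayPair(a, b)
  expect_equal(m$pairs$label_a, c(1L, 2L))
  expect_equal(m$pairs$label_b, c(1L, 2L))
  expect_equal(m$unmatched_b, 3L)
  expect_length(m$unmatched_a, 0L)
  expect_true(all(m$pairs$score >= 0.4))
  # no admissible partner at all
  c1 <- mk(1L, 5000, 1000)
  m2 <- matchDayPair(a, c1)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_a, c(1L, 2L))
  expect_equal(m2$unmatched_b, 1L)
})

test_that("buildTracks keeps identities on a well-separated truth series", {
  sim <- generateOrganoidTimeseries(
    n_organoids = 4, days = c(3, 5, 7, 9, 11, 13),
    class_mix = c(RAPID = 0, MEDIUM = 0.5, WEAK = 0.5, DTP = 0),
    field_um = c(180, 600, 600), semiaxes_um = c(8, 12), seed = 19)
  recs <- lapply(sim$truth$days, recordsFromTruth, truth = sim$truth)
  names(recs) <- sim$truth$days
  ts <- buildTracks(recs, spacing = sim$truth$spacing_um)
  expect_equal(ts$reference_day, 7)
  expect_equal(length(unique(ts$entries$track_id)), 4L)
  expect_equal(nrow(ts$entries), 4L * 6L)
  # every track follows a single truth id across all days
  for (id in unique(ts$entries$track_id)) {
    sub <- ts$entries[ts$entries$track_id == id, ]
    expect_equal(length(unique(sub$label)), 1L)
    expect_equal(sort(sub$day), c(3, 5, 7, 9, 11, 13))
  }
  expect_equal(nrow(ts$flags), 0L)
})

test_that("appearing and disappearing organoids are flagged", {
  mk <- function(label, cz, vol, day) data.frame(
    label = label, day = day, volume_um3 = vol, cz = cz, cy = 0, cx = 0,
    bbox_z0 = cz - 5, bbox_z1 = cz + 5, bbox_y0 = -5, bbox_y1 = 5,
    bbox_x0 = -5, bbox_x1 = 5, n_voxels = 1L)
  recs <- list(
    "3" = mk(1L, 0, 1000, 3L),
    "5" = rbind(mk(1L, 2, 1100, 5L), mk(2L, 300, 900, 5L)),
    "7" = mk(1L, 4, 1200, 7L))
  ts <- buildTracks(recs)
  flags <- ts$flags
  t2 <- ts$entries$track_id[ts$entries$label == 2L & ts$entries$day == 5L]
  expect_true(any(flags$track_id == t2 & flags$flag == "APPEARED" &
                    flags$day == 5L))
  expect_true(any(flags$track_id == t2 & flags$flag == "LOST" &
                    flags$day == 7L))
})

test_that("detectMerges flags tracks that fuse into one object", {
  dims <- c(4, 20, 4)
  m0 <- array(0L, dims)
  m0[, 2:6, ] <- 1L
  m0[, 10:14, ] <- 2L
  m1 <- array(0L, dims)
  m1[, 2:14, ] <- 1L # both previous objects now inside one label
  masks <- list("3" = LabelMask(m0, c(1, 1, 1), 3L),
                "5" = LabelMask(m1, c(1, 1, 1), 5L))
  recs <- list("3" = summarizeMask(masks[["3"]]),
               "5" = summarizeMask(masks[["5"]]))
  ts <- buildTracks(recs)
  ts <- detectMerges(ts, masks)
  mi <- ts$flags[ts$flags$flag == "MERGED_INTO", ]
  expect_equal(nrow(mi), 1L)
  expect_equal(mi$day, 5L)
})

test_that("tracksTable joins per-day volumes", {
  mk <- function(label, cz, vol, day) data.frame(
    label = label, day = day, volume_um3 = vol, cz = cz, cy = 0, cx = 0,
    bbox_z0 = cz - 5, bbox_z1 = cz + 5, bbox_y0 = -5, bbox_y1 = 5,
    bbox_x0 = -5, bbox_x1 = 5, n_voxels = 1L)
  recs <- list("3" = mk(1L, 0, 1000, 3L), "5" = mk(1L, 1, 2000, 5L))
  ts <- buildTracks(recs)
  tab <- tracksTable(ts, recs)
  expect_equal(tab$volume_um3[order(tab$day)], c(1000, 2000))
})
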