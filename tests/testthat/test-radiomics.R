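# radiomics: discretization, first-order, GLCM/GLRLM with brute-force oracles.

test_that("featureNames partitions 32 = 9 + 13 + 10", {
  fn <- featureNames()
  expect_length(fn, 32L)
  expect_equal(anyDuplicated(fn), 0L)
})

test_that("the 13 directions cover every unique 3D offset once", {
  d <- ocpam:::.directions13(1L)
  expect_equal(nrow(d), 13L)
  # no direction together with its negation
  key <- apply(d, 1, paste, collapse = ",")
  negkey <- apply(-d, 1, paste, collapse = ",")
  expect_length(intersect(key, negkey), 0L)
  # union with negations covers all 26 neighbour offsets
  expect_length(unique(c(key, negkey)), 26L)
  expect_equal(ocpam:::.directions13(2L), d * 2L)
})

test_that("discretization is equal-width, affine-invariant and clamped", {
  set.seed(41)
  a <- array(runif(125, 10, 50), c(5, 5, 5))
  roi <- array(runif(125) < 0.7, c(5, 5, 5))
  roi[1, 1, 1] <- TRUE
  v <- Volume3D(a, c(1, 1, 1))
  disc <- discretizeROI(v, roi, n_levels = 8)
  lv <- disc$levels
  expect_true(all(lv[!roi] == 0L))
  expect_true(all(lv[roi] >= 1L & lv[roi] <= 8L))
  # extremes land in the first and last bin
  x <- a[roi]
  expect_equal(lv[roi][which.min(x)], 1L)
  expect_equal(lv[roi][which.max(x)], 8L)
  # positive affine transform leaves levels unchanged
  v2 <- Volume3D(a * 3.7 + 12, c(1, 1, 1))
  expect_identical(discretizeROI(v2, roi, 8)$levels, lv)
  # constant ROI maps to level 1
  vc <- Volume3D(array(2, c(3, 3, 3)), c(1, 1, 1))
  dc <- discretizeROI(vc, array(TRUE, c(3, 3, 3)), 8)
  expect_true(all(dc$levels == 1L))
  expect_error(discretizeROI(v, array(FALSE, c(5, 5, 5))), "empty ROI")
})

test_that("first-order features match independent references", {
  set.seed(42)
  a <- array(rlnorm(216, 0, 0.4), c(6, 6, 6))
  roi <- array(runif(216) < 0.8, c(6, 6, 6))
  roi[1:2, 1, 1] <- TRUE
  v <- Volume3D(a, c(1, 1, 1))
  disc <- discretizeROI(v, roi, 16)
  fo <- firstOrderFeatures(disc)
  x <- a[roi]
  expect_equal(unname(fo["Mean"]), mean(x))
  expect_equal(unname(fo["Median"]), median(x))
  expect_equal(unname(fo["Variance"]), mean((x - mean(x))^2))
  expect_equal(unname(fo["Energy"]), sum(x^2))
  expect_equal(unname(fo["Range"]), diff(range(x)))
  expect_equal(unname(fo["Skewness"]),
               e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(unname(fo["Kurtosis"]),
               e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
  p <- tabulate(disc$levels[disc$levels > 0], 16) / length(x)
  p <- p[p > 0]
  expect_equal(unname(fo["Entropy"]), -sum(p * log2(p)))
  expect_equal(unname(fo["Uniformity"]), sum(p^2))
})

test_that("GLCM counts equal brute-force pair enumeration", {
  set.seed(43)
  dirs <- ocpam:::.directions13(1L)
  for (trial in 1:5) {
    lv <- array(sample(0:4, 216, replace = TRUE), c(6, 6, 6))
    counts <- ocpam:::cpp_glcm_counts(as.integer(lv), dim(lv), dirs, 4L)
    for (d in seq_len(nrow(dirs))) {
      want <- oracleGlcm(lv, dirs[d, ], 4L)
      expect_equal(as.matrix(counts[[d]]), want, tolerance = 1e-8)
    }
  }
})

test_that("GLRLM counts equal brute-force run enumeration", {
  set.seed(44)
  dirs <- ocpam:::.directions13(1L)
  for (trial in 1:5) {
    lv <- array(sample(0:3, 216, replace = TRUE), c(6, 6, 6))
    counts <- ocpam:::cpp_glrlm_counts(as.integer(lv), dim(lv), dirs, 3L)
    for (d in seq_len(nrow(dirs))) {
      want <- oracleGlrlm(lv, dirs[d, ], 3L)
      expect_equal(as.matrix(counts[[d]]), want, tolerance = 1e-8)
    }
  }
})

test_that("GLCM features match hand-computed values on a tiny ROI", {
  # one row of levels 1,1,2 along x; single direction checks via the oracle
  lv <- array(0L, c(1, 1, 3))
  lv[1, 1, ] <- c(1L, 1L, 2L)
  counts <- ocpam:::cpp_glcm_counts(as.integer(lv), dim(lv),
                                    matrix(c(0L, 0L, 1L), 1), 2L)
  m <- as.matrix(counts[[1]])
  expect_equal(m, matrix(c(2, 1, 1, 0), 2, 2)) # pairs (1,1), (1,2)+(2,1)
  P <- m / sum(m)
  f <- ocpam:::.glcmFromP(P)
  expect_equal(unname(f[5]), sum(outer(1:2, 1:2, function(i, j)
    (i - j)^2) * P)) # Contrast
  expect_equal(unname(f[3]), sum(P^2)) # Joint Energy
})

test_that("GLRLM features match hand-computed values on a tiny ROI", {
  lv <- array(0L, c(1, 1, 5))
  lv[1, 1, ] <- c(1L, 1L, 2L, 2L, 2L)
  counts <- ocpam:::cpp_glrlm_counts(as.integer(lv), dim(lv),
                                     matrix(c(0L, 0L, 1L), 1), 2L)
  m <- as.matrix(counts[[1]])
  expect_equal(m[1, 2], 1) # one run of level 1, length 2
  expect_equal(m[2, 3], 1) # one run of level 2, length 3
  expect_equal(sum(m), 2)
  f <- ocpam:::.glrlmFromCounts(m, n_voxels = 5)
  # SRE = sum_j r_j / j^2 / Nr = (1/4 + 1/9) / 2
  expect_equal(unname(f[1]), (1 / 4 + 1 / 9) / 2)
  # RP = Nr / Np = 2 / 5
  expect_equal(unname(f[6]), 2 / 5)
})

test_that("extractFeatureVector emits 32 finite named features", {
  set.seed(45)
  a <- array(rlnorm(1000, 0, 0.3), c(10, 10, 10))
  lab <- array(0L, c(10, 10, 10))
  lab[3:8, 3:8, 3:8] <- 1L
  v <- Volume3D(a, c(1, 1, 1))
  m <- LabelMask(lab, c(1, 1, 1), 3L)
  fv <- extractFeatureVector(v, m, 1L)
  expect_length(fv, 32L)
  expect_identical(names(fv), featureNames())
  expect_true(all(is.finite(fv)))
  expect_error(extractFeatureVector(v, m, 2L), "not present")
  small <- LabelMask(array(c(rep(1L, 8), rep(0L, 992)), c(10, 10, 10)),
                     c(1, 1, 1))
  expect_error(extractFeatureVector(v, small, 1L), "smaller than")
  tab <- extractFeatureTable(v, m)
  expect_equal(nrow(tab), 1L)
  expect_identical(names(tab), c("label", "day", featureNames()))
})

test_that("features separate the two synthetic texture regimes", {
  coh <- generateTextureCohort(n_per_class = 6, seed = 46)
  hi <- coh$features[coh$labels == "HIGH", "Mean"]
  lo <- coh$features[coh$labels == "LOW", "Mean"]
  expect_gt(min(hi), max(lo)) # regimes differ in mean backscatter
})
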