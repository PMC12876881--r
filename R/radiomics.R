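# Radiomics texture extraction: 9 first-order, 13 grey-level co-occurrence
# (GLCM) and 10 grey-level run-length (GLRLM) features per organoid ROI,
# computed in 3D on the original (non-preprocessed) OCM intensities over the
# 13 unique 3D directions, direction-averaged. Feature definitions follow
# the standard radiomics conventions for these families.

.FIRST_ORDER_NAMES <- c("Mean", "Median", "Variance", "Skewness", "Kurtosis",
                        "Energy", "Entropy", "Uniformity", "Range")
.GLCM_NAMES <- c("Autocorrelation", "Joint Average", "Joint Energy",
                 "Joint Entropy", "Contrast", "Correlation",
                 "Inverse Difference Moment", "Sum Average", "Sum Entropy",
                 "Difference Entropy", "Difference Variance",
                 "Sum of Squares", "Cluster Tendency")
.GLRLM_NAMES <- c("Short Run Emphasis", "Long Run Emphasis",
                  "Gray Level Non-Uniformity", "Run Length Non-Uniformity",
                  "Run Length Non-Uniformity Normalized", "Run Percentage",
                  "Low Gray Level Run Emphasis",
                  "High Gray Level Run Emphasis", "Gray Level Variance",
                  "Run Entropy")

#' Names of the 32 texture features, in extraction order
#'
#' @return Character vector: 9 first-order, then 13 GLCM, then 10 GLRLM
#'   feature names.
#' @export
featureNames <- function() c(.FIRST_ORDER_NAMES, .GLCM_NAMES, .GLRLM_NAMES)

# the 13 unique 3D offsets (one per direction up to sign): all (dz, dy, dx)
# in {-1,0,1}^3 \ {0} whose first non-zero component is positive
.directions13 <- function(distance = 1L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  keep <- apply(g[, c("dz", "dy", "dx")], 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  m <- as.matrix(g[keep, c("dz", "dy", "dx")])
  dimnames(m) <- NULL
  m * as.integer(distance)
}

#' Discretize an ROI to a fixed number of grey levels
#'
#' Equal-width binning of the in-ROI intensities from the ROI minimum to the
#' ROI maximum into \code{n_levels} levels (1..n_levels). The binning is
#' invariant under positive affine transforms of the ROI intensities. A
#' constant ROI maps every voxel to level 1.
#'
#' @param vol a \linkS4class{Volume3D} (the original, non-preprocessed
#'   intensities).
#' @param roi logical array marking the ROI, same shape as \code{vol}.
#' @param n_levels number of grey levels (>= 2), default 32.
#' @return A \code{DiscretizedROI}: list with \code{levels} (integer array,
#'   0 outside the ROI), \code{n_levels}, \code{roi} and \code{raw} (the
#'   in-ROI raw intensities, in array order).
#' @export
discretizeROI <- function(vol, roi, n_levels = 32) {
  stopifnot(n_levels >= 2)
  a <- voxels(vol)
  stopifnot(identical(dim(a), dim(roi)))
  idx <- which(roi)
  if (!length(idx)) stop("empty ROI")
  x <- a[idx]
  lv <- array(0L, dim(a))
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    lv[idx] <- 1L
  } else {
    b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L
    lv[idx] <- pmin(as.integer(b), as.integer(n_levels))
  }
  structure(list(levels = lv, n_levels = as.integer(n_levels),
                 roi = roi, raw = x),
            class = "DiscretizedROI")
}

#' First-order (histogram) features of an ROI
#'
#' Mean, Median, Variance (population), Skewness, Kurtosis (non-excess),
#' Energy (sum of squared intensities) and Range are computed on the raw
#' in-ROI intensities; Entropy (base 2) and Uniformity on the discretized
#' level histogram.
#'
#' @param disc a \code{DiscretizedROI} from [discretizeROI()].
#' @return Named numeric vector of the 9 first-order features.
#' @export
firstOrderFeatures <- function(disc) {
  x <- disc$raw
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  pl <- tabulate(disc$levels[disc$levels > 0L], nbins = disc$n_levels) / n
  pl <- pl[pl > 0]
  out <- c(mu, stats::median(x), m2, skew, kurt, sum(x^2),
           -sum(pl * log2(pl)), sum(pl^2), diff(range(x)))
  names(out) <- .FIRST_ORDER_NAMES
  out
}

# the 13 GLCM features from one normalized symmetric co-occurrence matrix
.glcmFromP <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P) # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), numeric(1))
  kk_sum <- 2:(2 * ng)
  pxy_dif <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]),
                    numeric(1))
  kk_dif <- 0:(ng - 1)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  autoc <- sum(i * j * P)
  da <- sum(kk_dif * pxy_dif)
  c(autoc,
    sum(i * P),                                   # Joint Average
    sum(P^2),                                     # Joint Energy
    ent(P),                                       # Joint Entropy
    sum((i - j)^2 * P),                           # Contrast
    if (sig2 > 0) (autoc - mu^2) / sig2 else 1,   # Correlation
    sum(pxy_dif / (1 + kk_dif^2)),                # Inverse Difference Moment
    sum(kk_sum * pxy_sum),                        # Sum Average
    ent(pxy_sum),                                 # Sum Entropy
    ent(pxy_dif),                                 # Difference Entropy
    sum((kk_dif - da)^2 * pxy_dif),               # Difference Variance
    sum((i - mu)^2 * P),                          # Sum of Squares
    sum((i + j - 2 * mu)^2 * P))                  # Cluster Tendency
}

#' Grey-level co-occurrence features of an ROI
#'
#' For each of the 13 unique 3D directions at the given voxel distance,
#' counts symmetric co-occurrences between in-ROI voxel pairs, normalizes to
#' a probability matrix and computes the 13 named features; the mean over
#' directions with at least one valid pair is returned.
#'
#' @param disc a \code{DiscretizedROI}.
#' @param distance offset length in voxels (default 1).
#' @return Named numeric vector of the 13 GLCM features.
#' @export
glcmFeatures <- function(disc, distance = 1) {
  dirs <- .directions13(distance)
  counts <- cpp_glcm_counts(as.integer(disc$levels), dim(disc$levels), dirs,
                            disc$n_levels)
  vals <- lapply(counts, function(m) {
    s <- sum(m)
    if (s == 0) return(NULL)
    .glcmFromP(m / s)
  })
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!length(vals)) stop("no valid co-occurrence pairs in any direction")
  out <- Reduce(`+`, vals) / length(vals)
  names(out) <- .GLCM_NAMES
  out
}

# the 10 GLRLM features from one run-length count matrix (levels x lengths)
.glrlmFromCounts <- function(M, n_voxels) {
  nr <- sum(M)
  if (nr == 0) return(rep(NA_real_, 10))
  ii <- seq_len(nrow(M))
  jj <- seq_len(ncol(M))
  ri <- rowSums(M)
  rj <- colSums(M)
  p <- M / nr
  mu_g <- sum(ii * rowSums(p))
  pe <- p[p > 0]
  c(sum(rj / jj^2) / nr,              # Short Run Emphasis
    sum(rj * jj^2) / nr,              # Long Run Emphasis
    sum(ri^2) / nr,                   # Gray Level Non-Uniformity
    sum(rj^2) / nr,                   # Run Length Non-Uniformity
    sum(rj^2) / nr^2,                 # Run Length Non-Uniformity Normalized
    nr / n_voxels,                    # Run Percentage
    sum(ri / ii^2) / nr,              # Low Gray Level Run Emphasis
    sum(ri * ii^2) / nr,              # High Gray Level Run Emphasis
    sum(p * outer((ii - mu_g)^2, rep(1, ncol(M)))), # Gray Level Variance
    -sum(pe * log2(pe)))              # Run Entropy
}

#' Grey-level run-length features of an ROI
#'
#' For each of the 13 unique 3D directions, counts maximal runs of equal
#' level along in-ROI lines (runs break at the ROI boundary), builds the
#' grey-level by run-length count matrix and computes the 10 named features;
#' the mean over directions is returned.
#'
#' @param disc a \code{DiscretizedROI}.
#' @return Named numeric vector of the 10 GLRLM features.
#' @export
glrlmFeatures <- function(disc) {
  dirs <- .directions13(1L)
  counts <- cpp_glrlm_counts(as.integer(disc$levels), dim(disc$levels), dirs,
                             disc$n_levels)
  nvox <- sum(disc$levels > 0L)
  vals <- lapply(counts, .glrlmFromCounts, n_voxels = nvox)
  vals <- vals[!vapply(vals, function(v) any(is.na(v)), logical(1))]
  if (!length(vals)) stop("empty ROI")
  out <- Reduce(`+`, vals) / length(vals)
  names(out) <- .GLRLM_NAMES
  out
}

#' Extract the 32-feature texture vector of one organoid
#'
#' Concatenates the first-order, GLCM and GLRLM blocks, in that fixed order,
#' computed on the original (non-preprocessed) OCM intensities restricted to
#' the organoid's mask label.
#'
#' @param vol the original \linkS4class{Volume3D} (OCM modality).
#' @param mask a \linkS4class{LabelMask} aligned to \code{vol}.
#' @param label the organoid label to extract.
#' @param params list overriding the \code{radiomics} group of
#'   [defaultConfig()] (\code{n_levels}, \code{distance},
#'   \code{min_roi_voxels}).
#' @return Named numeric vector of exactly 32 finite values; names from
#'   [featureNames()].
#' @export
extractFeatureVector <- function(vol, mask, label, params = list()) {
  p <- utils::modifyList(defaultConfig()$radiomics, params)
  roi <- labelData(mask) == label
  nvox <- sum(roi)
  if (nvox == 0L) stop("label ", label, " not present in mask")
  if (nvox < p$min_roi_voxels)
    stop("ROI smaller than ", p$min_roi_voxels, " voxels")
  disc <- discretizeROI(vol, roi, p$n_levels)
  out <- c(firstOrderFeatures(disc), glcmFeatures(disc, p$distance),
           glrlmFeatures(disc))
  stopifnot(length(out) == 32L, all(is.finite(out)))
  out
}

#' Texture feature table for every organoid of a scene
#'
#' @param vol the original \linkS4class{Volume3D}.
#' @param mask a \linkS4class{LabelMask}.
#' @param params list overriding the \code{radiomics} group of
#'   [defaultConfig()].
#' @return data.frame with \code{label}, \code{day} and the 32 feature
#'   columns; organoids below the minimum ROI size are skipped.
#' @export
extractFeatureTable <- function(vol, mask, params = list()) {
  p <- utils::modifyList(defaultConfig()$radiomics, params)
  lab <- labelData(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- list()
  for (id in ids) {
    if (sum(lab == id) < p$min_roi_voxels) next
    fv <- extractFeatureVector(vol, mask, id, params)
    fd <- as.data.frame(t(fv))
    names(fd) <- names(fv) # keep the canonical names (with spaces)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(label = id, day = acqDay(mask)), fd)
  }
  if (!length(rows)) stop("no organoid meets the minimum ROI size")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
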