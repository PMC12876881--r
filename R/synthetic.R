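# Synthetic-data generators. Every generator takes an explicit seed and is
# bit-reproducible; together they emulate the imaging conditions of the
# longitudinal organoid study: speckled ellipsoidal organoids with
# class-dependent growth trajectories and texture, paired live/dead
# fluorescence renderings, mixed spheroids with sparse melanin-positive
# cells, a gold-coated pyramid phantom pair, and spectral interferograms.

.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.GROWTH_CLASSES <- c("RAPID", "MEDIUM", "WEAK", "DTP")

#' Per-interval fold-changes for a growth class
#'
#' Default trajectories reproduce the qualitative growth regimes seen in
#' longitudinally imaged organoids: RAPID organoids gain roughly ten-fold
#' between the first two imaging days and reach two to three decades of
#' relative volume; MEDIUM organoids stay between one and two decades; WEAK
#' organoids remain under one decade; DTP (drug-tolerant persister)
#' trajectories grow, stall for several intervals (fold-change near 1) and
#' then regrow explosively to beyond three decades.
#'
#' @param class one of \code{"RAPID"}, \code{"MEDIUM"}, \code{"WEAK"},
#'   \code{"DTP"}.
#' @param n_intervals number of imaging intervals (days minus one).
#' @return Numeric vector of \code{n_intervals} fold-changes, all > 0.
#' @export
classTrajectory <- function(class, n_intervals) {
  class <- match.arg(class, .GROWTH_CLASSES)
  if (class == "DTP") {
    if (n_intervals < 4)
      stop("a DTP trajectory needs at least 4 intervals ",
           "(growth, >=2 plateau, regrowth)")
    n_grow <- if (n_intervals >= 6) 2L else 1L
    n_plateau <- if (n_intervals >= 7) 3L else 2L
    n_regrow <- n_intervals - n_grow - n_plateau
    grow <- c(8, 3)[seq_len(n_grow)]
    plateau <- rep(1.05, n_plateau)
    regrow <- rep(c(10, 8, 5, 2), length.out = n_regrow)
    return(c(grow, plateau, regrow))
  }
  base <- switch(class,
    RAPID  = c(10, 5, 5, 2, 1.5),
    MEDIUM = c(4, 2.5, 2, 1.8, 1.3),
    WEAK   = c(1.8, 1.5, 1.3, 1.2, 1.1))
  ext <- switch(class, RAPID = 1.5, MEDIUM = 1.2, WEAK = 1.05)
  if (n_intervals <= length(base)) base[seq_len(n_intervals)]
  else c(base, rep(ext, n_intervals - length(base)))
}

# multiplicative Rayleigh speckle with a controllable correlation length;
# normalized to unit mean so the class base intensity is preserved
.speckleField <- function(dims, corr_sigma_vox) {
  u <- stats::runif(prod(dims))
  r <- sqrt(-2 * log(pmax(u, 1e-12)))
  if (corr_sigma_vox > 0)
    r <- cpp_gauss3(r, as.integer(dims), rep(corr_sigma_vox, 3))
  array(r / mean(r), dims)
}

# texture regimes used for the two viability classes: higher backscatter and
# longer speckle correlation for viable tissue, dimmer and finer for dying
.TEXTURE_REGIMES <- list(
  HIGH = list(base = 0.55, corr_sigma = 1.6),
  LOW  = list(base = 0.32, corr_sigma = 0.6)
)

# indices (1-based array subscripts) of voxels inside an ellipsoid
.ellipsoidVoxels <- function(dims, spacing, center, semi) {
  lo <- pmax(1L, floor((center - semi) / spacing) + 1L)
  hi <- pmin(dims, ceiling((center + semi) / spacing) + 1L)
  if (any(lo > hi)) return(NULL)
  zz <- ((lo[1]:hi[1]) - 1) * spacing[1]
  yy <- ((lo[2]:hi[2]) - 1) * spacing[2]
  xx <- ((lo[3]:hi[3]) - 1) * spacing[3]
  a2 <- ((zz - center[1]) / semi[1])^2
  b2 <- ((yy - center[2]) / semi[2])^2
  c2 <- ((xx - center[3]) / semi[3])^2
  inside <- outer(outer(a2, b2, "+"), c2, "+") <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cbind(idx[, 1] + lo[1] - 1L, idx[, 2] + lo[2] - 1L, idx[, 3] + lo[3] - 1L)
}

#' Generate a longitudinal organoid OCM series with ground truth
#'
#' Places \code{n_organoids} ellipsoidal organoids in the field of view,
#' assigns each a growth class (with per-interval fold-changes jittered
#' log-normally around the class trajectory) and a viability class that
#' selects its speckle texture regime, and renders one speckled OCM volume
#' and one true label mask per imaging day. Organoid centres drift slowly
#' between days; volumes follow the trajectory via the ellipsoid semi-axes.
#'
#' @param n_organoids number of organoids (>= 1).
#' @param days ordered integer imaging days (>= 2 days). Default mirrors
#'   imaging every second day from day 3 to day 13.
#' @param class_mix named probabilities over the four growth classes,
#'   summing to 1.
#' @param field_um physical field of view \code{(z, y, x)} in micrometres.
#' @param spacing_um voxel spacing in micrometres (default 2.52, the
#'   longitudinal imaging step size).
#' @param viability_mix probability that an organoid is of the HIGH-viability
#'   texture regime.
#' @param semiaxes_um range (min, max) of initial mean semi-axes in
#'   micrometres; per-axis eccentricity is drawn within 25%.
#' @param drift_um_per_day standard deviation of the per-day centre drift.
#' @param fold_jitter_sdlog log-normal jitter applied to each fold-change.
#' @param seed integer seed.
#' @return A list with \code{volumes} (per-day \linkS4class{Volume3D}),
#'   \code{masks} (per-day \linkS4class{LabelMask} ground truth) and
#'   \code{truth}, a \code{SceneTruth} list holding per-organoid classes and
#'   per-day ellipsoid geometry.
#' @export
generateOrganoidTimeseries <- function(n_organoids,
                                       days = c(3, 5, 7, 9, 11, 13),
                                       class_mix = c(RAPID = 0.25,
                                                     MEDIUM = 0.35,
                                                     WEAK = 0.30,
                                                     DTP = 0.10),
                                       field_um = c(150, 600, 600),
                                       spacing_um = c(2.52, 2.52, 2.52),
                                       viability_mix = 0.5,
                                       semiaxes_um = c(12, 18),
                                       drift_um_per_day = 1.5,
                                       fold_jitter_sdlog = 0.06,
                                       seed = 1) {
  stopifnot(n_organoids >= 1, length(days) >= 2, !is.unsorted(days))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  .withSeed(seed, {
    n_int <- length(days) - 1L
    cls <- sample(names(class_mix), n_organoids, replace = TRUE,
                  prob = class_mix)
    viab <- ifelse(stats::runif(n_organoids) < viability_mix, "HIGH", "LOW")
    folds <- lapply(cls, function(cl) {
      f <- classTrajectory(cl, n_int)
      f * stats::rlnorm(n_int, 0, fold_jitter_sdlog)
    })
    relvol <- lapply(folds, function(f) c(1, cumprod(f)))

    # initial geometry; semi-axes grow with the cube root of relative volume
    mean_semi <- stats::runif(n_organoids, semiaxes_um[1], semiaxes_um[2])
    ecc <- matrix(stats::runif(3 * n_organoids, 0.8, 1.25), n_organoids, 3)
    semi0 <- mean_semi * ecc / rowMeans(ecc)^(1) # (n x 3), um at day 1
    final_semi <- semi0 * vapply(relvol, function(r) r[length(r)]^(1 / 3),
                                 numeric(1))
    max_final <- apply(final_semi, 1, max)

    # total drift budget over the series
    drift_margin <- drift_um_per_day * (max(days) - min(days))

    # rejection-sample non-overlapping centres that stay in the field
    centers <- matrix(NA_real_, n_organoids, 3)
    order_big <- order(max_final, decreasing = TRUE)
    for (i in order_big) {
      margin <- pmin(final_semi[i, ] + drift_margin + 2, field_um / 2)
      ok <- FALSE
      for (try in seq_len(4000L)) {
        cand <- stats::runif(3, margin, field_um - margin)
        prev <- which(!is.na(centers[, 1]))
        if (length(prev)) {
          d <- sqrt(colSums((t(centers[prev, , drop = FALSE]) - cand)^2))
          req <- max_final[prev] + max_final[i] + 2 * drift_margin + 4
          if (any(d < req)) next
        }
        centers[i, ] <- cand
        ok <- TRUE
        break
      }
      if (!ok) stop("field too small for requested organoid count at final day")
    }

    dims <- as.integer(round(field_um / spacing_um))
    drift <- array(stats::rnorm(n_organoids * 3 * n_int, 0,
                                drift_um_per_day * mean(diff(days)) /
                                  sqrt(3)),
                   c(n_organoids, 3, n_int))

    volumes <- vector("list", length(days))
    masks <- vector("list", length(days))
    ell <- list()
    for (t in seq_along(days)) {
      vol <- array(0.02 + 0.015 * abs(stats::rnorm(prod(dims))), dims)
      lab <- array(0L, dims)
      spk <- list(HIGH = .speckleField(dims, .TEXTURE_REGIMES$HIGH$corr_sigma),
                  LOW = .speckleField(dims, .TEXTURE_REGIMES$LOW$corr_sigma))
      for (i in seq_len(n_organoids)) {
        ctr <- centers[i, ]
        if (t > 1) ctr <- ctr + rowSums(drift[i, , seq_len(t - 1), drop = FALSE])
        semi <- semi0[i, ] * relvol[[i]][t]^(1 / 3)
        if (any(ctr - semi < 0) || any(ctr + semi > field_um))
          stop("field too small for requested organoid count at final day")
        vx <- .ellipsoidVoxels(dims, spacing_um, ctr, semi)
        if (is.null(vx)) next
        base <- .TEXTURE_REGIMES[[viab[i]]]$base
        vol[vx] <- base * spk[[viab[i]]][vx]
        lab[vx] <- i
        ell[[length(ell) + 1L]] <- data.frame(
          id = i, day = days[t], cz = ctr[1], cy = ctr[2], cx = ctr[3],
          az = semi[1], ay = semi[2], ax = semi[3])
      }
      volumes[[t]] <- Volume3D(vol, spacing_um, "OCM", days[t])
      masks[[t]] <- LabelMask(lab, spacing_um, days[t])
    }
    truth <- structure(list(
      organoids = data.frame(id = seq_len(n_organoids), growth_class = cls,
                             viability_class = viab, texture_regime = viab,
                             stringsAsFactors = FALSE),
      ellipsoids = do.call(rbind, ell),
      relative_volume = do.call(rbind, lapply(relvol, rbind)),
      days = days, spacing_um = spacing_um, field_um = field_um),
      class = "SceneTruth")
    list(volumes = volumes, masks = masks, truth = truth)
  })
}

# additive rendering of a Gaussian blob into `img` around a voxel index
.addBlob <- function(img, center_idx, sigma_vox, amp) {
  dims <- dim(img)
  r <- ceiling(3 * sigma_vox)
  lo <- pmax(1L, center_idx - r)
  hi <- pmin(dims, center_idx + r)
  zz <- (lo[1]:hi[1]) - center_idx[1]
  yy <- (lo[2]:hi[2]) - center_idx[2]
  xx <- (lo[3]:hi[3]) - center_idx[3]
  g <- amp * exp(-outer(outer(zz^2, yy^2, "+"), xx^2, "+") /
                   (2 * sigma_vox^2))
  img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + g
  img
}

#' Generate a paired live/dead fluorescence rendering for a labelled scene
#'
#' Cells are seeded uniformly inside each organoid; each cell is live with
#' the probability assigned to its organoid's viability class and rendered
#' as a bright Gaussian blob in the corresponding channel (acridine
#' orange-like live channel, propidium iodide-like dead channel). The two
#' channels are made spatially disjoint per voxel: where renderings overlap,
#' the brighter channel keeps the voxel.
#'
#' @param mask a \linkS4class{LabelMask} of the scene.
#' @param truth the \code{SceneTruth} of the scene (for viability classes);
#'   may be \code{NULL}, in which case \code{live_fraction_by_class["HIGH"]}
#'   applies to all organoids.
#' @param live_fraction_by_class named vector of live-cell probabilities per
#'   viability class, values in [0, 1].
#' @param cells_per_1000_voxels seeded cell density.
#' @param blob_sigma_vox Gaussian blob radius in voxels.
#' @param seed integer seed.
#' @return A list with \code{live} and \code{dead} \linkS4class{Volume3D}
#'   channels (modalities \code{FLM_LIVE} / \code{FLM_DEAD}).
#' @export
generateFlmPair <- function(mask, truth = NULL,
                            live_fraction_by_class = c(HIGH = 0.9, LOW = 0.15),
                            cells_per_1000_voxels = 10,
                            blob_sigma_vox = 1.2,
                            seed = 1) {
  if (any(live_fraction_by_class < 0 | live_fraction_by_class > 1))
    stop("live fractions must lie in [0, 1]")
  lab <- labelData(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) stop("mask is empty")
  .withSeed(seed, {
    dims <- dim(lab)
    live <- array(0, dims)
    dead <- array(0, dims)
    for (id in ids) {
      cl <- "HIGH"
      if (!is.null(truth)) {
        row <- match(id, truth$organoids$id)
        if (!is.na(row)) cl <- truth$organoids$viability_class[row]
      }
      lf <- unname(live_fraction_by_class[cl])
      vox <- which(lab == id)
      n_cells <- max(1L, round(length(vox) * cells_per_1000_voxels / 1000))
      ctrs <- sample(vox, min(n_cells, length(vox)))
      is_live <- stats::runif(length(ctrs)) < lf
      for (j in seq_along(ctrs)) {
        ci <- arrayInd(ctrs[j], dims)[1, ]
        amp <- stats::rnorm(1, 0.9, 0.05)
        if (is_live[j]) live <- .addBlob(live, ci, blob_sigma_vox, amp)
        else dead <- .addBlob(dead, ci, blob_sigma_vox, amp)
      }
    }
    both <- live > 0.02 & dead > 0.02
    keep_live <- live >= dead
    live[both & !keep_live] <- 0
    dead[both & keep_live] <- 0
    noise <- function() array(abs(stats::rnorm(prod(dims), 0.02, 0.008)), dims)
    live <- pmax(live, noise())
    dead <- pmax(dead, noise())
    list(live = Volume3D(live, voxelSpacing(mask), "FLM_LIVE", acqDay(mask)),
         dead = Volume3D(dead, voxelSpacing(mask), "FLM_DEAD", acqDay(mask)))
  })
}

#' Generate a mixed spheroid imaged by OCM and PAM
#'
#' Cells are packed into a sphere with a minimum-separation dart-throwing
#' scheme; a fraction of them carries melanin. The OCM channel shows the
#' whole speckled spheroid; the PAM channel shows Gaussian amplitude blobs
#' only at melanin-positive cell centres, with per-cell amplitude
#' proportional to a log-normal melanin load. A zero fraction leaves the PAM
#' channel at the noise floor.
#'
#' @param melanin_fraction fraction of melanin-positive cells in [0, 1]
#'   (the mixing experiments use 0, 0.01, 0.2 and 1).
#' @param n_cells number of cells (>= 1).
#' @param spacing_um voxel spacing (default 0.84, the spheroid-mode step).
#' @param cell_radius_um nominal cell radius.
#' @param pam_sigma_um Gaussian PAM blob radius.
#' @param noise_floor PAM background noise scale.
#' @param seed integer seed.
#' @return A list with \code{ocm} and \code{pam} \linkS4class{Volume3D}
#'   volumes and \code{truth} (spheroid geometry, all cell centres and the
#'   melanin-positive subset with loads).
#' @export
generateSpheroidPam <- function(melanin_fraction, n_cells = 1000,
                                spacing_um = c(0.84, 0.84, 0.84),
                                cell_radius_um = 5,
                                pam_sigma_um = 2.5,
                                noise_floor = 0.005,
                                seed = 1) {
  stopifnot(n_cells >= 1, melanin_fraction >= 0, melanin_fraction <= 1)
  .withSeed(seed, {
    packing <- 0.3
    radius <- cell_radius_um * (n_cells / packing)^(1 / 3)
    margin <- 4 * pam_sigma_um + 6
    field <- rep(2 * (radius + margin), 3)
    ctr <- field / 2
    dims <- as.integer(round(field / spacing_um))

    # dart-throwing with minimum centre separation of 1.6 cell radii
    min_sep2 <- (1.6 * cell_radius_um)^2
    centers <- matrix(NA_real_, n_cells, 3)
    n_placed <- 0L
    tries <- 0L
    while (n_placed < n_cells && tries < 200L * n_cells) {
      tries <- tries + 1L
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cand <- ctr + u * (radius - cell_radius_um)
      if (n_placed > 0L) {
        d2 <- colSums((t(centers[seq_len(n_placed), , drop = FALSE]) - cand)^2)
        if (any(d2 < min_sep2)) next
      }
      n_placed <- n_placed + 1L
      centers[n_placed, ] <- cand
    }
    centers <- centers[seq_len(n_placed), , drop = FALSE]

    n_pos <- round(melanin_fraction * nrow(centers))
    pos_idx <- if (n_pos > 0) sample(nrow(centers), n_pos) else integer(0)
    load <- stats::rlnorm(length(pos_idx), 0, 0.15)

    # OCM: speckled spheroid
    ocm <- array(0.02 + 0.015 * abs(stats::rnorm(prod(dims))), dims)
    spk <- .speckleField(dims, .TEXTURE_REGIMES$HIGH$corr_sigma)
    vx <- .ellipsoidVoxels(dims, spacing_um, ctr, rep(radius, 3))
    ocm[vx] <- .TEXTURE_REGIMES$HIGH$base * spk[vx]

    # PAM: blobs at melanin-positive centres over a noise floor
    pam <- array(abs(stats::rnorm(prod(dims), 0, noise_floor)), dims)
    if (length(pos_idx)) {
      sig_vox <- pam_sigma_um / mean(spacing_um)
      for (j in seq_along(pos_idx)) {
        ci <- pmin(dims, pmax(1L, as.integer(round(
          centers[pos_idx[j], ] / spacing_um)) + 1L))
        pam <- .addBlob(pam, ci, sig_vox, load[j])
      }
    }
    truth <- structure(list(
      spheroid_center_um = ctr, spheroid_radius_um = radius,
      cells = data.frame(cz = centers[, 1], cy = centers[, 2],
                         cx = centers[, 3]),
      melanin = data.frame(cz = centers[pos_idx, 1], cy = centers[pos_idx, 2],
                           cx = centers[pos_idx, 3], load = load),
      melanin_fraction = melanin_fraction, spacing_um = spacing_um),
      class = "SceneTruth")
    list(ocm = Volume3D(ocm, spacing_um, "OCM"),
         pam = Volume3D(pam, spacing_um, "PAM"),
         truth = truth)
  })
}

#' Generate a gold-coated pyramid phantom pair for fusion calibration
#'
#' Renders the same pyramid surface shell in an OCM grid and in a PAM grid
#' whose physical coordinates map into the OCM frame as
#' \code{ocm = scale * pam + offset}, plus independent sensor noise in each
#' copy. Used to validate [calibrateFusion()] recovery.
#'
#' @param true_offset_um per-axis \code{(z, y, x)} offset in micrometres.
#' @param true_scale per-axis scale factors, > 0.
#' @param base_um pyramid base width.
#' @param height_um pyramid height.
#' @param spacing_um voxel spacing of both grids.
#' @param noise_sd additive noise scale.
#' @param seed integer seed.
#' @return List with \code{ocm}, \code{pam} (\linkS4class{Volume3D},
#'   modality \code{PHANTOM}) and \code{truth} (offset and scale).
#' @export
generatePhantomPair <- function(true_offset_um = c(0, 0, 0),
                                true_scale = c(1, 1, 1),
                                base_um = 200, height_um = 60,
                                spacing_um = c(2, 2, 2),
                                noise_sd = 0.01, seed = 1) {
  stopifnot(all(true_scale > 0))
  .withSeed(seed, {
    field <- c(height_um + 50, base_um * 1.4, base_um * 1.4)
    dims <- as.integer(round(field / spacing_um))
    cy <- field[2] / 2
    cx <- field[3] / 2
    z_apex <- 15
    shell_sigma <- 2.5

    surf_z <- function(y, x) {
      h <- pmax(0, height_um * (1 - pmax(abs(y - cy), abs(x - cx)) /
                                  (base_um / 2)))
      z_apex + (height_um - h)
    }
    render <- function(to_ocm) {
      # to_ocm maps this grid's physical coords into the OCM frame
      a <- array(0, dims)
      zz <- ((seq_len(dims[1])) - 1) * spacing_um[1]
      yy <- ((seq_len(dims[2])) - 1) * spacing_um[2]
      xx <- ((seq_len(dims[3])) - 1) * spacing_um[3]
      q <- to_ocm(zz, yy, xx) # list(z=vec nz, y=vec ny, x=vec nx)
      zs <- outer(q$y, q$x, FUN = surf_z) # (ny, nx) surface depth in OCM frame
      for (iz in seq_len(dims[1]))
        a[iz, , ] <- exp(-(q$z[iz] - zs)^2 / (2 * shell_sigma^2))
      a + abs(stats::rnorm(prod(dims), 0, noise_sd))
    }
    ocm <- render(function(z, y, x) list(z = z, y = y, x = x))
    pam <- render(function(z, y, x) list(
      z = true_scale[1] * z + true_offset_um[1],
      y = true_scale[2] * y + true_offset_um[2],
      x = true_scale[3] * x + true_offset_um[3]))
    list(ocm = Volume3D(ocm, spacing_um, "PHANTOM"),
         pam = Volume3D(pam, spacing_um, "PHANTOM"),
         truth = list(offset_um = true_offset_um, scale = true_scale))
  })
}

#' Generate a spectral-domain interferogram frame
#'
#' Synthesizes the raw spectrometer fringes of point reflectors under a
#' Gaussian source envelope: each reflector adds
#' \code{reflectivity * cos(2 * k * n_medium * depth + phase(k))}, sampled on
#' a wavelength axis that is uniform in wavelength and therefore nonlinear in
#' wavenumber (so reconstruction must resample to uniform k). Optional
#' residual dispersion adds a polynomial phase in \code{(k - k0)}.
#'
#' @param reflector_depths_um reflector depths in micrometres (may be empty).
#' @param reflectivities one reflectivity per reflector.
#' @param n_samples spectral samples per A-line.
#' @param center_wl_nm source centre wavelength (default 845 nm).
#' @param bandwidth_nm source FWHM bandwidth (default 131 nm).
#' @param background_level DC background amplitude.
#' @param dispersion polynomial phase coefficients \code{c(c2, c3, ...)} in
#'   rad per (rad/um)^order, applied as \code{sum c_j (k - k0)^(j+1)}.
#' @param n_alines number of identical lateral A-lines (with independent
#'   noise).
#' @param noise_sd additive detector noise.
#' @param n_medium refractive index of the medium (default 1.38, soft
#'   tissue).
#' @param seed integer seed.
#' @return A \code{SpectralFrame}: list with \code{fringes} (n_alines x
#'   n_samples), \code{wavelength_nm}, \code{background} and
#'   \code{dispersion}.
#' @export
generateInterferogram <- function(reflector_depths_um = numeric(0),
                                  reflectivities = numeric(0),
                                  n_samples = 1024,
                                  center_wl_nm = 845, bandwidth_nm = 131,
                                  background_level = 5,
                                  dispersion = c(0, 0),
                                  n_alines = 1,
                                  noise_sd = 0.002,
                                  n_medium = 1.38,
                                  seed = 1) {
  stopifnot(length(reflector_depths_um) == length(reflectivities))
  .withSeed(seed, {
    span <- 1.8 * bandwidth_nm
    wl <- seq(center_wl_nm - span / 2, center_wl_nm + span / 2,
              length.out = n_samples)
    k <- 2 * pi / (wl * 1e-3)              # rad/um, decreasing in wl
    k0 <- 2 * pi / (center_wl_nm * 1e-3)
    dk_fwhm <- 2 * pi * bandwidth_nm / center_wl_nm^2 * 1e3 # rad/um
    sig_k <- dk_fwhm / (2 * sqrt(2 * log(2)))
    env <- exp(-(k - k0)^2 / (2 * sig_k^2))

    z_max <- pi * n_samples / (2 * n_medium * (max(k) - min(k)))
    if (any(reflector_depths_um > 0.95 * z_max))
      stop("depth beyond Nyquist range (max ", signif(0.95 * z_max, 4), " um)")

    phase_d <- 0
    if (length(dispersion) && any(dispersion != 0)) {
      for (j in seq_along(dispersion))
        phase_d <- phase_d + dispersion[j] * (k - k0)^(j + 1)
    }
    bg <- background_level * env
    signal <- bg
    for (r in seq_along(reflector_depths_um))
      signal <- signal + reflectivities[r] * env *
        cos(2 * n_medium * k * reflector_depths_um[r] + phase_d)
    fr <- matrix(rep(signal, each = n_alines), n_alines, n_samples) +
      stats::rnorm(n_alines * n_samples, 0, noise_sd)
    structure(list(fringes = fr, wavelength_nm = wl, background = bg,
                   dispersion = dispersion, n_medium = n_medium),
              class = "SpectralFrame")
  })
}

#' Generate a two-regime texture cohort for classifier studies
#'
#' Renders single-organoid mini-scenes, half in the HIGH-viability and half
#' in the LOW-viability texture regime, and extracts the 32-feature texture
#' vector of each organoid from its ground-truth mask. A convenience wrapper
#' used to validate the viability classifier at a chosen sample size.
#'
#' @param n_per_class organoids per viability class.
#' @param spacing_um voxel spacing.
#' @param semiaxes_um (min, max) organoid mean semi-axes in micrometres.
#' @param n_levels grey levels for feature discretization.
#' @param seed integer seed.
#' @return List with \code{features} (matrix, 2 * n_per_class x 32),
#'   \code{labels} (factor HIGH/LOW) and \code{meta} (data.frame).
#' @export
generateTextureCohort <- function(n_per_class = 100,
                                  spacing_um = c(2.52, 2.52, 2.52),
                                  semiaxes_um = c(25, 35),
                                  n_levels = 32,
                                  seed = 1) {
  .withSeed(seed, {
    cls <- rep(c("HIGH", "LOW"), each = n_per_class)
    feats <- NULL
    for (i in seq_along(cls)) {
      reg <- .TEXTURE_REGIMES[[cls[i]]]
      semi <- stats::runif(3, semiaxes_um[1], semiaxes_um[2])
      field <- 2 * semi + 20
      dims <- as.integer(round(field / spacing_um))
      vol <- array(0.02 + 0.015 * abs(stats::rnorm(prod(dims))), dims)
      spk <- .speckleField(dims, reg$corr_sigma)
      vx <- .ellipsoidVoxels(dims, spacing_um, field / 2, semi)
      vol[vx] <- reg$base * spk[vx]
      lab <- array(0L, dims)
      lab[vx] <- 1L
      v <- Volume3D(vol, spacing_um, "OCM")
      m <- LabelMask(lab, spacing_um)
      fv <- extractFeatureVector(v, m, 1L,
                                 params = list(n_levels = n_levels))
      if (is.null(feats))
        feats <- matrix(NA_real_, length(cls), length(fv),
                        dimnames = list(NULL, names(fv)))
      feats[i, ] <- fv
    }
    list(features = feats, labels = factor(cls, levels = c("LOW", "HIGH")),
         meta = data.frame(id = seq_along(cls), class = cls))
  })
}
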