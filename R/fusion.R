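# OCM/PAM fusion: phantom-based calibration of the axis-aligned affine
# between the two modalities, resampling PAM onto the OCM grid,
# melanin-positive cell detection by per-line peak-amplitude thresholding,
# and fused overlays.

# top-surface map of a phantom volume: per lateral position, the depth (um)
# of the line peak refined to sub-voxel precision by a parabolic vertex fit
# on the log-intensities about the peak (exact for a Gaussian axial profile,
# which removes the grid-phase bias of a plain weighted mean). Lines whose
# peak is below the floor -- a fraction of the global peak or a robust noise
# ceiling, whichever is larger -- are NA.
.surfaceMap <- function(vol, floor_frac = 0.3) {
  a <- voxels(vol)
  sp <- voxelSpacing(vol)
  d <- dim(a)
  zcoord <- (seq_len(d[1]) - 1) * sp[1]
  peak <- apply(a, c(2, 3), max)
  floor_abs <- max(floor_frac * max(peak),
                   stats::median(a) + 10 * stats::mad(a))
  zs <- matrix(NA_real_, d[2], d[3])
  wt <- matrix(0, d[2], d[3])
  cols <- seq_len(d[3])
  for (y in seq_len(d[2])) {
    ln <- a[, y, , drop = FALSE]
    dim(ln) <- c(d[1], d[3]) # (nz, nx)
    pk <- peak[y, ]
    ok <- pk >= floor_abs
    if (!any(ok)) next
    im <- max.col(t(ln), ties.method = "first")
    z0 <- zcoord[im]
    interior <- im > 1L & im < d[1]
    lc <- ln[cbind(im, cols)]
    lo <- hi <- rep(NA_real_, d[3])
    lo[interior] <- ln[cbind(im[interior] - 1L, cols[interior])]
    hi[interior] <- ln[cbind(im[interior] + 1L, cols[interior])]
    good <- interior & is.finite(lo) & is.finite(hi) &
      lo > 0 & hi > 0 & lc > 0 & lo < lc & hi < lc
    if (any(good)) {
      la <- log(lo[good])
      lb <- log(lc[good])
      lz <- log(hi[good])
      den <- la - 2 * lb + lz
      frac <- ifelse(den < 0, 0.5 * (la - lz) / den, 0)
      z0[good] <- z0[good] + pmax(pmin(frac, 0.5), -0.5) * sp[1]
    }
    zs[y, ok] <- z0[ok]
    wt[y, ok] <- pk[ok]
  }
  list(z = zs, weight = wt,
       y_um = (seq_len(d[2]) - 1) * sp[2],
       x_um = (seq_len(d[3]) - 1) * sp[3])
}

# weighted mean/sd of lateral coordinates under surface-height weights;
# sy = sx = 0 signals a featureless (flat) surface
.lateralMoments <- function(sm) {
  h <- sm$z
  valid <- !is.na(h)
  base <- stats::quantile(h[valid], 0.95, names = FALSE)
  w <- pmax(base - h, 0) # height above the base plane
  w[!valid] <- 0
  # drop the near-base skirt: lines within 2% of the peak prominence carry
  # no shape information and their heights are dominated by per-line noise
  if (max(w) > 0) w[w < 0.02 * max(w)] <- 0
  W <- sum(w)
  if (!is.finite(W) || W <= 0)
    return(list(my = NA_real_, mx = NA_real_, sy = 0, sx = 0))
  ym <- sum(w * matrix(sm$y_um, nrow(h), ncol(h))) / W
  xm <- sum(w * matrix(sm$x_um, nrow(h), ncol(h), byrow = TRUE)) / W
  yv <- sum(w * (matrix(sm$y_um, nrow(h), ncol(h)) - ym)^2) / W
  xv <- sum(w * (matrix(sm$x_um, nrow(h), ncol(h), byrow = TRUE) - xm)^2) / W
  list(my = ym, mx = xm, sy = sqrt(yv), sx = sqrt(xv))
}

#' Calibrate the PAM-to-OCM mapping from a phantom pair
#'
#' Estimates the axis-aligned affine (per-axis scale and offset) that maps
#' PAM physical coordinates onto the OCM frame, from two images of the same
#' pyramid phantom. The top surface is extracted per lateral position in
#' each modality; the lateral scale and offset follow from height-weighted
#' first and second moments of the surface footprint, and the axial pair
#' from a least-squares fit of the OCM surface depths against the PAM
#' surface depths sampled at corresponding lateral positions. The residual
#' is the RMS axial misfit after calibration.
#'
#' @param ocm_phantom,pam_phantom \linkS4class{Volume3D} phantom volumes.
#' @return A \linkS4class{FusionCalibration}.
#' @export
calibrateFusion <- function(ocm_phantom, pam_phantom) {
  so <- .surfaceMap(ocm_phantom)
  sp_ <- .surfaceMap(pam_phantom)
  vo <- mean(!is.na(so$z))
  vp <- mean(!is.na(sp_$z))
  if (vo < 0.05 || vp < 0.05)
    stop("phantom surface not detected (featureless or pure-noise volume)")
  mo <- .lateralMoments(so)
  mp <- .lateralMoments(sp_)
  if (mp$sy <= 0 || mp$sx <= 0 || mo$sy <= 0 || mo$sx <= 0)
    stop("flat surface: lateral scale unidentifiable")
  # ocm = scale * pam + offset, per axis
  sy <- mo$sy / mp$sy
  sx <- mo$sx / mp$sx
  oy <- mo$my - sy * mp$my
  ox <- mo$mx - sx * mp$mx

  # axial fit: sample the PAM surface at OCM lateral positions mapped into
  # PAM coordinates (bilinear interpolation)
  ny <- length(so$y_um)
  nx <- length(so$x_um)
  yg <- matrix(so$y_um, ny, nx)
  xg <- matrix(so$x_um, ny, nx, byrow = TRUE)
  yp <- (yg - oy) / sy
  xp <- (xg - ox) / sx
  zp <- .bilinear(sp_$z, sp_$y_um, sp_$x_um, yp, xp)
  ok <- !is.na(zp) & !is.na(so$z)
  if (sum(ok) < 10) stop("insufficient surface overlap for axial fit")
  fit <- stats::lm(zo ~ zp, data = data.frame(zo = so$z[ok], zp = zp[ok]))
  sz <- unname(stats::coef(fit)[2])
  oz <- unname(stats::coef(fit)[1])
  if (!is.finite(sz) || sz <= 0) stop("axial scale unidentifiable")
  res <- sqrt(mean(stats::residuals(fit)^2))
  FusionCalibration(offset = c(oz, oy, ox), scale = c(sz, sy, sx),
                    residual = res)
}

# bilinear interpolation of matrix m (rows at yc, cols at xc) at query
# coordinates (ym, xm); NA outside or when any corner is NA
.bilinear <- function(m, yc, xc, ym, xm) {
  dy <- yc[2] - yc[1]
  dx <- xc[2] - xc[1]
  fy <- (ym - yc[1]) / dy
  fx <- (xm - xc[1]) / dx
  i0 <- floor(fy)
  j0 <- floor(fx)
  wy <- fy - i0
  wx <- fx - j0
  out <- array(NA_real_, dim(ym))
  valid <- i0 >= 0 & i0 <= length(yc) - 2 & j0 >= 0 & j0 <= length(xc) - 2
  idx <- which(valid)
  if (!length(idx)) return(out)
  i0 <- i0[idx] + 1
  j0 <- j0[idx] + 1
  get <- function(di, dj) m[cbind(i0 + di, j0 + dj)]
  v <- (1 - wy[idx]) * ((1 - wx[idx]) * get(0, 0) + wx[idx] * get(0, 1)) +
    wy[idx] * ((1 - wx[idx]) * get(1, 0) + wx[idx] * get(1, 1))
  out[idx] <- v
  out
}

#' Resample a PAM volume onto an OCM grid under a calibration
#'
#' Each OCM voxel's physical coordinate is mapped back into PAM coordinates
#' through the inverse affine and the PAM volume is sampled by trilinear
#' interpolation; voxels falling outside the PAM field are zero.
#'
#' @param pam a \linkS4class{Volume3D} (PAM modality).
#' @param calib a \linkS4class{FusionCalibration}.
#' @param target a \linkS4class{Volume3D} defining the OCM grid (shape and
#'   spacing).
#' @return A \linkS4class{Volume3D} on the target grid, PAM modality.
#' @export
applyCalibration <- function(pam, calib, target) {
  a <- voxels(pam)
  dp <- dim(a)
  spp <- voxelSpacing(pam)
  dt <- dim(target)
  spt <- voxelSpacing(target)
  # OCM physical coords per axis
  zc <- ((seq_len(dt[1]) - 1) * spt[1] - calib@offset[1]) / calib@scale[1] /
    spp[1]
  yc <- ((seq_len(dt[2]) - 1) * spt[2] - calib@offset[2]) / calib@scale[2] /
    spp[2]
  xc <- ((seq_len(dt[3]) - 1) * spt[3] - calib@offset[3]) / calib@scale[3] /
    spp[3]
  # fractional PAM voxel indices (0-based)
  out <- array(0, dt)
  z0 <- floor(zc); y0 <- floor(yc); x0 <- floor(xc)
  wz <- zc - z0; wy <- yc - y0; wx <- xc - x0
  okz <- z0 >= 0 & z0 <= dp[1] - 2
  oky <- y0 >= 0 & y0 <= dp[2] - 2
  okx <- x0 >= 0 & x0 <= dp[3] - 2
  iz <- which(okz); iy <- which(oky); ix <- which(okx)
  if (length(iz) && length(iy) && length(ix)) {
    gz <- z0[iz] + 1; gy <- y0[iy] + 1; gx <- x0[ix] + 1
    WZ <- wz[iz]; WY <- wy[iy]; WX <- wx[ix]
    acc <- array(0, c(length(iz), length(iy), length(ix)))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- outer(outer(if (dz) WZ else 1 - WZ, if (dy) WY else 1 - WY),
                 if (dx) WX else 1 - WX)
      acc <- acc + w * a[gz + dz, gy + dy, gx + dx, drop = FALSE]
    }
    out[iz, iy, ix] <- acc
  }
  Volume3D(out, spt, "PAM", acqDay(target))
}

#' Detect melanin-positive absorbers in a PAM volume
#'
#' Default (per-line) scope: within each depth line, voxels at or above
#' \code{threshold_fraction} of that line's peak amplitude are kept; lines
#' whose peak stays below the global noise floor (mean + \code{noise_sd_mult}
#' standard deviations of a background region) are skipped entirely. Kept
#' voxels are grouped into 26-connected components and summarized by their
#' intensity-weighted centroid. The global scope thresholds against the
#' volume-wide peak instead. Components smaller than \code{min_voxels} are
#' discarded: a real absorber is at least the size of the acoustic point
#' spread function, whereas isolated noise excursions above the floor are
#' single voxels.
#'
#' @param pam a \linkS4class{Volume3D} (PAM modality).
#' @param threshold_fraction fraction of the peak amplitude, in (0, 1);
#'   default 0.87.
#' @param scope \code{"per_aline"} (default) or \code{"global"}.
#' @param background logical array marking a background (noise-only) region;
#'   default: the lateral border frame of the volume.
#' @param noise_sd_mult noise floor multiplier (default 5).
#' @param min_voxels minimum component size in voxels (default 5, well below
#'   the point-spread-function support at micrometre-scale sampling).
#' @return data.frame with one row per absorber: \code{cz, cy, cx} (um),
#'   \code{peak_amplitude}, \code{n_voxels}. Zero rows for an all-noise
#'   volume.
#' @export
detectAbsorbers <- function(pam, threshold_fraction = 0.87,
                            scope = c("per_aline", "global"),
                            background = NULL, noise_sd_mult = 5,
                            min_voxels = 5L) {
  scope <- match.arg(scope)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  a <- voxels(pam)
  d <- dim(a)
  sp <- voxelSpacing(pam)
  if (max(a) <= 0)
    return(data.frame(cz = numeric(0), cy = numeric(0), cx = numeric(0),
                      peak_amplitude = numeric(0), n_voxels = integer(0)))
  if (is.null(background)) {
    background <- array(FALSE, d)
    b <- 3L
    background[, c(seq_len(min(b, d[2])), seq(max(1, d[2] - b + 1), d[2])), ] <- TRUE
    background[, , c(seq_len(min(b, d[3])), seq(max(1, d[3] - b + 1), d[3]))] <- TRUE
  }
  bg <- a[background]
  floor_abs <- mean(bg) + noise_sd_mult * stats::sd(bg)
  keep <- array(FALSE, d)
  if (scope == "global") {
    pk <- max(a)
    if (pk >= floor_abs) keep <- a >= threshold_fraction * pk & a >= floor_abs
  } else {
    peak <- apply(a, c(2, 3), max) # per depth line (y, x)
    line_ok <- peak >= floor_abs
    if (any(line_ok)) {
      thr <- array(rep(threshold_fraction * peak, each = d[1]), d)
      okmask <- array(rep(line_ok, each = d[1]), d)
      keep <- okmask & a >= thr & a >= floor_abs
    }
  }
  if (!any(keep))
    return(data.frame(cz = numeric(0), cy = numeric(0), cx = numeric(0),
                      peak_amplitude = numeric(0), n_voxels = integer(0)))
  lab <- array(cpp_label26(as.logical(keep), as.integer(d)), d)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids)) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(ids))[ids]
    ids <- ids[sizes >= min_voxels]
  }
  if (!length(ids))
    return(data.frame(cz = numeric(0), cy = numeric(0), cx = numeric(0),
                      peak_amplitude = numeric(0), n_voxels = integer(0)))
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    w <- a[lab == id]
    ctr <- colSums((idx - 1) * w) / sum(w) * sp
    data.frame(cz = ctr[1], cy = ctr[2], cx = ctr[3],
               peak_amplitude = max(w), n_voxels = nrow(idx))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_amplitude), ]
  rownames(out) <- NULL
  out
}

#' Fused OCM/PAM overlay
#'
#' Renders the OCM channel as a grayscale standard-deviation en-face
#' projection in log scale and the PAM channel on a warm (orange-red)
#' colormap from its maximum-amplitude projection in log scale,
#' alpha-composited onto the grayscale. When the PAM channel holds no
#' detectable absorber (per [detectAbsorbers()]) the fused image equals the
#' OCM grayscale exactly, so noise-only PAM volumes add no colour.
#'
#' @param ocm a \linkS4class{Volume3D} (OCM modality).
#' @param pam_on_grid a \linkS4class{Volume3D} already resampled onto the
#'   OCM grid (see [applyCalibration()]).
#' @param db_floor log-compression floor in dB (default -40).
#' @param alpha maximum PAM opacity in the composite.
#' @param pam_floor linear PAM amplitude below which a pixel shows no
#'   colour; default: mean + 5 SD of the PAM lateral border.
#' @return List with \code{image} (ny x nx x 3 RGB array in [0, 1]),
#'   \code{ocm_db}, \code{pam_db} (the projections) and \code{volume}
#'   (4D array: the two co-registered channels).
#' @export
fuseOverlay <- function(ocm, pam_on_grid, db_floor = -40, alpha = 0.8,
                        pam_floor = NULL) {
  if (!identical(dim(ocm), dim(pam_on_grid))) stop("shape mismatch")
  g_db <- enFaceProjection(ocm, "STD", log_compress = TRUE,
                           db_floor = db_floor)
  g <- (g_db - db_floor) / (-db_floor)
  p_lin <- enFaceProjection(pam_on_grid, "MAX", log_compress = FALSE)
  if (is.null(pam_floor)) {
    d <- dim(p_lin)
    border <- c(p_lin[c(1:min(3, d[1]), max(1, d[1] - 2):d[1]), ],
                p_lin[, c(1:min(3, d[2]), max(1, d[2] - 2):d[2])])
    pam_floor <- mean(border) + 5 * stats::sd(border)
  }
  mx <- max(p_lin)
  empty <- mx <= pam_floor || nrow(detectAbsorbers(pam_on_grid)) == 0L
  if (empty) {
    av <- matrix(0, nrow(p_lin), ncol(p_lin))
    pv <- av
  } else {
    pv <- pmax(20 * log10(pmax(p_lin, .Machine$double.xmin) / mx), db_floor)
    pv <- (pv - db_floor) / (-db_floor)
    av <- ifelse(p_lin > pam_floor, alpha * pv, 0)
  }
  # warm colormap: dark red -> orange-red
  warm_r <- pmin(1, 0.4 + 0.6 * pv)
  warm_g <- 0.45 * pv
  warm_b <- 0.05 * pv
  img <- array(0, c(nrow(g), ncol(g), 3))
  img[, , 1] <- (1 - av) * g + av * warm_r
  img[, , 2] <- (1 - av) * g + av * warm_g
  img[, , 3] <- (1 - av) * g + av * warm_b
  vol4 <- array(0, c(dim(ocm), 2))
  vol4[, , , 1] <- voxels(ocm)
  vol4[, , , 2] <- voxels(pam_on_grid)
  list(image = img, ocm_db = g_db,
       pam_db = if (!empty) pv * (-db_floor) + db_floor else
         matrix(db_floor, nrow(g), ncol(g)),
       volume = vol4)
}
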