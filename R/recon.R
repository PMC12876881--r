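# Spectral-domain OCM reconstruction: background subtraction, resampling from
# the wavelength axis to uniformly spaced wavenumber, software dispersion
# compensation, and inverse Fourier transform; plus the en-face projections
# used for display.

#' Reconstruct a B-scan from a spectral frame
#'
#' Per A-line: subtracts the background spectrum, resamples the fringe by
#' cubic spline from the (nonlinear) wavelength axis onto a uniformly spaced
#' wavenumber grid, applies the polynomial dispersion phase correction, and
#' takes the magnitude of the inverse Fourier transform over positive depths.
#' The depth pixel pitch follows from the spanned wavenumber range:
#' \code{dz = pi / (n_medium * delta_k)} micrometres.
#'
#' @param frame a \code{SpectralFrame} (see [generateInterferogram()]): list
#'   with \code{fringes} (n_alines x n_samples), \code{wavelength_nm},
#'   \code{background}, \code{dispersion}.
#' @param n_medium refractive index of the medium (default 1.38).
#' @param correct_dispersion apply the frame's dispersion coefficients with
#'   opposite sign (set \code{FALSE} to see the uncompensated point spread).
#' @return A \linkS4class{Volume3D} of shape (n_depth, 1, n_alines), OCM
#'   modality, with attribute \code{depth_um} giving the depth axis.
#' @export
reconstructBscan <- function(frame, n_medium = 1.38,
                             correct_dispersion = TRUE) {
  wl <- frame$wavelength_nm
  if (!(all(diff(wl) > 0) || all(diff(wl) < 0)))
    stop("wavelength axis must be strictly monotonic")
  k <- 2 * pi / (wl * 1e-3) # rad/um
  n <- length(k)
  ku <- seq(min(k), max(k), length.out = n)
  k0 <- 2 * pi / (mean(range(wl)) * 1e-3)

  fr <- frame$fringes
  if (is.null(dim(fr))) fr <- matrix(fr, nrow = 1)
  n_alines <- nrow(fr)

  phase <- 0
  disp <- frame$dispersion
  if (correct_dispersion && length(disp) && any(disp != 0)) {
    for (j in seq_along(disp)) phase <- phase + disp[j] * (ku - k0)^(j + 1)
  }
  corr <- exp(-1i * phase)

  n_keep <- floor(n / 2)
  out <- matrix(0, n_keep, n_alines)
  for (a in seq_len(n_alines)) {
    f <- fr[a, ] - frame$background
    fu <- stats::spline(k, f, xout = ku, method = "natural")$y
    A <- stats::fft(fu * corr)
    out[, a] <- Mod(A)[seq_len(n_keep)]
  }
  dk <- max(k) - min(k)
  dz <- pi / (n_medium * dk) # um per depth pixel
  vol <- array(out, c(n_keep, 1, n_alines))
  v <- Volume3D(vol, spacing = c(dz, 1, 1), modality = "OCM")
  attr(v, "depth_um") <- (seq_len(n_keep) - 1) * dz
  v
}

#' En-face projection of a volume
#'
#' Collapses the depth (z) axis by a statistic. With \code{log_compress},
#' intensities are mapped to \code{20 * log10(x / max(x))} decibels and
#' clipped at \code{db_floor} below the peak, the standard display transform
#' for interferometric and photoacoustic volumes.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param method \code{"STD"} (standard deviation, the usual OCM en-face
#'   statistic), \code{"MAX"} (maximum amplitude projection) or
#'   \code{"MEAN"}.
#' @param log_compress logical; apply dB compression after projecting.
#' @param db_floor clipping floor in dB below the peak (default -40).
#' @return A (ny, nx) matrix: linear units, or dB in \code{[db_floor, 0]}.
#' @export
enFaceProjection <- function(vol, method = c("STD", "MAX", "MEAN"),
                             log_compress = FALSE, db_floor = -40) {
  method <- match.arg(method)
  a <- voxels(vol)
  img <- switch(method,
    STD = apply(a, c(2, 3), stats::sd),
    MAX = apply(a, c(2, 3), max),
    MEAN = apply(a, c(2, 3), mean))
  if (dim(a)[1] == 1L && method == "STD") img[] <- 0
  if (log_compress) {
    mx <- max(img)
    if (mx <= 0) {
      warning("all-zero projection; returning floor image")
      img[] <- db_floor
    } else {
      img <- pmax(20 * log10(pmax(img, .Machine$double.xmin) / mx), db_floor)
    }
  }
  img
}
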