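#' Read a TIFF stack into a Volume3D
#'
#' Pages of the stack become z slices; each page is a (y, x) matrix. Integer
#' TIFFs (8/16-bit) are read back at their native integer values; 32-bit
#' stacks come back as [0, 1] intensities (see [writeVolume()] for the
#' quantization). Voxel data is always returned in double storage.
#'
#' @param path path to a single- or multi-page TIFF.
#' @param spacing voxel spacing \code{(dz, dy, dx)} in micrometres.
#' @param modality modality tag (see \linkS4class{Volume3D}).
#' @param day integer acquisition day or \code{NA}.
#' @return A \linkS4class{Volume3D}.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, spacing, modality = "OCM", day = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty stack: ", path)
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (!is.null(bits) && bits >= 32L) {
    # 32-bit samples: as.is reinterprets them through the signed-integer
    # range, so reread in the default mode, which rescales to [0, 1]
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("non-scalar samples: every page must be a single-channel matrix")
  shp <- dim(pages[[1L]])
  if (any(vapply(pages, function(p) !identical(dim(p), shp), logical(1))))
    stop("non-uniform page shapes in ", path)
  a <- aperm(simplify2array(pages), c(3L, 1L, 2L)) # (z, y, x)
  storage.mode(a) <- "double"
  Volume3D(a, spacing = spacing, modality = modality, day = day)
}

#' Write a Volume3D (or LabelMask) as a TIFF stack
#'
#' Integer-valued grids are stored at 8 or 16 bits and round-trip exactly
#' through [readVolume()]. All other grids must lie in [0, 1] and are stored
#' at 32-bit depth, which quantizes intensities to steps of 1/(2^32 - 1)
#' (about 2.3e-10); rescale before writing if the data exceed that range.
#'
#' @param vol a \linkS4class{Volume3D} or \linkS4class{LabelMask}.
#' @param path output file path.
#' @param bits bits per sample: 8, 16 (integer) or 32 ([0, 1] intensities).
#'   Default picks 16 for integer-valued data, 32 otherwise.
#' @return The output path, invisibly.
#' @export
writeVolume <- function(vol, path, bits = NULL) {
  a <- if (is(vol, "LabelMask")) vol@labels else vol@data
  if (!all(is.finite(a))) stop("grid contains non-finite values")
  integerish <- all(a == round(a)) && min(a) >= 0
  if (is.null(bits)) bits <- if (integerish && max(a) < 65536) 16L else 32L
  pages <- lapply(seq_len(dim(a)[1L]), function(z) a[z, , , drop = TRUE])
  pages <- lapply(pages, function(p) matrix(p, dim(a)[2L], dim(a)[3L]))
  if (bits %in% c(8L, 16L)) {
    mx <- 2^bits - 1
    if (max(a) > mx) stop("values exceed ", bits, "-bit range")
    pages <- lapply(pages, function(p) p / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else {
    if (min(a) < 0 || max(a) > 1)
      stop("32-bit storage expects values in [0, 1]; rescale before writing")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Write flat records to CSV
#'
#' @param records a data.frame, or a list of identically named lists/vectors.
#' @param path output CSV path.
#' @return The output path, invisibly.
#' @export
writeTable <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records)) {
      fields <- lapply(records, function(r) sort(names(r)))
      if (!all(vapply(fields, identical, logical(1), fields[[1L]])))
        stop("heterogeneous field sets across records")
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      stop("cannot infer columns from an empty record list; pass a data.frame")
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a FusionCalibration as JSON
#'
#' @param calib a \linkS4class{FusionCalibration}.
#' @param path JSON file path.
#' @return \code{writeCalibration}: the path, invisibly.
#'   \code{readCalibration}: a \linkS4class{FusionCalibration}.
#' @export
writeCalibration <- function(calib, path) {
  jsonlite::write_json(
    list(offset_um = calib@offset, scale = calib@scale,
         residual_um = calib@residual),
    path, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  FusionCalibration(offset = j$offset_um, scale = j$scale,
                    residual = j$residual_um)
}
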