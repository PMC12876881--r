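#' @useDynLib ocpam, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.MODALITIES <- c("OCM", "PAM", "FLM_LIVE", "FLM_DEAD", "PHANTOM")

#' Volume3D: a 3D intensity grid with physical voxel spacing
#'
#' The central image container of the package. The grid is indexed
#' \code{(z, y, x)} (depth first); voxel indices are 0-based in all physical
#' coordinate conversions, with the origin at the centre of voxel
#' \code{(0, 0, 0)}, so the physical position of a voxel is
#' \code{index * spacing} in micrometres.
#'
#' @slot data 3D numeric array, dimensions \code{(nz, ny, nx)}, finite and
#'   non-negative intensities in arbitrary units.
#' @slot spacing numeric length-3 vector \code{(dz, dy, dx)} in micrometres,
#'   all strictly positive.
#' @slot modality one of \code{"OCM"}, \code{"PAM"}, \code{"FLM_LIVE"},
#'   \code{"FLM_DEAD"}, \code{"PHANTOM"}.
#' @slot day integer acquisition day, or \code{NA} when not applicable.
#'
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", modality = "character",
                 day = "integer"),
  prototype(modality = "OCM", day = NA_integer_)
)

setValidity("Volume3D", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3D array (z, y, x)")
  if (any(dim(object@data) < 1L))
    msgs <- c(msgs, "grid dimensions must all be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive finite values (dz, dy, dx)")
  if (!all(is.finite(object@data)))
    msgs <- c(msgs, "intensities must be finite")
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msgs <- c(msgs, paste("modality must be one of",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Volume3D
#'
#' @param data 3D numeric array indexed \code{(z, y, x)}.
#' @param spacing voxel spacing \code{(dz, dy, dx)} in micrometres.
#' @param modality modality tag; see \linkS4class{Volume3D}.
#' @param day integer acquisition day or \code{NA}.
#' @return A \linkS4class{Volume3D}.
#' @examples
#' v <- Volume3D(array(runif(60), c(3, 4, 5)), spacing = c(2.52, 2.52, 2.52))
#' dim(v)
#' @export
Volume3D <- function(data, spacing, modality = "OCM", day = NA_integer_) {
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      modality = modality, day = as.integer(day))
}

#' LabelMask: integer organoid labels aligned to a Volume3D
#'
#' Voxel value 0 is background; values 1..K identify individual organoids.
#' After the filtering stage of segmentation, labels are contiguous and each
#' label is 26-connected.
#'
#' @slot labels 3D integer array, same shape as the source volume.
#' @slot spacing voxel spacing \code{(dz, dy, dx)} in micrometres.
#' @slot day integer acquisition day or \code{NA}.
#' @export
setClass("LabelMask",
  representation(labels = "array", spacing = "numeric", day = "integer"),
  prototype(day = NA_integer_)
)

setValidity("LabelMask", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array (z, y, x)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  lv <- object@labels
  if (any(lv < 0) || any(lv != round(lv)))
    msgs <- c(msgs, "labels must be non-negative integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabelMask
#'
#' @param labels 3D array of non-negative integer labels.
#' @param spacing voxel spacing \code{(dz, dy, dx)} in micrometres.
#' @param day integer acquisition day or \code{NA}.
#' @return A \linkS4class{LabelMask}.
#' @export
LabelMask <- function(labels, spacing, day = NA_integer_) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, spacing = as.numeric(spacing),
      day = as.integer(day))
}

#' FusionCalibration: axis-aligned affine mapping PAM onto the OCM frame
#'
#' Maps a PAM physical coordinate \code{p} (micrometres) to the OCM frame as
#' \code{scale * p + offset}, per axis in \code{(z, y, x)} order.
#'
#' @slot offset per-axis offset in micrometres.
#' @slot scale per-axis scale factor, strictly positive.
#' @slot residual RMS registration residual in micrometres after the fit.
#' @export
setClass("FusionCalibration",
  representation(offset = "numeric", scale = "numeric", residual = "numeric"))

setValidity("FusionCalibration", function(object) {
  msgs <- character()
  if (length(object@offset) != 3L || length(object@scale) != 3L)
    msgs <- c(msgs, "offset and scale must each have 3 components (z, y, x)")
  if (any(object@scale <= 0)) msgs <- c(msgs, "scales must be > 0")
  if (length(object@residual) != 1L || object@residual < 0)
    msgs <- c(msgs, "residual must be a single non-negative value")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FusionCalibration
#'
#' @param offset per-axis offset \code{(z, y, x)} in micrometres.
#' @param scale per-axis scale factor \code{(z, y, x)}.
#' @param residual RMS residual of the calibration fit in micrometres.
#' @return A \linkS4class{FusionCalibration}.
#' @export
FusionCalibration <- function(offset = c(0, 0, 0), scale = c(1, 1, 1),
                              residual = 0) {
  new("FusionCalibration", offset = as.numeric(offset),
      scale = as.numeric(scale), residual = as.numeric(residual))
}

## ------------------------------------------------------------------ generics

#' @rdname Volume3D-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname Volume3D-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname Volume3D-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname Volume3D-accessors
#' @export
setGeneric("acqDay", function(x) standardGeneric("acqDay"))
#' @rdname LabelMask-accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname LabelMask-accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' Accessors for Volume3D
#'
#' \code{voxels} returns the raw 3D array, \code{voxelSpacing} the
#' \code{(dz, dy, dx)} spacing in micrometres, \code{modality} the modality
#' tag and \code{acqDay} the acquisition day.
#'
#' @param x a \linkS4class{Volume3D} or \linkS4class{LabelMask}.
#' @name Volume3D-accessors
#' @aliases voxels voxelSpacing modality acqDay
NULL

#' @rdname Volume3D-accessors
#' @export
setMethod("voxels", "Volume3D", function(x) x@data)
#' @rdname Volume3D-accessors
#' @export
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)
#' @rdname Volume3D-accessors
#' @export
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname Volume3D-accessors
#' @export
setMethod("modality", "Volume3D", function(x) x@modality)
#' @rdname Volume3D-accessors
#' @export
setMethod("acqDay", "Volume3D", function(x) x@day)
#' @rdname Volume3D-accessors
#' @export
setMethod("acqDay", "LabelMask", function(x) x@day)
#' @rdname Volume3D-accessors
#' @export
setMethod("dim", "Volume3D", function(x) dim(x@data))

#' Accessors for LabelMask
#'
#' \code{labelData} returns the integer 3D array; \code{nLabels} the number of
#' distinct non-zero labels.
#'
#' @param x a \linkS4class{LabelMask}.
#' @name LabelMask-accessors
#' @aliases labelData nLabels
NULL

#' @rdname LabelMask-accessors
#' @export
setMethod("labelData", "LabelMask", function(x) x@labels)
#' @rdname LabelMask-accessors
#' @export
setMethod("nLabels", "LabelMask",
          function(x) length(setdiff(unique(as.vector(x@labels)), 0L)))
#' @rdname LabelMask-accessors
#' @export
setMethod("dim", "LabelMask", function(x) dim(x@labels))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D [%s] %d x %d x %d voxels (z,y,x)\n", object@modality,
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g um; day: %s\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              ifelse(is.na(object@day), "-", object@day)))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMask %d x %d x %d voxels (z,y,x), %d organoid(s)\n",
              d[1], d[2], d[3], nLabels(object)))
  cat(sprintf("  spacing: %.3g x %.3g x %.3g um; day: %s\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              ifelse(is.na(object@day), "-", object@day)))
})

setMethod("show", "FusionCalibration", function(object) {
  cat("FusionCalibration (PAM -> OCM frame)\n")
  cat(sprintf("  offset (z,y,x): %s um\n",
              paste(signif(object@offset, 4), collapse = ", ")))
  cat(sprintf("  scale  (z,y,x): %s\n",
              paste(signif(object@scale, 4), collapse = ", ")))
  cat(sprintf("  residual: %.3g um\n", object@residual))
})
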