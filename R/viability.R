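# Fluorescence-derived viability ground truth: CLAHE + Otsu channel
# binarization, live/(live + dead) pixel scoring, and the 50% status cut-off
# separating high- from low-viability organoids.

#' Binarize a fluorescence channel
#'
#' Applies contrast-limited adaptive histogram equalization slice-wise (tiled
#' per slice, with padding to a tile multiple), then a single global Otsu
#' threshold over the equalized stack. Because equalization stretches noise
#' in signal-free tiles up to full range, the equalized threshold is gated by
#' a robust raw-intensity floor (median + 3 MAD of the normalized stack), so
#' empty background cannot cross it.
#'
#' @param img a \linkS4class{Volume3D} of modality \code{FLM_LIVE} or
#'   \code{FLM_DEAD}.
#' @param params list overriding the \code{viability} group of
#'   [defaultConfig()] (\code{clahe_tiles}, \code{clahe_limit}).
#' @return A logical 3D array (same shape), TRUE on stained pixels.
#' @export
binarizeChannel <- function(img, params = list()) {
  p <- utils::modifyList(defaultConfig()$viability, params)
  a <- voxels(img)
  if (max(a) - min(a) < .Machine$double.eps) {
    warning("constant image; returning empty mask")
    return(array(FALSE, dim(a)))
  }
  rng <- range(a)
  a <- (a - rng[1]) / (rng[2] - rng[1])
  dims <- dim(a)
  nt <- p$clahe_tiles
  pad <- function(n) ((n + nt - 1) %/% nt) * nt
  ny <- pad(dims[2])
  nx <- pad(dims[3])
  eq <- array(0, dims)
  for (z in seq_len(dims[1])) {
    sl <- matrix(0, ny, nx)
    sl[seq_len(dims[2]), seq_len(dims[3])] <- a[z, , ]
    es <- EBImage::clahe(sl, nx = nt, ny = nt, limit = p$clahe_limit)
    eq[z, , ] <- es[seq_len(dims[2]), seq_len(dims[3])]
  }
  th <- EBImage::otsu(matrix(as.vector(eq), nrow = dims[1] * dims[2]),
                      range = c(0, 1))
  floor_raw <- stats::median(a) + 3 * stats::mad(a)
  eq > th & a > floor_raw
}

#' Viability score of an organoid region
#'
#' Counts stained pixels of each channel inside the region of interest;
#' score = live / (live + dead). Pixels positive in both channels are counted
#' once, as dead (the dead stain dominates by convention).
#'
#' @param live_mask,dead_mask logical arrays from [binarizeChannel()],
#'   aligned to the ROI grid.
#' @param roi logical array (or integer-indexable selection) marking the
#'   organoid region.
#' @param id optional organoid identifier.
#' @return A \code{ViabilityLabel}: list with \code{id}, \code{live},
#'   \code{dead}, \code{score} and \code{status} (\code{NA} until
#'   [assignStatus()]; \code{"UNSCORABLE"} when no stained pixel falls in the
#'   ROI).
#' @export
viabilityScore <- function(live_mask, dead_mask, roi, id = NA_integer_) {
  stopifnot(identical(dim(live_mask), dim(dead_mask)))
  live <- live_mask & roi & !dead_mask # double-positives count as dead
  dead <- dead_mask & roi
  nl <- sum(live)
  nd <- sum(dead)
  status <- NA_character_
  score <- if (nl + nd > 0) nl / (nl + nd) else {
    status <- "UNSCORABLE"
    NA_real_
  }
  structure(list(id = id, live = nl, dead = nd, score = score,
                 status = status),
            class = "ViabilityLabel")
}

#' Assign the viability status by the 50% cut-off
#'
#' HIGH when the score strictly exceeds the cut-off, LOW otherwise (a score
#' exactly at the cut-off is LOW). Unscorable labels pass through unchanged.
#'
#' @param label a \code{ViabilityLabel} from [viabilityScore()].
#' @param cutoff score cut-off, default 0.5.
#' @return The label with \code{status} set to \code{"HIGH"} or
#'   \code{"LOW"}.
#' @export
assignStatus <- function(label, cutoff = 0.5) {
  if (identical(label$status, "UNSCORABLE")) return(label)
  label$status <- if (label$score > cutoff) "HIGH" else "LOW"
  label
}

#' Score all organoids of a labelled scene
#'
#' @param flm_live,flm_dead \linkS4class{Volume3D} fluorescence channels.
#' @param mask a \linkS4class{LabelMask} aligned to the channels.
#' @param params list overriding the \code{viability} group of
#'   [defaultConfig()].
#' @return data.frame with \code{label, live, dead, score, status}.
#' @export
viabilityTable <- function(flm_live, flm_dead, mask, params = list()) {
  p <- utils::modifyList(defaultConfig()$viability, params)
  lm <- binarizeChannel(flm_live, params)
  dm <- binarizeChannel(flm_dead, params)
  lab <- labelData(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    vl <- assignStatus(viabilityScore(lm, dm, lab == id, id = id),
                       cutoff = p$cutoff)
    data.frame(label = id, live = vl$live, dead = vl$dead, score = vl$score,
               status = vl$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
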