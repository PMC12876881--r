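# Longitudinal tracking: organoids are matched between adjacent imaged days
# by attribute-based probability scoring (spatial proximity, volume ratio,
# bounding-box overlap), solved as an optimal bipartite assignment. Tracks
# are seeded at a middle-day reference volume and extended day by day in two
# branches, forward to the last day and backward to the first.

#' Select the reference day for tracking
#'
#' Returns the median imaging day; for an even number of days, the earlier of
#' the two central days.
#'
#' @param days ordered integer vector of imaging days (>= 2).
#' @return One element of \code{days}.
#' @export
selectReferenceDay <- function(days) {
  if (length(days) < 2) stop("need at least 2 imaging days")
  days[ceiling(length(days) / 2)]
}

#' Attribute-based match score between two organoid records
#'
#' Combines a Gaussian spatial kernel \code{exp(-d^2 / (2 sigma_d^2))} on the
#' centroid distance, a volume-ratio kernel \code{min(Va, Vb) / max(Va, Vb)}
#' and the intersection-over-union of the bounding boxes, as a weighted sum
#' with weights summing to 1.
#'
#' @param a,b single rows of a [summarizeMask()] record table.
#' @param weights named weights \code{(spatial, volume, bbox)} summing to 1.
#' @param sigma_d_um spatial kernel bandwidth in micrometres.
#' @param spacing voxel spacing, needed to express bounding boxes in
#'   micrometres for the overlap kernel.
#' @return List with the three kernel values and \code{combined} in [0, 1].
#' @export
scorePair <- function(a, b, weights = c(spatial = 0.5, volume = 0.3,
                                        bbox = 0.2),
                      sigma_d_um = 30, spacing = c(1, 1, 1)) {
  if (a$volume_um3 <= 0 || b$volume_um3 <= 0) stop("zero volume record")
  d2 <- (a$cz - b$cz)^2 + (a$cy - b$cy)^2 + (a$cx - b$cx)^2
  spatial <- exp(-d2 / (2 * sigma_d_um^2))
  volume <- min(a$volume_um3, b$volume_um3) / max(a$volume_um3, b$volume_um3)
  ov <- function(lo1, hi1, lo2, hi2, s)
    max(0, (min(hi1, hi2) - max(lo1, lo2)) * s)
  inter <- ov(a$bbox_z0, a$bbox_z1, b$bbox_z0, b$bbox_z1, spacing[1]) *
    ov(a$bbox_y0, a$bbox_y1, b$bbox_y0, b$bbox_y1, spacing[2]) *
    ov(a$bbox_x0, a$bbox_x1, b$bbox_x0, b$bbox_x1, spacing[3])
  volbox <- function(r) (r$bbox_z1 - r$bbox_z0) * spacing[1] *
    (r$bbox_y1 - r$bbox_y0) * spacing[2] * (r$bbox_x1 - r$bbox_x0) * spacing[3]
  bbox <- inter / (volbox(a) + volbox(b) - inter)
  combined <- sum(weights * c(spatial, volume, bbox)[
    match(names(weights), c("spatial", "volume", "bbox"))])
  list(spatial = spatial, volume = volume, bbox = bbox, combined = combined)
}

# Hungarian algorithm (Kuhn-Munkres with potentials and predecessor
# tracking), square cost matrix, minimization. Returns for each row its
# assigned column; deterministic, forbidden entries carry a large finite
# cost.
.assign_lsap <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    while (j0 != 0L) {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

#' Match organoid records between two adjacent imaged days
#'
#' Builds the full score matrix with [scorePair()], forbids pairs scoring
#' below the acceptance threshold \code{tau}, and solves the optimal
#' one-to-one assignment maximizing the total combined score (Hungarian
#' algorithm; ties resolved deterministically by label order). Labels left
#' without an admissible partner are reported unmatched.
#'
#' @param recs_a,recs_b record tables from [summarizeMask()] for the two
#'   days.
#' @param params list overriding the \code{tracking} group of
#'   [defaultConfig()].
#' @param spacing voxel spacing in micrometres.
#' @return List with \code{pairs} (data.frame \code{label_a, label_b, score}),
#'   \code{unmatched_a}, \code{unmatched_b}.
#' @export
matchDayPair <- function(recs_a, recs_b, params = list(),
                         spacing = c(1, 1, 1)) {
  p <- utils::modifyList(defaultConfig()$tracking, params)
  na <- nrow(recs_a)
  nb <- nrow(recs_b)
  if (na == 0L || nb == 0L)
    return(list(pairs = data.frame(label_a = integer(0), label_b = integer(0),
                                   score = numeric(0)),
                unmatched_a = recs_a$label, unmatched_b = recs_b$label))
  recs_a <- recs_a[order(recs_a$label), , drop = FALSE]
  recs_b <- recs_b[order(recs_b$label), , drop = FALSE]
  S <- matrix(0, na, nb)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      S[i, j] <- scorePair(recs_a[i, ], recs_b[j, ], p$weights, p$sigma_d_um,
                           spacing)$combined
  n <- max(na, nb)
  BIG <- 1e6
  cost <- matrix(1, n, n) # dummy assignment costs score 0
  cost[seq_len(na), seq_len(nb)] <- ifelse(S >= p$tau, 1 - S, BIG)
  sol <- .assign_lsap(cost)
  pairs <- data.frame(label_a = integer(0), label_b = integer(0),
                      score = numeric(0))
  for (i in seq_len(na)) {
    j <- sol[i]
    if (j <= nb && S[i, j] >= p$tau)
      pairs <- rbind(pairs, data.frame(label_a = recs_a$label[i],
                                       label_b = recs_b$label[j],
                                       score = S[i, j]))
  }
  list(pairs = pairs,
       unmatched_a = setdiff(recs_a$label, pairs$label_a),
       unmatched_b = setdiff(recs_b$label, pairs$label_b))
}

#' Build tracks across a longitudinal series
#'
#' Seeds one track per organoid of the reference day (the middle imaging
#' day), then extends day by day with [matchDayPair()] in two branches:
#' forward to the last day and backward to the first. Organoids without a
#' match at a later day end their track (\code{LOST} at the first absent
#' day); organoids with no match at an earlier day are flagged
#' \code{APPEARED} at their first observed day and new labels encountered
#' while chaining open new tracks.
#'
#' @param records_by_day named list of [summarizeMask()] tables, names are
#'   the integer days in increasing order.
#' @param params list overriding the \code{tracking} group of
#'   [defaultConfig()].
#' @param spacing voxel spacing in micrometres.
#' @return A \code{TrackSet}: list with \code{entries} (data.frame
#'   \code{track_id, day, label}), \code{flags} (data.frame \code{track_id,
#'   flag, day, partner_id}) and \code{reference_day}.
#' @export
buildTracks <- function(records_by_day, params = list(),
                        spacing = c(1, 1, 1)) {
  days <- as.integer(names(records_by_day))
  if (length(days) < 2) stop("need at least 2 imaging days")
  stopifnot(!is.unsorted(days))
  ref <- selectReferenceDay(days)
  ref_i <- match(ref, days)

  ref_recs <- records_by_day[[ref_i]]
  entries <- data.frame(track_id = seq_len(nrow(ref_recs)), day = ref,
                        label = ref_recs$label)
  next_id <- nrow(ref_recs) + 1L

  chain <- function(idx_seq, entries, next_id) {
    for (s in seq_len(length(idx_seq) - 1L)) {
      i_cur <- idx_seq[s]
      i_nxt <- idx_seq[s + 1L]
      m <- matchDayPair(records_by_day[[i_cur]], records_by_day[[i_nxt]],
                        params, spacing)
      cur_day <- days[i_cur]
      nxt_day <- days[i_nxt]
      active <- entries[entries$day == cur_day, ]
      for (r in seq_len(nrow(active))) {
        lbl <- active$label[r]
        hit <- m$pairs$label_b[m$pairs$label_a == lbl]
        if (length(hit) == 1L)
          entries <- rbind(entries, data.frame(track_id = active$track_id[r],
                                               day = nxt_day, label = hit))
      }
      for (lbl in m$unmatched_b) {
        entries <- rbind(entries, data.frame(track_id = next_id,
                                             day = nxt_day, label = lbl))
        next_id <- next_id + 1L
      }
    }
    list(entries = entries, next_id = next_id)
  }

  fwd <- chain(ref_i:length(days), entries, next_id)
  # backward branch: swap roles so "next" is the earlier day
  bwd <- chain(rev(seq_len(ref_i)), fwd$entries, fwd$next_id)
  entries <- bwd$entries
  entries <- entries[order(entries$track_id, entries$day), ]
  rownames(entries) <- NULL

  flags <- data.frame(track_id = integer(0), flag = character(0),
                      day = integer(0), partner_id = integer(0))
  for (id in unique(entries$track_id)) {
    obs <- sort(entries$day[entries$track_id == id])
    if (min(obs) > min(days))
      flags <- rbind(flags, data.frame(track_id = id, flag = "APPEARED",
                                       day = min(obs),
                                       partner_id = NA_integer_))
    if (max(obs) < max(days)) {
      lost_day <- days[match(max(obs), days) + 1L]
      flags <- rbind(flags, data.frame(track_id = id, flag = "LOST",
                                       day = lost_day,
                                       partner_id = NA_integer_))
    }
  }
  structure(list(entries = entries, flags = flags, reference_day = ref,
                 days = days),
            class = "TrackSet")
}

#' @export
print.TrackSet <- function(x, ...) {
  cat(sprintf("TrackSet: %d tracks over days %s (reference day %d)\n",
              length(unique(x$entries$track_id)),
              paste(x$days, collapse = ", "), x$reference_day))
  if (nrow(x$flags))
    cat(sprintf("  flags: %s\n",
                paste(sprintf("%s(track %d, day %d)", x$flags$flag,
                              x$flags$track_id, x$flags$day), collapse = "; ")))
  invisible(x)
}

#' Detect organoid merges along a track set
#'
#' For each pair of consecutive imaged days, when two or more labels of the
#' earlier day each overlap one label of the later day with at least
#' \code{merge_fraction} of their own voxels, the tracks of the smaller
#' labels are flagged \code{MERGED_INTO} the track owning the largest label
#' at that day.
#'
#' @param tracks a \code{TrackSet} from [buildTracks()].
#' @param masks named list of \linkS4class{LabelMask} per day (names are the
#'   days, aligned grids).
#' @param params list overriding the \code{tracking} group of
#'   [defaultConfig()].
#' @return The \code{TrackSet} with \code{MERGED_INTO} rows appended to its
#'   flags.
#' @export
detectMerges <- function(tracks, masks, params = list()) {
  p <- utils::modifyList(defaultConfig()$tracking, params)
  days <- tracks$days
  for (s in seq_len(length(days) - 1L)) {
    d0 <- days[s]
    d1 <- days[s + 1L]
    m0 <- labelData(masks[[as.character(d0)]])
    m1 <- labelData(masks[[as.character(d1)]])
    ids0 <- setdiff(sort(unique(as.vector(m0))), 0L)
    if (!length(ids0)) next
    # overlap fraction of each prior-day label inside each current-day label
    hits <- list()
    for (l0 in ids0) {
      sel <- m0 == l0
      tgt <- m1[sel]
      tgt <- tgt[tgt > 0L]
      if (!length(tgt)) next
      tab <- table(tgt)
      best <- as.integer(names(tab)[which.max(tab)])
      frac <- max(tab) / sum(sel)
      if (frac >= p$merge_fraction)
        hits[[length(hits) + 1L]] <- data.frame(l0 = l0, l1 = best,
                                                vol0 = sum(sel))
    }
    if (!length(hits)) next
    hits <- do.call(rbind, hits)
    for (l1 in unique(hits$l1)) {
      grp <- hits[hits$l1 == l1, ]
      if (nrow(grp) < 2L) next
      survivor <- grp$l0[which.max(grp$vol0)]
      surv_track <- tracks$entries$track_id[tracks$entries$day == d0 &
                                              tracks$entries$label == survivor]
      for (l0 in setdiff(grp$l0, survivor)) {
        tid <- tracks$entries$track_id[tracks$entries$day == d0 &
                                         tracks$entries$label == l0]
        if (!length(tid) || !length(surv_track)) next
        tracks$flags <- rbind(tracks$flags,
          data.frame(track_id = tid[1], flag = "MERGED_INTO", day = d1,
                     partner_id = surv_track[1]))
      }
    }
  }
  tracks
}

#' Export a track set as a tidy table
#'
#' @param tracks a \code{TrackSet}.
#' @param records_by_day optional named list of [summarizeMask()] tables to
#'   attach per-day volumes.
#' @return data.frame with \code{track_id, day, label} and, when records are
#'   given, \code{volume_um3}.
#' @export
tracksTable <- function(tracks, records_by_day = NULL) {
  out <- tracks$entries
  if (!is.null(records_by_day)) {
    out$volume_um3 <- NA_real_
    for (r in seq_len(nrow(out))) {
      recs <- records_by_day[[as.character(out$day[r])]]
      i <- match(out$label[r], recs$label)
      if (!is.na(i)) out$volume_um3[r] <- recs$volume_um3[i]
    }
  }
  out
}
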