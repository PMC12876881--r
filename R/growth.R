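# Growth quantification: relative volume normalization, growth-pattern
# classification (including the biphasic drug-tolerant-persister signature)
# and per-well summaries.

#' Relative volume growth of one track
#'
#' Normalizes a track's volume series to its first observed volume, giving a
#' dimensionless relative-volume curve (1 at the first observed day). Days on
#' which the organoid was not observed are carried as gaps and never
#' interpolated.
#'
#' @param days integer days of the observations, increasing.
#' @param volumes_um3 per-day volumes in cubic micrometres; \code{NA} marks a
#'   missing day.
#' @param track_id optional identifier carried through to summaries.
#' @return A \code{GrowthProfile}: list with \code{track_id}, \code{days},
#'   \code{volume_um3}, \code{relative} and \code{class} (unset,
#'   \code{NA}).
#' @export
relativeGrowth <- function(days, volumes_um3, track_id = NA_integer_) {
  stopifnot(length(days) == length(volumes_um3), !is.unsorted(days))
  obs <- which(!is.na(volumes_um3))
  if (length(obs) < 2) stop("need at least 2 observed days")
  v0 <- volumes_um3[obs[1]]
  if (!is.finite(v0) || v0 <= 0) stop("zero initial volume")
  structure(list(track_id = track_id, days = days,
                 volume_um3 = volumes_um3,
                 relative = volumes_um3 / v0,
                 class = NA_character_),
            class = "GrowthProfile")
}

#' @export
print.GrowthProfile <- function(x, ...) {
  cat(sprintf("GrowthProfile (track %s)%s\n",
              ifelse(is.na(x$track_id), "-", x$track_id),
              ifelse(is.na(x$class), "", paste0(" class ", x$class))))
  print(data.frame(day = x$days, volume_um3 = x$volume_um3,
                   relative = x$relative))
  invisible(x)
}

#' Classify the growth pattern of a profile
#'
#' A profile is DTP (drug-tolerant persister) when a plateau of at least
#' \code{p_plateau} consecutive intervals, each with fold-change at most
#' \code{f_plateau}, follows at least one growth interval (fold-change above
#' \code{f_plateau}) and is itself followed by a cumulative regrowth of at
#' least \code{f_regrow}. Otherwise the final relative volume R decides:
#' RAPID when \code{log10(R) >= 2}, MEDIUM when \code{1 <= log10(R) < 2},
#' WEAK when \code{log10(R) < 1}.
#'
#' @param profile a \code{GrowthProfile} from [relativeGrowth()].
#' @param thresholds list overriding the \code{growth} group of
#'   [defaultConfig()].
#' @return The profile with \code{class} set.
#' @export
classifyGrowthPattern <- function(profile, thresholds = list()) {
  th <- utils::modifyList(defaultConfig()$growth, thresholds)
  rel <- profile$relative[!is.na(profile$relative)]
  folds <- rel[-1] / rel[-length(rel)]
  cls <- NULL
  if (length(folds) >= th$p_plateau + 2) {
    low <- folds <= th$f_plateau
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values & r$lengths >= th$p_plateau)) {
      s <- starts[seg]
      e <- ends[seg]
      grew_before <- s > 1 && any(folds[seq_len(s - 1)] > th$f_plateau)
      if (!grew_before || e >= length(folds)) next
      regrow <- rel[length(rel)] / rel[e + 1] # cumulative post-plateau fold
      if (regrow >= th$f_regrow) {
        cls <- "DTP"
        break
      }
    }
  }
  if (is.null(cls)) {
    lr <- log10(rel[length(rel)])
    cls <- if (lr >= th$log10_rapid) "RAPID"
    else if (lr >= th$log10_medium) "MEDIUM"
    else "WEAK"
  }
  profile$class <- cls
  profile
}

#' Summarize growth profiles of one well
#'
#' @param profiles list of classified \code{GrowthProfile}s.
#' @return List with \code{curve} (data.frame \code{day, mean_relative,
#'   sd_relative, n}), \code{class_counts} (named integer vector) and
#'   \code{dtp_percent} (percentage of DTP tracks, 3 significant figures).
#' @export
wellSummary <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  all_days <- sort(unique(unlist(lapply(profiles, `[[`, "days"))))
  curve <- do.call(rbind, lapply(all_days, function(d) {
    vals <- unlist(lapply(profiles, function(p) {
      i <- match(d, p$days)
      if (is.na(i)) NA_real_ else p$relative[i]
    }))
    vals <- vals[!is.na(vals)]
    data.frame(day = d, mean_relative = mean(vals),
               sd_relative = if (length(vals) > 1) stats::sd(vals) else 0,
               n = length(vals))
  }))
  cls <- vapply(profiles, `[[`, character(1), "class")
  counts <- table(factor(cls, levels = c("RAPID", "MEDIUM", "WEAK", "DTP")))
  dtp <- signif(100 * sum(cls == "DTP") / length(cls), 3)
  list(curve = curve, class_counts = c(counts), dtp_percent = dtp)
}

#' Growth profiles for every track of a series
#'
#' Convenience wrapper: joins track entries with per-day volumes, computes
#' relative growth and classifies each track with enough observations.
#'
#' @param tracks a \code{TrackSet} from [buildTracks()].
#' @param records_by_day named list of [summarizeMask()] tables per day.
#' @param thresholds list overriding the \code{growth} group of
#'   [defaultConfig()].
#' @return List of classified \code{GrowthProfile}s (tracks observed on
#'   fewer than 2 days are skipped).
#' @export
growthProfiles <- function(tracks, records_by_day, thresholds = list()) {
  tab <- tracksTable(tracks, records_by_day)
  days <- tracks$days
  out <- list()
  for (id in unique(tab$track_id)) {
    sub <- tab[tab$track_id == id, ]
    vols <- rep(NA_real_, length(days))
    vols[match(sub$day, days)] <- sub$volume_um3
    if (sum(!is.na(vols)) < 2) next
    first_obs <- which(!is.na(vols))[1]
    prof <- relativeGrowth(days[first_obs:length(days)],
                           vols[first_obs:length(days)], track_id = id)
    out[[length(out) + 1L]] <- classifyGrowthPattern(prof, thresholds)
  }
  out
}
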