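#' Default pipeline configuration
#'
#' One named group per stage; every parameter is documented with its unit and
#' used wherever that stage runs. Values with a published basis keep it: the
#' absorber detection threshold fraction is 0.87 of the per-line peak, the
#' viability cut-off is 0.5, cross-validation uses 10 folds, and the
#' refractive index of soft tissue is 1.38.
#'
#' @return A nested named list of parameter groups.
#' @export
defaultConfig <- function() {
  list(
    recon = list(
      n_medium = 1.38,          # refractive index of soft tissue
      db_floor = -40            # display floor for log compression, dB
    ),
    segmentation = list(
      percentiles = c(1, 99.99), # histogram clip percentiles (upper is an
                                 # outlier guard: organoids occupy well under
                                 # 1% of a field, so a lower upper clip would
                                 # saturate the whole object class)
      denoise = "median",       # 3x3x3 median denoising
      threshold = "otsu",       # global Otsu on the preprocessed volume
      min_volume_um3 = 500,     # small-object removal
      split_marker_dist_um = 20 # minimum separation of watershed markers
    ),
    tracking = list(
      weights = c(spatial = 0.5, volume = 0.3, bbox = 0.2),
      sigma_d_um = 30,          # spatial kernel bandwidth
      tau = 0.4,                # acceptance threshold on combined score
      merge_fraction = 0.5      # overlap fraction (of smaller object) for merge
    ),
    growth = list(
      f_plateau = 1.25,         # max per-interval fold-change inside a plateau
      p_plateau = 2,            # min consecutive plateau intervals
      f_regrow = 10,            # min post-plateau cumulative fold-change
      log10_rapid = 2,          # final relative volume >= 2 decades -> RAPID
      log10_medium = 1          # >= 1 decade -> MEDIUM, below -> WEAK
    ),
    viability = list(
      cutoff = 0.5,             # HIGH iff score > cutoff
      clahe_tiles = 8,          # CLAHE tile grid per axis
      clahe_limit = 2           # CLAHE clip limit
    ),
    radiomics = list(
      n_levels = 32,            # grey levels for discretization
      distance = 1,             # co-occurrence offset length, voxels
      min_roi_voxels = 27       # smallest ROI accepted by the extractor
    ),
    classify = list(
      k = 10,                   # cross-validation folds
      nrounds = 300, max_depth = 4, eta = 0.1,
      cutoff = 0.5              # probability threshold for per-day status
    ),
    fusion = list(
      threshold_fraction = 0.87, # fraction of per-line peak amplitude
      noise_sd_mult = 5          # noise floor = mean + mult * SD of background
    )
  )
}

.check_range <- function(val, lo, hi, what) {
  if (any(!is.finite(val)) || any(val < lo) || any(val > hi))
    stop(what, " must lie in [", lo, ", ", hi, "]")
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' @param config a configuration list as returned by [defaultConfig()] or
#'   [readConfig()].
#' @return The config, invisibly, or an error describing the first violation.
#' @export
validateConfig <- function(config) {
  .check_range(config$recon$n_medium, 1, 2, "recon$n_medium")
  p <- config$segmentation$percentiles
  if (length(p) != 2L || p[1] >= p[2]) stop("percentiles must be ordered")
  .check_range(p, 0, 100, "segmentation$percentiles")
  if (config$segmentation$min_volume_um3 < 0) stop("min_volume_um3 must be >= 0")
  w <- config$tracking$weights
  if (abs(sum(w) - 1) > 1e-8) stop("tracking weights must sum to 1")
  .check_range(config$tracking$tau, 0, 1, "tracking$tau")
  .check_range(config$tracking$merge_fraction, 0, 1, "tracking$merge_fraction")
  if (config$growth$f_plateau <= 1) stop("f_plateau must exceed 1")
  if (config$growth$p_plateau < 1) stop("p_plateau must be >= 1")
  .check_range(config$viability$cutoff, 0, 1, "viability$cutoff")
  if (config$radiomics$n_levels < 2) stop("n_levels must be >= 2")
  if (config$classify$k < 2) stop("classify$k must be >= 2")
  tf <- config$fusion$threshold_fraction
  if (tf <= 0 || tf >= 1) stop("fusion$threshold_fraction must be in (0, 1)")
  invisible(config)
}

#' Read a YAML configuration, merged over the defaults
#'
#' Missing groups or parameters fall back to [defaultConfig()]; the merged
#' configuration is validated before being returned.
#'
#' @param path YAML file with one section per pipeline stage.
#' @return Validated configuration list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  for (grp in names(user)) {
    if (is.list(user[[grp]]) && grp %in% names(cfg)) {
      cfg[[grp]][names(user[[grp]])] <- user[[grp]]
    } else {
      cfg[[grp]] <- user[[grp]]
    }
  }
  validateConfig(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' Logs the fully resolved configuration so a run can be reproduced exactly.
#'
#' @param config configuration list.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
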