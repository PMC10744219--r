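# Run configuration: geometric conventions, mapping, metrics options.

#' Analysis configuration
#'
#' Collects every tunable convention of the pipeline with documented
#' defaults.  Unknown arguments are rejected.
#'
#' @param f_base,f_apex,center_mode centre-of-contraction rule; see
#'   [center_rule()].
#' @param n_resample points per view for arc-length correspondence
#'   (default 200).
#' @param cap_fraction wall-arc fraction forming the apical cap
#'   (default 0.10).
#' @param level_boundaries wall-arc fractions separating basal/mid and
#'   mid/apical bands (default `c(1/3, 2/3)`).
#' @param segment_map a segment map as from [default_segment_map()].
#' @param shared_weighting `"unweighted"` or `"points"`; how segments shared
#'   between views are fused.
#' @param n_disks disks for volumetry (default 250).
#' @param bsa_formula `"dubois"` (default) or `"mosteller"`.
#' @param akinesis_band,hypokinesis_z wall-motion classification thresholds;
#'   see [classify_wall_motion()].
#' @param seed optional RNG seed recorded in reports.
#' @return object of class `"ind_config"`.
#' @export
ind_config <- function(f_base = 0.5, f_apex = 2 / 3,
                       center_mode = "continuous",
                       n_resample = 200L, cap_fraction = 0.10,
                       level_boundaries = c(1 / 3, 2 / 3),
                       segment_map = NULL,
                       shared_weighting = "unweighted",
                       n_disks = 250L, bsa_formula = "dubois",
                       akinesis_band = 2, hypokinesis_z = -1.96,
                       seed = NULL) {
  if (is.null(segment_map)) segment_map <- default_segment_map(cap_fraction)
  segment_map$cap_fraction <- cap_fraction
  validate_segment_map(segment_map)
  if (length(level_boundaries) != 2L ||
      !(0 < level_boundaries[1L] && level_boundaries[1L] < level_boundaries[2L] &&
        level_boundaries[2L] < 1))
    stop("level_boundaries must be two increasing fractions in (0, 1)")
  cfg <- list(
    rule = center_rule(f_base, f_apex, center_mode),
    n_resample = as.integer(n_resample),
    cap_fraction = cap_fraction,
    level_boundaries = level_boundaries,
    segment_map = segment_map,
    shared_weighting = match.arg(shared_weighting, c("unweighted", "points")),
    n_disks = as.integer(n_disks),
    bsa_formula = match.arg(bsa_formula, c("dubois", "mosteller")),
    akinesis_band = akinesis_band,
    hypokinesis_z = hypokinesis_z,
    seed = seed)
  structure(cfg, class = "ind_config")
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [ind_config()]; a `segment_map` block may
#' override the per-view wall-to-segment binding as
#' `segment_map: {4CH: {wall1: [3, 9, 14], wall2: [6, 12, 16]}, ...}`.
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return an [ind_config()] object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(ind_config)), "segment_map")
  extra <- setdiff(names(y), c(known, "segment_map"))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  map <- NULL
  if (!is.null(y$segment_map)) {
    map <- default_segment_map()
    for (v in names(y$segment_map)) {
      if (!v %in% IND_VIEWS) stop("unknown view in segment_map: ", v)
      for (w in c("wall1", "wall2"))
        if (!is.null(y$segment_map[[v]][[w]]))
          map$views[[v]][[w]] <- as.integer(y$segment_map[[v]][[w]])
    }
    y$segment_map <- NULL
  }
  do.call(ind_config, c(y, list(segment_map = map)))
}

# Configuration echo used for report provenance.
config_echo <- function(cfg) {
  list(f_base = cfg$rule$f_base, f_apex = cfg$rule$f_apex,
       center_mode = cfg$rule$mode, n_resample = cfg$n_resample,
       cap_fraction = cfg$cap_fraction,
       level_boundaries = cfg$level_boundaries,
       segment_map = lapply(cfg$segment_map$views, function(v)
         list(wall1 = v$wall1, wall2 = v$wall2)),
       shared_weighting = cfg$shared_weighting, n_disks = cfg$n_disks,
       bsa_formula = cfg$bsa_formula, akinesis_band = cfg$akinesis_band,
       hypokinesis_z = cfg$hypokinesis_z, seed = cfg$seed)
}
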