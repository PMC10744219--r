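# Normal reference ranges for segmental InD in healthy adults, z-score
# comparison against them, and wall-motion classification.

#' Normal reference ranges for segmental inward displacement
#'
#' Loads the packaged normal ranges (mean and SD of InD %, per AHA segment
#' and per region) established in 120 healthy adults with normal ejection
#' fraction.  At load the regional means are re-derived from the segmental
#' means and checked against the packaged regional table within rounding.
#'
#' @param path optional path to a CSV with columns
#'   `segment,name,region,mean_pct,sd_pct` (17 rows); defaults to the
#'   packaged table.
#' @return data.frame of 17 rows with attribute `"regions"` holding the
#'   regional means/SDs (base, mid, apex, overall); class `"ind_reference"`.
#' @export
ind_reference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ind_reference_segments.csv",
                        package = "lvind", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "name", "region", "mean_pct", "sd_pct")
  if (!all(need %in% names(ref)))
    stop("reference file must have columns ", paste(need, collapse = ", "))
  ref <- ref[order(ref$segment), ]
  if (!identical(as.integer(ref$segment), 1:17))
    stop("reference must contain segments 1..17 exactly")
  if (any(ref$sd_pct <= 0)) stop("reference SDs must be positive")
  rpath <- system.file("extdata", "ind_reference_regions.csv",
                       package = "lvind", mustWork = TRUE)
  regions <- utils::read.csv(rpath, stringsAsFactors = FALSE)
  derived <- round(region_averages(ref$mean_pct, digits = 1), 1)
  packaged <- regions$mean_pct[match(c("base", "mid", "apex", "overall"),
                                     regions$region)]
  if (any(abs(derived - packaged) > 0.05 + 1e-9))
    stop("reference self-consistency failure: regional means do not match segment means")
  attr(ref, "regions") <- regions
  class(ref) <- c("ind_reference", "data.frame")
  ref
}

#' Compare a bullseye to the normal reference ranges
#'
#' Per segment, `z = (value - ref_mean) / ref_sd`; segments with `|z| > 1.96`
#' lie outside the 95% reference band and are flagged.  Missing segments are
#' flagged as missing and excluded.
#'
#' @param b a [bullseye17()] object or a numeric vector of 17 values.
#' @param ref an [ind_reference()] table.
#' @return data.frame with `segment`, `name`, `ind_pct`, `ref_mean`,
#'   `ref_sd`, `z`, `outside_95`, `missing`.
#' @export
zscore_bullseye <- function(b, ref = ind_reference()) {
  seg <- if (inherits(b, "bullseye17")) b$seg_pct else as.numeric(b)
  if (length(seg) != 17L) stop("need a complete 17-segment bullseye")
  z <- (seg - ref$mean_pct) / ref$sd_pct
  data.frame(segment = 1:17, name = ref$name, ind_pct = seg,
             ref_mean = ref$mean_pct, ref_sd = ref$sd_pct, z = z,
             outside_95 = !is.na(z) & abs(z) > 1.96,
             missing = is.na(seg))
}

#' Classify segmental wall motion
#'
#' Dyskinetic motion is paradoxically outward (InD < 0%); akinesis is the
#' absence of contraction (InD in `[0, akinesis_band)`, default band 2%);
#' hypokinesis is contraction significantly below the normal range
#' (`z < hypo_z`, default -1.96); otherwise motion is normal.
#'
#' @param ind_pct numeric vector of segmental InD values (%).
#' @param ref_mean,ref_sd matching reference means and SDs (%).
#' @param akinesis_band upper bound (%) of the akinetic band (default 2).
#' @param hypo_z z-score threshold for hypokinesis (default -1.96).
#' @return factor with levels normal, hypokinetic, akinetic, dyskinetic.
#' @examples
#' classify_wall_motion(c(-5, 0, 35.6), 35.6, 5.6)
#' @export
classify_wall_motion <- function(ind_pct, ref_mean, ref_sd,
                                 akinesis_band = 2, hypo_z = -1.96) {
  z <- (ind_pct - ref_mean) / ref_sd
  out <- ifelse(ind_pct < 0, "dyskinetic",
         ifelse(ind_pct < akinesis_band, "akinetic",
         ifelse(z < hypo_z, "hypokinetic", "normal")))
  factor(out, levels = c("normal", "hypokinetic", "akinetic", "dyskinetic"))
}
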