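# Main entry point: inward-displacement analysis of one subject's contour
# set, returning a classed result with print/summary/coef/plot methods.

#' Inward-displacement analysis of a left-ventricular contour set
#'
#' Runs the full regional-function pipeline on one subject: per view, the LV
#' axis is fitted from the end-diastolic contour and held fixed; ED and ES
#' points are paired (externally tracked indices when the set is paired,
#' arc-length correspondence otherwise); each point's inward displacement
#' toward its centre of contraction is computed in mm and as a percentage of
#' the ED point-to-centre distance; points are assigned to AHA segments and
#' averaged; the three views are fused into the 17-segment bullseye.
#' Volumes, ejection fraction and global longitudinal strain are derived
#' from the same contours.
#'
#' @param x a [contour_set()], or a path to a contour JSON/CSV file
#'   (see [read_contours()]).
#' @param config an [ind_config()].
#' @return object of class `"ind"`: list with `subject_id`, `bullseye` (a
#'   [bullseye17()]), `metrics` (see [lv_metrics()]), `points` (per-view
#'   per-point tables), `views`, `config`.
#' @examples
#' ph <- generate_phantom(phantom_spec(s = 0.33, n_points = 120))
#' fit <- inward_displacement(ph$contours)
#' coef(fit)[["10"]]  # segment 10 InD, %
#' @export
inward_displacement <- function(x, config = ind_config()) {
  if (is.character(x)) x <- read_contours(x)
  stopifnot(inherits(x, "contour_set"), inherits(config, "ind_config"))
  views <- intersect(IND_VIEWS, set_views(x))
  point_tables <- list()
  view_tables <- list()
  for (v in views) {
    ed <- get_contour(x, v, "ED")
    es <- get_contour(x, v, "ES")
    if (is.null(ed) || is.null(es)) next
    axis <- fit_axis(ed)
    pts <- view_ind_points(ed, es, rule = config$rule,
                           n = config$n_resample, paired = x$paired,
                           axis = axis)
    asg <- assign_segments(cbind(pts$x_ed, pts$y_ed), axis, v,
                           config$segment_map, config$level_boundaries)
    pts$wall <- asg$wall
    pts$wall_frac <- asg$wall_frac
    pts$segment <- asg$segment
    point_tables[[v]] <- pts
    view_tables[[v]] <- segment_means(pts$ind_pct, pts$segment)
  }
  if (length(view_tables) == 0L) stop("no view has both ED and ES contours")
  partial <- length(view_tables) < 3L
  if (partial)
    warning("partial analysis: missing view(s) ",
            paste(setdiff(IND_VIEWS, names(view_tables)), collapse = ", "),
            "; uncovered segments are reported as missing")
  bullseye <- merge_views(view_tables, weighting = config$shared_weighting,
                          partial = partial)
  metrics <- lv_metrics(x, n_disks = config$n_disks,
                        bsa_formula = config$bsa_formula)
  structure(list(subject_id = x$subject_id, bullseye = bullseye,
                 metrics = metrics, points = point_tables,
                 views = names(view_tables), config = config),
            class = "ind")
}

#' @export
print.ind <- function(x, ...) {
  cat(sprintf("Inward displacement analysis: subject %s (views %s)\n",
              x$subject_id, paste(x$views, collapse = ", ")))
  cat(sprintf("  overall InD %.1f%%  (base %.1f, mid %.1f, apex %.1f)\n",
              x$bullseye$overall, x$bullseye$base, x$bullseye$mid,
              x$bullseye$apex))
  m <- x$metrics
  cat(sprintf("  EDV %.1f mL  ESV %.1f mL  EF %.1f%%  GLS %.1f%%\n",
              m$edv_ml, m$esv_ml, m$ef_pct, m$gls_pct))
  if (!is.null(m$bsa_m2))
    cat(sprintf("  BSA %.2f m2  EDVi %.1f  ESVi %.1f mL/m2\n",
                m$bsa_m2, m$edvi_ml_m2, m$esvi_ml_m2))
  invisible(x)
}

#' @export
coef.ind <- function(object, ...) {
  object$bullseye$seg_pct
}

#' Summarise an analysis against the normal reference ranges
#'
#' @param object an `"ind"` result.
#' @param reference an [ind_reference()] table.
#' @param ... unused.
#' @return object of class `"summary.ind"` carrying the per-segment z-score
#'   and wall-motion classification table.
#' @export
summary.ind <- function(object, reference = ind_reference(), ...) {
  tab <- zscore_bullseye(object$bullseye, reference)
  tab$wall_motion <- classify_wall_motion(
    tab$ind_pct, tab$ref_mean, tab$ref_sd,
    akinesis_band = object$config$akinesis_band,
    hypo_z = object$config$hypokinesis_z)
  structure(list(ind = object, comparison = tab), class = "summary.ind")
}

#' @export
print.summary.ind <- function(x, ...) {
  print(x$ind)
  tab <- x$comparison
  tab$ind_pct <- round(tab$ind_pct, 1)
  tab$z <- round(tab$z, 2)
  cat("\nComparison with normal reference ranges:\n")
  print(tab[, c("segment", "name", "ind_pct", "ref_mean", "ref_sd", "z",
                "outside_95", "wall_motion")], row.names = FALSE)
  invisible(x)
}

#' Bullseye polar plot of segmental inward displacement
#'
#' Draws the standard AHA bullseye (basal ring outermost, apical cap in the
#' centre) coloured by segmental InD.
#'
#' @param x an `"ind"` result or a [bullseye17()] object.
#' @param palette colour ramp function (low to high).
#' @param zlim value range mapped to the palette; defaults to the data range.
#' @param main plot title.
#' @param ... unused.
#' @export
plot.ind <- function(x, palette = NULL, zlim = NULL, main = NULL, ...) {
  b <- if (inherits(x, "bullseye17")) x else x$bullseye
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))
  vals <- b$seg_pct
  if (is.null(zlim)) zlim <- range(vals, na.rm = TRUE) + c(-1e-9, 1e-9)
  cols <- palette(100L)[pmin(pmax(
    ceiling(99 * (vals - zlim[1L]) / diff(zlim)) + 1L, 1L), 100L)]
  graphics::plot.new()
  graphics::plot.window(c(-1.3, 1.3), c(-1.3, 1.3), asp = 1)
  sector <- function(r0, r1, a0, a1, col) {
    a <- seq(a0, a1, length.out = 30L)
    graphics::polygon(c(r1 * cos(a), r0 * cos(rev(a))),
                      c(r1 * sin(a), r0 * sin(rev(a))),
                      col = col, border = "grey30")
  }
  # standard orientation: segment 1 (anterior) at top, counter-clockwise
  ring <- function(ids, r0, r1) {
    k <- length(ids)
    for (i in seq_len(k)) {
      a0 <- pi / 2 + (i - 1) * 2 * pi / k + pi / k * (k == 4)
      sector(r0, r1, a0, a0 + 2 * pi / k, cols[ids[i]])
      am <- a0 + pi / k
      rm <- (r0 + r1) / 2
      graphics::text(rm * cos(am), rm * sin(am),
                     sprintf("%d\n%.0f", ids[i], vals[ids[i]]), cex = 0.6)
    }
  }
  ring(1:6, 2 / 3, 1)
  ring(7:12, 1 / 3, 2 / 3)
  ring(13:16, 1 / 6, 1 / 3)
  sector(0, 1 / 6, 0, 2 * pi, cols[17L])
  graphics::text(0, 0, sprintf("17\n%.0f", vals[17L]), cex = 0.6)
  graphics::title(main = if (is.null(main)) "Inward displacement (%)" else main)
  invisible(x)
}

#' @export
plot.bullseye17 <- function(x, ...) plot.ind(x, ...)
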