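# Contour geometry: LV axis, centre-of-contraction rule, point correspondence
# and per-point inward displacement.

#' Fit the left-ventricular long axis from an end-diastolic contour
#'
#' The axis runs from the midpoint of the two mitral-annulus insertion points
#' (the first and last contour points) to the apex, identified as the contour
#' point farthest from that midpoint.  This is parameter-free and correct for
#' convex ventricular shapes.
#'
#' @param contour a [lax_contour] or an n x 2 point matrix.
#' @return object of class `"lv_axis"`: list with `base_mid`, `apex`,
#'   `length_mm` and the unit direction `u` (base to apex).
#' @examples
#' th <- seq(0, pi, length.out = 41)
#' ax <- fit_axis(cbind(-20 * cos(th), 90 * sin(th)))
#' ax$length_mm  # 90
#' @export
fit_axis <- function(contour) {
  p <- contour_points(contour)
  base_mid <- (p[1L, ] + p[nrow(p), ]) / 2
  d2 <- (p[, 1L] - base_mid[1L])^2 + (p[, 2L] - base_mid[2L])^2
  # round before the argmax so near-exact ties (symmetric shapes) resolve to
  # the same sample regardless of the contour's rigid pose
  i <- which.max(round(d2, 6))
  len <- sqrt(d2[i])
  if (!is.finite(len) || len <= .Machine$double.eps^0.5)
    stop("zero-length axis")
  apex <- p[i, ]
  structure(list(base_mid = base_mid, apex = apex, length_mm = len,
                 u = (apex - base_mid) / len, apex_index = i),
            class = "lv_axis")
}

#' @export
print.lv_axis <- function(x, ...) {
  cat(sprintf("<lv_axis> base_mid (%.1f, %.1f) -> apex (%.1f, %.1f), L = %.1f mm\n",
              x$base_mid[1], x$base_mid[2], x$apex[1], x$apex[2], x$length_mm))
  invisible(x)
}

#' Longitudinal fraction of a point along the LV axis
#'
#' Projects point(s) onto the base-to-apex axis and returns the projected
#' position as a fraction of axis length, clamped to \[0, 1\] (annulus points
#' may project marginally outside due to noise).
#'
#' @param p a length-2 point or an n x 2 matrix of points.
#' @param axis an [fit_axis()] result.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
longitudinal_fraction <- function(p, axis) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2L)
  f <- ((p[, 1L] - axis$base_mid[1L]) * axis$u[1L] +
        (p[, 2L] - axis$base_mid[2L]) * axis$u[2L]) / axis$length_mm
  pmin(pmax(f, 0), 1)
}

#' Centre-of-contraction rule
#'
#' The target of inward motion lies on the LV axis at a position that varies
#' from half the base-to-apex distance (for basal points) to two thirds (for
#' apical points).  `mode = "continuous"` interpolates linearly in the
#' point's longitudinal fraction; `mode = "discrete3"` uses three fixed
#' levels (basal/mid/apical thirds).
#'
#' @param f_base,f_apex axis fractions of the centre for basal and apical
#'   points; defaults 1/2 and 2/3.
#' @param mode `"continuous"` or `"discrete3"`.
#' @return object of class `"center_rule"`.
#' @export
center_rule <- function(f_base = 0.5, f_apex = 2 / 3,
                        mode = c("continuous", "discrete3")) {
  mode <- match.arg(mode)
  if (!is.numeric(f_base) || !is.numeric(f_apex) ||
      !(f_base > 0 && f_base <= f_apex && f_apex < 1))
    stop("invalid center rule: need 0 < f_base <= f_apex < 1")
  structure(list(f_base = f_base, f_apex = f_apex, mode = mode),
            class = "center_rule")
}

#' Centre of contraction for a given longitudinal fraction
#'
#' @param f numeric vector of longitudinal fractions in \[0, 1\].
#' @param axis an [fit_axis()] result.
#' @param rule a [center_rule()].
#' @return n x 2 matrix of centre coordinates (mm).
#' @examples
#' ax <- list(base_mid = c(0, 0), apex = c(0, 90), length_mm = 90, u = c(0, 1))
#' class(ax) <- "lv_axis"
#' contraction_center(0, ax)    # (0, 45): half of base-to-apex
#' contraction_center(1, ax)    # (0, 60): two thirds
#' @export
contraction_center <- function(f, axis, rule = center_rule()) {
  if (!inherits(rule, "center_rule")) stop("`rule` must be a center_rule")
  if (any(f < 0 | f > 1)) stop("longitudinal fraction outside [0, 1]")
  g <- switch(rule$mode,
    continuous = rule$f_base + f * (rule$f_apex - rule$f_base),
    discrete3 = ifelse(f < 1 / 3, rule$f_base,
                ifelse(f < 2 / 3, (rule$f_base + rule$f_apex) / 2,
                       rule$f_apex)))
  cbind(axis$base_mid[1L] + g * axis$length_mm * axis$u[1L],
        axis$base_mid[2L] + g * axis$length_mm * axis$u[2L])
}

#' Resample a polyline at equal fractional arc length
#'
#' @param points n x 2 matrix.
#' @param n number of output samples (endpoints included).
#' @return n x 2 matrix of points on the polyline.
#' @export
resample_polyline <- function(points, n) {
  points <- contour_points(points)
  s <- arc_positions(points)
  keep <- c(TRUE, diff(s) > 0)  # drop zero-length segments for interpolation
  s <- s[keep]; points <- points[keep, , drop = FALSE]
  target <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, points[, 1L], xout = target, rule = 2)$y,
        stats::approx(s, points[, 2L], xout = target, rule = 2)$y)
}

#' Establish ED/ES point correspondence by arc-length resampling
#'
#' Stands in for image-based feature tracking: each contour is resampled at
#' `n` points at equal fractional arc length measured from the first annulus
#' endpoint, and points are paired by equal fraction.  Exact for similarity
#' motions of the wall.
#'
#' @param ed,es [lax_contour] objects of the same view at ED and ES.
#' @param n number of sample points (>= 20).
#' @return list with matrices `ed` and `es` (n x 2 each), paired row-wise.
#' @export
correspond_points <- function(ed, es, n = 200L) {
  if (!inherits(ed, "lax_contour") || !inherits(es, "lax_contour"))
    stop("`ed` and `es` must be lax_contour objects")
  if (ed$view != es$view)
    stop("mismatched views: ", ed$view, " vs ", es$view)
  if (n < 20L) stop("n must be at least 20")
  list(ed = resample_polyline(ed$points, n),
       es = resample_polyline(es$points, n))
}

#' Point-wise inward displacement
#'
#' For each paired ED/ES point and its centre of contraction, returns the
#' component of the ED-to-ES displacement vector directed toward the centre
#' (mm), and the same normalised to the ED point-to-centre distance (%).
#' 100% is the theoretical limit at which the wall reaches the centreline
#' (the ventricle shrinks to zero volume); 0% is akinesis (no motion) and
#' negative values indicate dyskinetic, outward motion.
#'
#' @param p_ed,p_es,center length-2 points or n x 2 matrices (mm).
#' @return list with numeric vectors `ind_mm` and `ind_pct`.
#' @examples
#' point_inward_displacement(c(40, 0), c(20, 0), c(0, 0))  # 20 mm, 50%
#' @export
point_inward_displacement <- function(p_ed, p_es, center) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2L)
  p_ed <- as_mat(p_ed); p_es <- as_mat(p_es); center <- as_mat(center)
  dx <- center[, 1L] - p_ed[, 1L]
  dy <- center[, 2L] - p_ed[, 2L]
  dist <- sqrt(dx^2 + dy^2)
  if (any(dist <= .Machine$double.eps^0.5))
    stop("point coincides with center of contraction")
  ux <- dx / dist
  uy <- dy / dist
  ind_mm <- (p_es[, 1L] - p_ed[, 1L]) * ux + (p_es[, 2L] - p_ed[, 2L]) * uy
  list(ind_mm = ind_mm, ind_pct = 100 * ind_mm / dist)
}

# Per-view InD table: pairs points, finds centres from the ED-frame axis
# (held fixed for ES) and computes point-wise InD.
view_ind_points <- function(ed, es, rule = center_rule(), n = 200L,
                            paired = FALSE, axis = NULL) {
  if (paired) {
    if (nrow(ed$points) != nrow(es$points))
      stop("paired input requires equal ED/ES point counts in view ", ed$view)
    pts <- list(ed = ed$points, es = es$points)
  } else {
    pts <- correspond_points(ed, es, n)
  }
  if (is.null(axis)) axis <- fit_axis(pts$ed)
  f <- longitudinal_fraction(pts$ed, axis)
  ctr <- contraction_center(f, axis, rule)
  ind <- point_inward_displacement(pts$ed, pts$es, ctr)
  data.frame(view = ed$view,
             x_ed = pts$ed[, 1L], y_ed = pts$ed[, 2L],
             x_es = pts$es[, 1L], y_es = pts$es[, 2L],
             f = f, center_x = ctr[, 1L], center_y = ctr[, 2L],
             ind_mm = ind$ind_mm, ind_pct = ind$ind_pct)
}
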