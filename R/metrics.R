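# Volumes, ejection fraction, global longitudinal strain and body-surface
# indexing, all derived from the same long-axis contour sets.

#' Triplane method-of-disks ventricular volume
#'
#' The long axis is divided into `n_disks` slabs.  Within each available view
#' the cavity half-widths are measured perpendicular to that view's axis on
#' both sides; the disk radius is the mean of all half-widths at that level
#' (across sides and views) and the disk area \eqn{\pi \bar r^2}.  Slab
#' levels are fractional positions along each view's own axis; slab thickness
#' uses the longest view axis.  A side not crossed by the contour at a level
#' contributes a zero half-width (warned about when more than 5% of slabs are
#' affected).
#'
#' @param contours list of 1-3 [lax_contour] objects of one phase (one per
#'   view).
#' @param n_disks number of slabs (>= 20; default 250).
#' @param axes optional list of [fit_axis()] results matching `contours`;
#'   fitted from each contour when omitted.
#' @return volume in mL.
#' @examples
#' th <- seq(0, pi, length.out = 201)
#' ct <- lax_contour(cbind(-20 * cos(th), 90 * sin(th)), "4CH", "ED")
#' disk_volume(list(ct), n_disks = 500)  # ~75.4 mL = (2/3) pi r^2 L / 1000
#' @export
disk_volume <- function(contours, n_disks = 250L, axes = NULL) {
  if (inherits(contours, "lax_contour")) contours <- list(contours)
  stopifnot(length(contours) >= 1L, length(contours) <= 3L)
  if (n_disks < 20L) stop("n_disks must be at least 20")
  if (is.null(axes)) axes <- lapply(contours, fit_axis)
  lens <- vapply(axes, `[[`, numeric(1), "length_mm")
  L <- max(lens)
  levels <- (seq_len(n_disks) - 0.5) / n_disks
  half <- matrix(0, nrow = n_disks, ncol = 0)
  miss <- 0L
  for (i in seq_along(contours)) {
    hw <- .half_widths(contour_points(contours[[i]]), axes[[i]], levels)
    miss <- miss + hw$missing
    half <- cbind(half, hw$left, hw$right)
  }
  if (miss > 0.05 * n_disks * 2L * length(contours))
    warning(sprintf("%d of %d half-widths missing (contour does not cross slab); treated as 0",
                    miss, n_disks * 2L * length(contours)))
  rbar <- rowMeans(half)
  sum(pi * rbar^2) * (L / n_disks) / 1000
}

# Half-widths of one view's cavity at fractional axis levels.  Points are
# expressed in axis coordinates (u = axial fraction, v = signed perpendicular
# offset); each polyline segment straddling a level contributes an
# interpolated crossing, and the half-width per side is the largest |v|
# among crossings of that sign.
.half_widths <- function(p, axis, levels) {
  nv <- c(-axis$u[2L], axis$u[1L])
  rel_x <- p[, 1L] - axis$base_mid[1L]
  rel_y <- p[, 2L] - axis$base_mid[2L]
  u <- (rel_x * axis$u[1L] + rel_y * axis$u[2L]) / axis$length_mm
  v <- rel_x * nv[1L] + rel_y * nv[2L]
  n <- length(u)
  left <- right <- numeric(length(levels))
  missing <- 0L
  for (j in seq_along(levels)) {
    lv <- levels[j]
    cross <- which((u[-n] - lv) * (u[-1L] - lv) <= 0 & u[-n] != u[-1L])
    if (length(cross)) {
      t <- (lv - u[cross]) / (u[cross + 1L] - u[cross])
      vc <- v[cross] + t * (v[cross + 1L] - v[cross])
      if (any(vc < 0)) left[j] <- max(-vc[vc < 0]) else missing <- missing + 1L
      if (any(vc > 0)) right[j] <- max(vc[vc > 0]) else missing <- missing + 1L
    } else missing <- missing + 2L
  }
  list(left = left, right = right, missing = missing)
}

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param edv,esv volumes in mL; `edv > 0`, `esv >= 0`.
#' @return EF in percent, `100 * (edv - esv) / edv`.  A negative EF (ESV
#'   exceeding EDV) is permitted but flagged with a warning.
#' @export
ejection_fraction <- function(edv, esv) {
  if (!is.finite(edv) || edv <= 0) stop("edv must be positive")
  if (!is.finite(esv) || esv < 0) stop("esv must be non-negative")
  if (esv > edv) warning("ESV exceeds EDV: negative ejection fraction")
  100 * (edv - esv) / edv
}

#' Global longitudinal strain from endocardial contour lengths
#'
#' Per view, the strain is the fractional systolic change of the endocardial
#' arc length, `100 * (l_ES - l_ED) / l_ED`; GLS is the mean over the views
#' present in both phases.  Negative values indicate shortening.
#'
#' @param ed_contours,es_contours lists of [lax_contour] objects; the same
#'   views must be present in both.
#' @return GLS in percent.
#' @export
gls_from_contours <- function(ed_contours, es_contours) {
  if (inherits(ed_contours, "lax_contour")) ed_contours <- list(ed_contours)
  if (inherits(es_contours, "lax_contour")) es_contours <- list(es_contours)
  ed_views <- vapply(ed_contours, `[[`, character(1), "view")
  es_views <- vapply(es_contours, `[[`, character(1), "view")
  if (!setequal(ed_views, es_views) || length(ed_views) == 0L)
    stop("ED and ES contours must cover the same non-empty set of views")
  strains <- vapply(ed_views, function(v) {
    led <- polyline_length(ed_contours[[which(ed_views == v)]]$points)
    les <- polyline_length(es_contours[[which(es_views == v)]]$points)
    100 * (les - led) / led
  }, numeric(1))
  mean(strains)
}

#' Body surface area
#'
#' Du Bois (default): `0.007184 * weight^0.425 * height^0.725`;
#' Mosteller: `sqrt(height * weight / 3600)`.
#'
#' @param height_cm,weight_kg positive anthropometrics.
#' @param formula `"dubois"` or `"mosteller"`.
#' @return BSA in m^2.
#' @examples
#' bsa(172.2, 72.0)  # ~1.85 m^2
#' @export
bsa <- function(height_cm, weight_kg, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  switch(formula,
         dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
         mosteller = sqrt(height_cm * weight_kg / 3600))
}

#' Volume indexed to body surface area
#'
#' @param vol_ml volume in mL.
#' @param bsa_m2 body surface area in m^2.
#' @return indexed volume in mL/m^2.
#' @export
volume_index <- function(vol_ml, bsa_m2) {
  if (any(bsa_m2 <= 0)) stop("BSA must be positive")
  vol_ml / bsa_m2
}

#' Volumetric and strain metrics for one subject
#'
#' Derives EDV, ESV, EF and GLS from a subject's contour set, plus BSA and
#' indexed volumes when anthropometrics are available.
#'
#' @param set a [contour_set()].
#' @param n_disks disks for [disk_volume()].
#' @param bsa_formula passed to [bsa()].
#' @return list with `edv_ml`, `esv_ml`, `ef_pct`, `gls_pct` and, when
#'   height/weight are present, `bsa_m2`, `edvi_ml_m2`, `esvi_ml_m2`.
#' @export
lv_metrics <- function(set, n_disks = 250L, bsa_formula = "dubois") {
  stopifnot(inherits(set, "contour_set"))
  views <- set_views(set)
  ed <- Filter(Negate(is.null), lapply(views, get_contour, set = set, phase = "ED"))
  es <- Filter(Negate(is.null), lapply(views, get_contour, set = set, phase = "ES"))
  if (length(ed) == 0L || length(es) == 0L)
    stop("contour set lacks a complete phase")
  edv <- disk_volume(ed, n_disks = n_disks)
  esv <- disk_volume(es, n_disks = n_disks)
  out <- list(edv_ml = edv, esv_ml = esv,
              ef_pct = ejection_fraction(edv, esv),
              gls_pct = gls_from_contours(ed, es))
  if (!is.null(set$height_cm) && !is.null(set$weight_kg)) {
    out$bsa_m2 <- bsa(set$height_cm, set$weight_kg, bsa_formula)
    out$edvi_ml_m2 <- volume_index(edv, out$bsa_m2)
    out$esvi_ml_m2 <- volume_index(esv, out$bsa_m2)
  }
  out
}
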