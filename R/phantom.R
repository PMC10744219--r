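# Parametric contracting-ventricle phantom with known ground truth.  Every
# pipeline stage can be validated against the construction: end-diastolic
# contours are half-ellipses, and each point's end-systolic position is the
# ED point moved a known fraction of the way toward its own centre of
# contraction.

#' Phantom specification
#'
#' @param ed_radius_mm end-diastolic equatorial (mid-cavity) radius, mm.
#' @param ed_length_mm end-diastolic base-to-apex length, mm.
#' @param s per-segment contraction fraction: scalar (uniform) or length-17
#'   vector, each in (-0.5, 0.9].  A point with fraction `s` travels `s` of
#'   the way to its centre of contraction, so its true InD is `100 * s` %.
#' @param annular_descent_mm extra systolic displacement of the annulus
#'   toward the apex, tapering linearly to zero at the apex (default 0).
#' @param noise_sd_mm SD of isotropic Gaussian noise added to the ES point
#'   coordinates (default 0).
#' @param n_points contour samples per view (>= 20).  An even count is
#'   increased by one so the exact apex lies on the contour, which keeps the
#'   fitted axis identical to the construction axis.
#' @param seed RNG seed, recorded in the output.
#' @param mode `"paired"` declares matched ED/ES indices (tracked-points
#'   input); `"resampled"` emits plain contours so the pipeline must
#'   re-establish correspondence by arc length.
#' @param smoothing_band wall-arc width over which the contraction fraction
#'   is blended across segment boundaries (default 0.05), avoiding
#'   discontinuous ES contours.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(ed_radius_mm = 22, ed_length_mm = 90, s = 0.33,
                         annular_descent_mm = 0, noise_sd_mm = 0,
                         n_points = 200L, seed = 1L,
                         mode = c("paired", "resampled"),
                         smoothing_band = 0.05) {
  mode <- match.arg(mode)
  if (ed_radius_mm <= 0 || ed_length_mm <= 0)
    stop("radius and length must be positive")
  if (length(s) == 1L) s <- rep(s, 17L)
  if (length(s) != 17L) stop("s must be a scalar or a length-17 vector")
  if (any(s >= 1)) stop("contraction fraction >= 1 would cross the center")
  if (any(s > 0.9) || any(s <= -0.5))
    stop("contraction fractions must lie in (-0.5, 0.9]")
  if (n_points < 20L) stop("n_points must be at least 20")
  structure(list(ed_radius_mm = ed_radius_mm, ed_length_mm = ed_length_mm,
                 s = s, annular_descent_mm = annular_descent_mm,
                 noise_sd_mm = noise_sd_mm, n_points = as.integer(n_points),
                 seed = as.integer(seed), mode = mode,
                 smoothing_band = smoothing_band),
            class = "phantom_spec")
}

# Piecewise contraction-fraction profile along one wall (0 = annulus,
# 1 = apex), linearly blended over `band` at level boundaries.
.s_profile <- function(frac, s_levels, boundaries, cap_start, band) {
  h <- band / 2
  xs <- c(0, boundaries[1L] - h, boundaries[1L] + h,
          boundaries[2L] - h, boundaries[2L] + h,
          cap_start - h, cap_start + h, 1)
  ys <- c(s_levels[1L], s_levels[1L], s_levels[2L], s_levels[2L],
          s_levels[3L], s_levels[3L], s_levels[4L], s_levels[4L])
  stats::approx(xs, ys, xout = frac, rule = 2)$y
}

#' Generate a contracting-ventricle phantom
#'
#' Builds half-ellipse ED contours for the three long-axis views, moves each
#' point the (segment-dependent, boundary-smoothed) contraction fraction of
#' the way toward its continuous-rule centre of contraction to obtain the ES
#' contour, optionally adds annular descent and contour noise, and returns
#' both the contour set and the ground truth computed from the noise-free
#' construction.
#'
#' @param spec a [phantom_spec()].
#' @param rule [center_rule()] used in the construction.
#' @param map [default_segment_map()] (or override) used both to attach
#'   contraction fractions and to compute the truth bullseye.
#' @param boundaries wall-arc level boundaries (default `c(1/3, 2/3)`).
#' @return list with `contours` (a [contour_set()]; paired or not per the
#'   spec mode), `clean` (the noise-free paired set), `truth` (list:
#'   `bullseye` with true segmental InD, `ef_pct`, `gls_pct`, `edv_ml`,
#'   `esv_ml`) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(s = 0.33, n_points = 80))
#' ph$truth$bullseye$overall  # 33
#' @export
generate_phantom <- function(spec, rule = center_rule(),
                             map = default_segment_map(),
                             boundaries = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_segment_map(map)
  n <- spec$n_points
  if (n %% 2L == 0L) n <- n + 1L  # include the exact apex sample
  r <- spec$ed_radius_mm
  L <- spec$ed_length_mm
  th <- seq(0, pi, length.out = n)
  set.seed(spec$seed)
  contours <- list(); clean <- list(); view_tables <- list()
  for (view in IND_VIEWS) {
    p_ed <- cbind(-r * cos(th), L * sin(th))
    axis <- fit_axis(p_ed)
    asg <- assign_segments(p_ed, axis, view, map, boundaries)
    vm <- map$views[[view]]
    s_pt <- numeric(n)
    for (w in 1:2) {
      ids <- c(if (w == 1L) vm$wall1 else vm$wall2, map$cap_segment)
      idx <- asg$wall == w
      s_pt[idx] <- .s_profile(asg$wall_frac[idx], spec$s[ids], boundaries,
                              1 - map$cap_fraction, spec$smoothing_band)
    }
    f <- longitudinal_fraction(p_ed, axis)
    ctr <- contraction_center(f, axis, rule)
    p_es <- p_ed + s_pt * (ctr - p_ed)
    if (spec$annular_descent_mm != 0)
      p_es <- p_es + spec$annular_descent_mm * (1 - asg$wall_frac) %o% axis$u
    p_es_noisy <- p_es
    if (spec$noise_sd_mm > 0)
      p_es_noisy <- p_es + matrix(stats::rnorm(2L * n, sd = spec$noise_sd_mm),
                                  ncol = 2L)
    clean[[paste(view, "ED")]] <- lax_contour(p_ed, view, "ED")
    clean[[paste(view, "ES")]] <- lax_contour(p_es, view, "ES")
    contours[[paste(view, "ED")]] <- lax_contour(p_ed, view, "ED")
    contours[[paste(view, "ES")]] <- lax_contour(p_es_noisy, view, "ES")
    ind <- point_inward_displacement(p_ed, p_es, ctr)
    view_tables[[view]] <- segment_means(ind$ind_pct, asg$segment)
  }
  clean_set <- contour_set(clean, subject_id = "phantom", paired = TRUE)
  truth_bullseye <- merge_views(view_tables)
  ed_list <- lapply(IND_VIEWS, get_contour, set = clean_set, phase = "ED")
  es_list <- lapply(IND_VIEWS, get_contour, set = clean_set, phase = "ES")
  edv <- .fine_volume(ed_list)
  esv <- .fine_volume(es_list)
  list(contours = contour_set(contours, subject_id = "phantom",
                              paired = spec$mode == "paired"),
       clean = clean_set,
       truth = list(bullseye = truth_bullseye,
                    edv_ml = edv, esv_ml = esv,
                    ef_pct = 100 * (edv - esv) / edv,
                    gls_pct = gls_from_contours(ed_list, es_list)),
       spec = spec)
}

# Reference volume of a contour set by dense functional integration:
# each wall's |perpendicular offset| is interpolated as a function of axial
# position, the mean over all walls and views taken on a fine grid, and
# pi * rbar^2 integrated by the trapezoidal rule.  Used as the phantom's
# volume oracle; independent of the slab-crossing machinery in disk_volume().
.fine_volume <- function(contours, n_grid = 4000L) {
  axes <- lapply(contours, fit_axis)
  L <- max(vapply(axes, `[[`, numeric(1), "length_mm"))
  y_grid <- seq(0, L, length.out = n_grid)
  widths <- matrix(0, nrow = n_grid, ncol = 0)
  for (i in seq_along(contours)) {
    p <- contour_points(contours[[i]])
    ax <- axes[[i]]
    nv <- c(-ax$u[2L], ax$u[1L])
    u <- ((p[, 1L] - ax$base_mid[1L]) * ax$u[1L] +
          (p[, 2L] - ax$base_mid[2L]) * ax$u[2L])
    v <- (p[, 1L] - ax$base_mid[1L]) * nv[1L] +
         (p[, 2L] - ax$base_mid[2L]) * nv[2L]
    ai <- ax$apex_index
    for (idx in list(seq_len(ai), seq(ai, nrow(p)))) {
      ord <- order(u[idx])
      uu <- u[idx][ord]; vv <- abs(v[idx][ord])
      keep <- c(TRUE, diff(uu) > 0)
      w <- stats::approx(uu[keep], vv[keep], xout = y_grid, rule = 1)$y
      w[is.na(w)] <- 0
      widths <- cbind(widths, w)
    }
  }
  rbar <- rowMeans(widths)
  a <- pi * rbar^2
  sum((a[-1L] + a[-n_grid]) / 2) * (L / (n_grid - 1L)) / 1000
}

#' Simulate a second observer's contour reading
#'
#' Adds seeded isotropic point-wise jitter to every contour of a set,
#' emulating manual contour correction by a different analyst.  The same
#' seed always yields the same perturbation.
#'
#' @param set a [contour_set()].
#' @param jitter_sd_mm SD of the Gaussian jitter (mm); 0 returns the set
#'   unchanged.
#' @param seed RNG seed.
#' @return a perturbed [contour_set()] (pairing flag preserved).
#' @export
simulate_observers <- function(set, jitter_sd_mm = 1, seed = 1L) {
  stopifnot(inherits(set, "contour_set"))
  if (jitter_sd_mm < 0) stop("jitter SD must be non-negative")
  if (jitter_sd_mm == 0) return(set)
  set.seed(seed)
  set$contours <- lapply(set$contours, function(ct) {
    ct$points <- ct$points +
      matrix(stats::rnorm(length(ct$points), sd = jitter_sd_mm), ncol = 2L)
    ct
  })
  set
}
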